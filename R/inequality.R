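# Block-group aggregation and population-weighted inequality metrics.
#
# Enhancements are aggregated to census block-group polygons by exact
# area weighting (polygon clipped against each grid cell), then summarised
# per demographic group as population-weighted means over the group's
# "eligible" block groups — those whose group population share is at or
# above the regional mean share. Inequality for a group is the absolute
# (and percent) difference of its population-weighted mean from the
# reference group's, with standard-mean-error uncertainties.

#' Construct a block-group polygon set
#'
#' @param ids character vector of block-group ids
#' @param polygons list of two-column (lon, lat) vertex matrices, one ring
#'   per block group (no holes)
#' @return an object of class `nh3_blockgroups`: a data frame of id,
#'   centroid and area with the rings stored in attribute `polygons`
#' @export
blockgroup_set <- function(ids, polygons) {
  stopifnot(length(ids) == length(polygons))
  cent <- t(vapply(polygons, ring_centroid, numeric(2)))
  area <- vapply(polygons, ring_area_km2, numeric(1))
  if (any(area <= 0)) stop("all block-group polygons must have positive area")
  df <- data.frame(id = as.character(ids),
                   center_lon = cent[, 1], center_lat = cent[, 2],
                   area_km2 = area, stringsAsFactors = FALSE)
  names(polygons) <- df$id
  structure(df, polygons = polygons, class = c("nh3_blockgroups", "data.frame"))
}

#' Polygon rings of a block-group set
#' @param bgs an `nh3_blockgroups`
#' @return named list of (lon, lat) vertex matrices
#' @export
blockgroup_polygons <- function(bgs) attr(bgs, "polygons")

#' Area-weighted mean enhancement within one polygon
#'
#' Exact polygon-cell intersection: the ring is clipped against every grid
#' cell it might touch and the enhancement values of enhanced cells are
#' averaged with the intersection areas as weights. `coverage` is the
#' fraction of the polygon's area lying over enhanced (defined) cells.
#' With `method = "centers"` a faster cell-centre containment rule is used
#' instead (each cell belongs wholly to the polygon containing its centre);
#' for polygons much larger than a cell the two agree closely.
#'
#' @param enh an `nh3_enhancement` (or any object with `delta`, `enhanced`
#'   matrices and a `grid` spec)
#' @param ring two-column (lon, lat) vertex matrix
#' @param method "intersection" (exact clipping, default) or "centers"
#' @return list with `value` (NA when coverage is 0) and `coverage`
#' @export
area_weighted_mean <- function(enh, ring, method = c("intersection", "centers")) {
  method <- match.arg(method)
  g <- enh$grid
  sp <- g$spacing_deg
  # cells whose extent could intersect the ring's bounding box
  lo_lat <- min(ring[, 2]); hi_lat <- max(ring[, 2])
  lo_lon <- min(ring[, 1]); hi_lon <- max(ring[, 1])
  ii <- which(g$lat + sp / 2 > lo_lat & g$lat - sp / 2 < hi_lat)
  jj <- which(g$lon + sp / 2 > lo_lon & g$lon - sp / 2 < hi_lon)
  if (!length(ii) || !length(jj))
    return(list(value = NA_real_, coverage = 0))

  poly_area <- ring_area_km2(ring)
  num <- 0; den <- 0
  if (method == "intersection") {
    for (i in ii) for (j in jj) {
      if (!enh$enhanced[i, j]) next
      piece <- clip_ring_rect(ring,
                              g$lon[j] - sp / 2, g$lon[j] + sp / 2,
                              g$lat[i] - sp / 2, g$lat[i] + sp / 2)
      a <- ring_area_km2(piece)
      if (a > 0) { num <- num + a * enh$delta[i, j]; den <- den + a }
    }
  } else {
    # cell-centre containment via even-odd ray casting
    for (i in ii) for (j in jj) {
      if (!enh$enhanced[i, j]) next
      if (point_in_ring(g$lon[j], g$lat[i], ring)) {
        a <- (sp * km_per_deg_lon(g$lat[i])) * (sp * KM_PER_DEG_LAT)
        num <- num + a * enh$delta[i, j]; den <- den + a
      }
    }
  }
  if (den == 0) return(list(value = NA_real_, coverage = 0))
  list(value = num / den, coverage = min(1, den / poly_area))
}

# Even-odd point-in-polygon test.
point_in_ring <- function(x, y, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

#' Aggregate an enhancement grid to block groups
#'
#' @param enh an `nh3_enhancement`
#' @param blockgroups an `nh3_blockgroups`
#' @param method passed to [area_weighted_mean()]
#' @return data frame (class `nh3_bgtable`): one row per block group with
#'   `delta` (area-weighted mean enhancement, NA if none), `has_enhancement`
#'   and `coverage`
#' @export
aggregate_blockgroups <- function(enh, blockgroups,
                                  method = c("intersection", "centers")) {
  method <- match.arg(method)
  polys <- blockgroup_polygons(blockgroups)
  res <- lapply(polys, function(p) area_weighted_mean(enh, p, method = method))
  out <- data.frame(
    blockgroup_id = blockgroups$id,
    delta = vapply(res, `[[`, numeric(1), "value"),
    coverage = vapply(res, `[[`, numeric(1), "coverage"),
    stringsAsFactors = FALSE)
  out$has_enhancement <- !is.na(out$delta) & out$coverage > 0
  class(out) <- c("nh3_bgtable", "data.frame")
  out
}

#' Block groups eligible for a group's population-weighted mean
#'
#' A block group is eligible for a group when the group's population share
#' there is at or above the unweighted mean share across all block groups in
#' the region. With `basis = "count"` raw group counts are compared to the
#' mean count instead.
#'
#' @param demographics data frame (blockgroup_id, group, population)
#' @param group group label
#' @param basis "share" (default) or "count"
#' @return character vector of eligible block-group ids, with the threshold
#'   in attribute `threshold`
#' @export
eligible_subset <- function(demographics, group, basis = c("share", "count")) {
  basis <- match.arg(basis)
  if (!group %in% demographics$group) stop("unknown group: ", group)
  totals <- tapply(demographics$population, demographics$blockgroup_id, sum)
  d <- demographics[demographics$group == group, ]
  metric <- if (basis == "share") {
    d$population / as.numeric(totals[d$blockgroup_id])
  } else {
    d$population
  }
  thr <- mean(metric)
  # small relative tolerance so block groups exactly at the threshold are
  # kept regardless of floating-point summation order
  out <- d$blockgroup_id[metric >= thr - 1e-9 * max(1, abs(thr))]
  attr(out, "threshold") <- thr
  out
}

#' Population-weighted mean enhancement for a group
#'
#' `xbar_w = sum(p_i x_i) / sum(p_i)` over the block groups i of `subset`
#' that carry an enhancement, with p_i the group's population there. The
#' uncertainty is the weighted standard mean error
#' `sqrt(sum(w_i^2 (x_i - xbar_w)^2))` with `w_i = p_i / sum(p)`.
#'
#' @param table an `nh3_bgtable`
#' @param demographics demographic long table
#' @param group group label
#' @param subset block-group ids to use (default: the group's
#'   [eligible_subset()])
#' @return list with `mean`, `sem`, `n_bg` (block groups used), `total_pop`
#' @export
population_weighted_mean <- function(table, demographics, group,
                                     subset = NULL) {
  if (is.null(subset)) subset <- eligible_subset(demographics, group)
  d <- demographics[demographics$group == group &
                      demographics$blockgroup_id %in% subset, ]
  m <- merge(d, as.data.frame(table), by = "blockgroup_id")
  m <- m[m$has_enhancement, ]
  if (nrow(m) == 0L || sum(m$population) == 0)
    stop("no populated block groups with enhancements for group: ", group)
  w <- m$population / sum(m$population)
  xbar <- sum(w * m$delta)
  list(mean = xbar,
       sem = sqrt(sum(w^2 * (m$delta - xbar)^2)),
       n_bg = nrow(m),
       total_pop = sum(m$population))
}

#' Absolute and relative inequality for a group versus a reference
#'
#' `absolute = pw(group) - pw(reference)` over each group's own eligible
#' block groups; `relative = 100 * absolute / pw(reference)` (percent).
#' `sem_abs` combines the two weighted standard mean errors in quadrature;
#' `sem_rel` propagates it onto the percent scale.
#'
#' @param table an `nh3_bgtable`
#' @param demographics demographic long table
#' @param group,reference group labels
#' @param subset_group,subset_ref optional explicit block-group id subsets
#'   (default: each group's [eligible_subset()])
#' @return an `nh3_inequality` list: group, reference, the two
#'   population-weighted means, absolute, relative (NA when the reference
#'   mean is not positive), sem_abs, sem_rel, block-group counts
#' @export
compute_inequality <- function(table, demographics, group, reference,
                               subset_group = NULL, subset_ref = NULL) {
  pg <- population_weighted_mean(table, demographics, group, subset_group)
  pr <- population_weighted_mean(table, demographics, reference, subset_ref)
  absolute <- pg$mean - pr$mean
  sem_abs <- sqrt(pg$sem^2 + pr$sem^2)
  if (pr$mean > 0) {
    relative <- 100 * absolute / pr$mean
    sem_rel <- 100 * sem_abs / pr$mean
  } else {
    relative <- NA_real_
    sem_rel <- NA_real_
    warning("reference population-weighted mean is not positive; ",
            "relative inequality undefined")
  }
  structure(list(group = group, reference = reference,
                 pw_mean_group = pg$mean, pw_mean_ref = pr$mean,
                 absolute = absolute, relative = relative,
                 sem_abs = sem_abs, sem_rel = sem_rel,
                 n_bg_group = pg$n_bg, n_bg_ref = pr$n_bg),
            class = "nh3_inequality")
}

#' @export
print.nh3_inequality <- function(x, ...) {
  cat(sprintf("<nh3_inequality> %s vs %s: %+.3g (%.1f%%), sem_abs %.2g\n",
              x$group, x$reference, x$absolute,
              if (is.na(x$relative)) NaN else x$relative, x$sem_abs))
  invisible(x)
}

#' Inequality table for several groups
#'
#' @inheritParams compute_inequality
#' @param groups group labels (default: all non-reference groups present)
#' @return data frame with one row per group
#' @export
inequality_table <- function(table, demographics, groups = NULL, reference) {
  if (is.null(groups))
    groups <- setdiff(unique(demographics$group), reference)
  do.call(rbind, lapply(groups, function(g) {
    r <- compute_inequality(table, demographics, g, reference)
    data.frame(group = g, reference = reference,
               pw_mean_group = r$pw_mean_group, pw_mean_ref = r$pw_mean_ref,
               absolute = r$absolute, relative = r$relative,
               sem_abs = r$sem_abs, sem_rel = r$sem_rel,
               n_bg_group = r$n_bg_group, n_bg_ref = r$n_bg_ref,
               stringsAsFactors = FALSE)
  }))
}

#' Decompose multi-period inequality trends into column and composition parts
#'
#' Recomputes per-period inequalities twice, holding demographics at vintage
#' `a` and then at vintage `b`, so changes driven by the evolving column
#' field (rows of one series) can be separated from changes driven by
#' population composition (difference between series at a fixed period).
#'
#' @param tables named list of `nh3_bgtable`, one per period
#' @param demographics_a,demographics_b two demographic vintages over the
#'   same block groups
#' @param groups,reference as in [inequality_table()]
#' @return data frame with one row per (period, vintage, group)
#' @export
decompose_trend <- function(tables, demographics_a, demographics_b,
                            groups = NULL, reference) {
  stopifnot(length(tables) >= 2)
  ids_a <- sort(unique(demographics_a$blockgroup_id))
  ids_b <- sort(unique(demographics_b$blockgroup_id))
  if (!identical(ids_a, ids_b))
    stop("demographic vintages cover different block-group ids")
  periods <- names(tables)
  if (is.null(periods)) periods <- as.character(seq_along(tables))
  out <- list()
  for (p in seq_along(tables)) {
    for (v in c("a", "b")) {
      dem <- if (v == "a") demographics_a else demographics_b
      t <- inequality_table(tables[[p]], dem, groups, reference)
      t$period <- periods[p]
      t$vintage <- v
      out[[length(out) + 1L]] <- t
    }
  }
  do.call(rbind, out)
}
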