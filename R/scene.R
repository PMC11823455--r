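# Synthetic scenes: a known truth field, facilities, block groups and
# demographics with controllable source-proximity structure.
#
# The truth column field is a uniform tropospheric background plus one
# isotropic exponential-decay term per facility,
#   truth(x) = B + sum_f strength_f * exp(-d_f(x) / decay_length),
# a statistical stand-in for the observed decay of enhancements away from
# point sources (no plume physics). Demographic composition is tied to
# source proximity through a softmax (multinomial-logistic) link whose slope
# is the scene's `proximity_bias`, so the inequality the pipeline should
# recover is known by construction and recorded as `designed_inequality`.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of (config, seed).
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for a synthetic scene
#'
#' Defaults describe a ~100 km x 100 km rural region with 100 animal
#' facilities concentrated in a few dense clusters (leaving a genuine
#' far field beyond 20 km), a regional background of 4e15 molecules cm^-2,
#' per-facility source enhancements of 1-4 x 10^15 molecules cm^-2 decaying
#' with a 10 km e-folding length, and four demographic groups whose
#' regional baseline composition approximates 25/10/2/63 percent with the
#' last group as reference.
#'
#' @param region_bounds list with lon_min, lon_max, lat_min, lat_max (degrees)
#' @param n_facilities number of point sources
#' @param facility_cluster_sd within-cluster scatter of facilities (km)
#' @param emission_strength_range c(lo, hi) column enhancement at the source
#'   (molecules cm^-2)
#' @param decay_length_km e-folding distance of each source's enhancement
#' @param background_column uniform background column (molecules cm^-2, >= 0)
#' @param demographic_groups group labels; the last is the reference unless
#'   `reference_group` says otherwise
#' @param reference_group reference group label
#' @param baseline_shares named regional mean shares (sum to 1)
#' @param proximity_bias slope (>= 0) of the softmax link tying non-reference
#'   group shares to the proximity covariate exp(-d/decay_length); 0 removes
#'   all spatial demographic structure
#' @param blockgroup_grid_n block groups tessellate the bounds as an n x n
#'   grid of rectangles
#' @param total_pop_meanlog,total_pop_sdlog lognormal parameters of
#'   block-group total population
#' @param hot_source_multiplier source-strength factor on hot
#'   (above-median-temperature) days
#' @param calm_decay_multiplier decay-length factor on calm
#'   (at-or-below-median-wind) days
#' @param grid_spacing_deg analysis-grid spacing used when recording the
#'   designed inequality (matches the oversampling default)
#' @param seed integer RNG seed
#' @return validated list of class `nh3_scene_config`
#' @export
scene_config <- function(region_bounds = list(lon_min = -78.5, lon_max = -77.5,
                                              lat_min = 34.5, lat_max = 35.5),
                         n_facilities = 100,
                         facility_cluster_sd = 15,
                         emission_strength_range = c(1e15, 4e15),
                         decay_length_km = 10,
                         background_column = 4e15,
                         demographic_groups = c("black", "hispanic",
                                                "american_indian", "white"),
                         reference_group = "white",
                         baseline_shares = c(black = 0.25, hispanic = 0.10,
                                             american_indian = 0.02,
                                             white = 0.63),
                         proximity_bias = 1,
                         blockgroup_grid_n = 12,
                         total_pop_meanlog = log(1200),
                         total_pop_sdlog = 0.4,
                         hot_source_multiplier = 1.5,
                         calm_decay_multiplier = 1.5,
                         grid_spacing_deg = 0.01,
                         seed = 1L) {
  b <- as.list(region_bounds)
  if (b$lon_max <= b$lon_min || b$lat_max <= b$lat_min)
    stop("degenerate region bounds")
  stopifnot(decay_length_km > 0, background_column >= 0, proximity_bias >= 0,
            n_facilities >= 0, blockgroup_grid_n >= 2,
            length(emission_strength_range) == 2,
            emission_strength_range[1] <= emission_strength_range[2])
  if (n_facilities == 0 && proximity_bias > 0)
    stop("inconsistent config: proximity_bias > 0 requires facilities")
  if (!reference_group %in% demographic_groups)
    stop("reference_group must be one of demographic_groups")
  if (!setequal(names(baseline_shares), demographic_groups))
    stop("baseline_shares must be named by demographic_groups")
  baseline_shares <- baseline_shares[demographic_groups] /
    sum(baseline_shares)
  structure(list(
    region_bounds = b, n_facilities = n_facilities,
    facility_cluster_sd = facility_cluster_sd,
    emission_strength_range = emission_strength_range,
    decay_length_km = decay_length_km,
    background_column = background_column,
    demographic_groups = demographic_groups,
    reference_group = reference_group,
    baseline_shares = baseline_shares,
    proximity_bias = proximity_bias,
    blockgroup_grid_n = as.integer(blockgroup_grid_n),
    total_pop_meanlog = total_pop_meanlog,
    total_pop_sdlog = total_pop_sdlog,
    hot_source_multiplier = hot_source_multiplier,
    calm_decay_multiplier = calm_decay_multiplier,
    grid_spacing_deg = grid_spacing_deg,
    seed = as.integer(seed)
  ), class = "nh3_scene_config")
}

# Truth column field closure over a facility table.
make_truth_field <- function(facilities, background, decay_length_km) {
  function(lat, lon, strength_scale = 1, decay_scale = 1) {
    v <- rep(background, length(lat))
    if (nrow(facilities)) {
      L <- decay_length_km * decay_scale
      for (f in seq_len(nrow(facilities))) {
        d <- haversine_km(lon, lat, facilities$lon[f], facilities$lat[f])
        v <- v + strength_scale * facilities$strength[f] * exp(-d / L)
      }
    }
    v
  }
}

#' Generate a synthetic scene
#'
#' Places clustered facilities inside the bounds, tessellates the bounds into
#' rectangular block groups, draws demographics with the configured proximity
#' bias, builds the truth column field, and records the scene's designed
#' inequality: the relative/absolute gap obtained by running the
#' package's own percentile-background, area-weighting, eligibility and
#' population-weighting machinery directly on the noiseless truth field
#' evaluated at analysis-grid resolution. This is the no-measurement limit a
#' satellite-sampled pipeline run should recover.
#'
#' @param config an [scene_config()]
#' @return an object of class `nh3_scene` with elements `config`,
#'   `facilities` (data frame id/lat/lon/type/strength/allowable_count),
#'   `blockgroups` (an `nh3_blockgroups`), `demographics` (long table),
#'   `truth_field` (function(lat, lon, strength_scale, decay_scale)),
#'   `designed_inequality` (per-group data frame) and `truth_background`
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "nh3_scene_config"))
  b <- config$region_bounds
  with_seed(config$seed, {
    ## facilities: cluster centres uniform in the inner 60% of the bounds,
    ## members scattered around them; rejected draws resampled into bounds
    n <- config$n_facilities
    facilities <- data.frame(id = character(0), lat = numeric(0),
                             lon = numeric(0), type = character(0),
                             strength = numeric(0),
                             allowable_count = integer(0))
    if (n > 0) {
      n_clusters <- max(1L, round(n / 5))
      shrink <- 0.2
      c_lat <- stats::runif(n_clusters,
                            b$lat_min + shrink * (b$lat_max - b$lat_min),
                            b$lat_max - shrink * (b$lat_max - b$lat_min))
      c_lon <- stats::runif(n_clusters,
                            b$lon_min + shrink * (b$lon_max - b$lon_min),
                            b$lon_max - shrink * (b$lon_max - b$lon_min))
      assign_cl <- sample.int(n_clusters, n, replace = TRUE)
      lat <- c_lat[assign_cl] +
        stats::rnorm(n, 0, config$facility_cluster_sd) / KM_PER_DEG_LAT
      lon <- c_lon[assign_cl] +
        stats::rnorm(n, 0, config$facility_cluster_sd) /
        km_per_deg_lon(mean(c(b$lat_min, b$lat_max)))
      lat <- pmin(pmax(lat, b$lat_min), b$lat_max)
      lon <- pmin(pmax(lon, b$lon_min), b$lon_max)
      facilities <- data.frame(
        id = sprintf("fac_%03d", seq_len(n)),
        lat = lat, lon = lon, type = "swine",
        strength = stats::runif(n, config$emission_strength_range[1],
                                config$emission_strength_range[2]),
        allowable_count = as.integer(round(stats::runif(n, 1000, 20000))),
        stringsAsFactors = FALSE)
    }

    ## block groups: n x n rectangular tessellation of the bounds
    ng <- config$blockgroup_grid_n
    lon_edges <- seq(b$lon_min, b$lon_max, length.out = ng + 1L)
    lat_edges <- seq(b$lat_min, b$lat_max, length.out = ng + 1L)
    ids <- character(0); polys <- list()
    for (i in seq_len(ng)) for (j in seq_len(ng)) {
      ids <- c(ids, sprintf("bg_%02d_%02d", i, j))
      polys[[length(polys) + 1L]] <-
        rect_ring(lon_edges[j], lon_edges[j + 1L],
                  lat_edges[i], lat_edges[i + 1L])
    }
    blockgroups <- blockgroup_set(ids, polys)

    ## demographics: softmax link on the proximity covariate z = exp(-d/L)
    if (nrow(facilities)) {
      dists <- nearest_facility_distance(
        data.frame(id = blockgroups$id, lat = blockgroups$center_lat,
                   lon = blockgroups$center_lon),
        facilities, type_filter = "swine")
      z <- exp(-dists / config$decay_length_km)
    } else {
      z <- rep(0, nrow(blockgroups))
    }
    groups <- config$demographic_groups
    eta <- sapply(groups, function(g) {
      base <- log(config$baseline_shares[[g]])
      if (g == config$reference_group) rep(base, length(z))
      else base + config$proximity_bias * z
    })
    shares <- exp(eta) / rowSums(exp(eta))
    ## populations are expected counts (total x share), not a multinomial
    ## draw: the designed inequality is then an exact functional of the
    ## configuration, and a proximity_bias of 0 yields identical group
    ## weights in every block group (hence exactly zero inequality)
    totals <- pmax(50, round(stats::rlnorm(
      nrow(blockgroups), config$total_pop_meanlog, config$total_pop_sdlog)))
    demographics <- do.call(rbind, lapply(seq_len(nrow(blockgroups)), function(i) {
      data.frame(blockgroup_id = blockgroups$id[i], group = groups,
                 population = totals[i] * shares[i, ],
                 stringsAsFactors = FALSE)
    }))

    truth_field <- make_truth_field(facilities, config$background_column,
                                    config$decay_length_km)

    ## designed inequality: percentile background + area weighting +
    ## eq-S1 population weighting applied to the noiseless truth field
    gs <- grid_spec_for_bounds(b, config$grid_spacing_deg)
    truth_vals <- outer(gs$lat, gs$lon,
                        function(la, lo) truth_field(la, lo))
    truth_bg <- unname(stats::quantile(truth_vals, 0.10, type = 7))
    enhanced <- truth_vals > truth_bg
    delta <- truth_vals - truth_bg
    delta[!enhanced] <- NA_real_
    truth_enh <- structure(list(delta = delta, enhanced = enhanced,
                                background = truth_bg, grid = gs,
                                source_k = NA),
                           class = "nh3_enhancement")
    non_ref <- setdiff(groups, config$reference_group)
    if (any(enhanced)) {
      truth_tab <- aggregate_blockgroups(truth_enh, blockgroups)
      designed <- inequality_table(truth_tab, demographics,
                                   reference = config$reference_group)
    } else {
      # uniform truth field (e.g. no facilities): no enhancements anywhere,
      # so the designed gap is identically zero
      designed <- data.frame(group = non_ref,
                             reference = config$reference_group,
                             pw_mean_group = 0, pw_mean_ref = 0,
                             absolute = 0, relative = 0,
                             sem_abs = 0, sem_rel = 0,
                             n_bg_group = 0L, n_bg_ref = 0L,
                             stringsAsFactors = FALSE)
    }
    if (any(!is.finite(designed$relative)))
      stop("designed inequality is not finite; check scene configuration")

    structure(list(config = config, facilities = facilities,
                   blockgroups = blockgroups, demographics = demographics,
                   truth_field = truth_field,
                   truth_background = truth_bg,
                   designed_inequality = designed),
              class = "nh3_scene")
  })
}

#' @export
print.nh3_scene <- function(x, ...) {
  cat(sprintf("<nh3_scene> %d facilities, %d block groups, %d groups (ref %s)\n",
              nrow(x$facilities), nrow(x$blockgroups),
              length(x$config$demographic_groups), x$config$reference_group))
  cat("designed relative inequality (%):\n")
  print(stats::setNames(round(x$designed_inequality$relative, 2),
                        x$designed_inequality$group))
  invisible(x)
}
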