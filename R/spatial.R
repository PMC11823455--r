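# Meteorological stratification and facility-distance analyses.
#
# Days are split at the median of morning wind speed (calm/windy) or morning
# air temperature (cool/hot). Block-group enhancements are profiled against
# distance to the nearest permitted swine facility; the downfield spatial
# extent is where the binned mean signal drops below twice a far-field
# (15-20 km) noise level.

#' Median-split stratification of meteorological days
#'
#' Days at or below the median of the chosen morning variable go to the
#' lower stratum (calm / cool), days above it to the upper stratum
#' (windy / hot). The tie rule (at-median days join the lower stratum) is
#' fixed so that strata always partition the labelled days.
#'
#' @param met data frame with columns `date`, `morning_wind`, `morning_temp`
#' @param variable "wind" or "temp"
#' @return data frame (date, value, stratum) of class `nh3_strata`, with the
#'   median in attribute `median`; stratum labels are calm/windy for wind and
#'   cool/hot for temperature
#' @export
median_split <- function(met, variable = c("wind", "temp")) {
  variable <- match.arg(variable)
  v <- if (variable == "wind") met$morning_wind else met$morning_temp
  if (length(v) < 2L) stop("need at least 2 days for a median split")
  if (length(unique(v)) < 2L)
    stop("all values identical; median split is degenerate")
  med <- stats::median(v)
  labs <- if (variable == "wind") c("calm", "windy") else c("cool", "hot")
  out <- data.frame(date = met$date, value = v,
                    stratum = ifelse(v <= med, labs[1], labs[2]),
                    stringsAsFactors = FALSE)
  attr(out, "median") <- med
  class(out) <- c("nh3_strata", "data.frame")
  out
}

#' Distance from points to the nearest facility of a given type
#'
#' Haversine (great-circle) minimum over the filtered facility set.
#'
#' @param points data frame with columns `id`, `lat`, `lon` (e.g. block-group
#'   centre points)
#' @param facilities data frame with columns `id`, `lat`, `lon`, `type`
#' @param type_filter facility type to keep (default "swine"); NULL keeps all
#' @return named numeric vector of distances in km, one per point id
#' @export
nearest_facility_distance <- function(points, facilities, type_filter = "swine") {
  f <- facilities
  if (!is.null(type_filter)) f <- f[f$type == type_filter, , drop = FALSE]
  if (nrow(f) == 0L) stop("no facilities after type filter")
  d <- vapply(seq_len(nrow(points)), function(i) {
    min(haversine_km(points$lon[i], points$lat[i], f$lon, f$lat))
  }, numeric(1))
  names(d) <- points$id
  d
}

#' Binned enhancement profile against distance to the nearest facility
#'
#' Block-group enhancements are averaged in half-open distance bins
#' `[lo, hi)` of width `bin_width_km`; the first bin `[0, 1)` km is the
#' at-facility bin. Per-bin uncertainty is the standard mean error. The noise
#' floor is defined as twice the standard deviation of block-group
#' enhancements at far-field distances (15-20 km by default), where facility
#' influence is assumed negligible.
#'
#' @param bg_table an `nh3_bgtable`
#' @param distances named km vector from [nearest_facility_distance()]
#'   (names are block-group ids)
#' @param bin_width_km bin width in km (default 1)
#' @param max_km outer edge of the last bin (default 20)
#' @param noise_band two-element km range defining the far-field noise band
#' @param noise_2sigma externally supplied noise level. Stratified profiles
#'   pass the all-days value here, so that every stratum is judged against
#'   one common noise floor; the default (NULL) computes it from this
#'   table's own noise band.
#' @return an `nh3_profile`: data frame (bin_lo, bin_hi, mean, sem, n) with
#'   attributes `noise_2sigma` and `extent_km`
#' @export
distance_profile <- function(bg_table, distances, bin_width_km = 1,
                             max_km = 20, noise_band = c(15, 20),
                             noise_2sigma = NULL) {
  stopifnot(bin_width_km > 0)
  t <- as.data.frame(bg_table)
  t <- t[t$has_enhancement, ]
  t$dist <- as.numeric(distances[t$blockgroup_id])
  t <- t[!is.na(t$dist), ]
  if (is.null(noise_2sigma)) {
    in_band <- t$dist >= noise_band[1] & t$dist < noise_band[2]
    if (sum(in_band) < 2L)
      stop("fewer than 2 block groups in the ", noise_band[1], "-",
           noise_band[2], " km noise band; noise level undefined")
    noise_2sigma <- 2 * stats::sd(t$delta[in_band])
  }

  edges <- seq(0, max_km, by = bin_width_km)
  prof <- do.call(rbind, lapply(seq_len(length(edges) - 1L), function(b) {
    sel <- t$dist >= edges[b] & t$dist < edges[b + 1L]
    n <- sum(sel)
    data.frame(bin_lo = edges[b], bin_hi = edges[b + 1L],
               mean = if (n) mean(t$delta[sel]) else NA_real_,
               sem = if (n > 1) stats::sd(t$delta[sel]) / sqrt(n) else
                 if (n == 1) 0 else NA_real_,
               n = n)
  }))
  class(prof) <- c("nh3_profile", "data.frame")
  attr(prof, "noise_2sigma") <- noise_2sigma
  attr(prof, "extent_km") <- spatial_extent(prof)
  prof
}

#' Downfield spatial extent of the enhancement signal
#'
#' Scans outward from the first bin and returns the outer edge of the last
#' bin in the contiguous-from-source run whose mean is at least
#' `snr` times the far-field noise level (`noise_2sigma`). Returns 0 when
#' the first bin already fails.
#'
#' @param profile an `nh3_profile` (or data frame with bin_lo/bin_hi/mean)
#' @param noise_2sigma noise level; default taken from the profile attribute
#' @param snr required signal-to-noise ratio (default 2)
#' @return extent in km
#' @export
spatial_extent <- function(profile, noise_2sigma = NULL, snr = 2) {
  if (is.null(noise_2sigma)) noise_2sigma <- attr(profile, "noise_2sigma")
  if (is.null(noise_2sigma) || !is.finite(noise_2sigma) || noise_2sigma <= 0)
    stop("noise_2sigma must be a positive number")
  ext <- 0
  for (b in seq_len(nrow(profile))) {
    m <- profile$mean[b]
    if (is.na(m) || m < snr * noise_2sigma) break
    ext <- profile$bin_hi[b]
  }
  ext
}

#' Population-weighted distance to the nearest facility for a group
#'
#' `sum(p_i d_i) / sum(p_i)` over the group's eligible block groups (same
#' eligibility rule as the inequality metrics).
#'
#' @param distances named km vector (names are block-group ids)
#' @param demographics demographic long table
#' @param group group label
#' @param subset block-group ids (default: the group's [eligible_subset()])
#' @return distance in km
#' @export
population_weighted_distance <- function(distances, demographics, group,
                                         subset = NULL) {
  if (is.null(subset)) subset <- eligible_subset(demographics, group)
  d <- demographics[demographics$group == group &
                      demographics$blockgroup_id %in% subset, ]
  d$dist <- as.numeric(distances[d$blockgroup_id])
  d <- d[!is.na(d$dist), ]
  if (nrow(d) == 0L || sum(d$population) == 0)
    stop("no populated eligible block groups with distances for group: ", group)
  sum(d$population * d$dist) / sum(d$population)
}
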