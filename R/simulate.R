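# Simulated meteorology and Level-2-like satellite soundings over a scene.

#' Generate synthetic station meteorology
#'
#' Morning (8 am-12 pm LT) wind speeds are lognormal with mean `wind_mean`
#' (default 3 m s^-1, a typical warm-season regional value); morning air
#' temperatures are normal with mean `temp_mean` (default 24 C); daily
#' precipitation is exponential with mean `precip_mean` mm. All draws are
#' reproducible under `seed`.
#'
#' @param n_days number of days (>= 2; a later median split needs variation)
#' @param seed integer RNG seed
#' @param start_date first calendar day
#' @param wind_mean,wind_sdlog lognormal mean (m s^-1) and log-sd of wind
#' @param temp_mean,temp_sd normal mean and sd of temperature (degrees C)
#' @param precip_mean mean daily precipitation (mm)
#' @param constant if TRUE every day receives identical values (a degenerate
#'   record useful for exercising downstream error paths)
#' @return data frame (date, morning_wind, morning_temp, daily_precip)
#' @export
generate_meteorology <- function(n_days, seed = 1L,
                                 start_date = as.Date("2016-04-01"),
                                 wind_mean = 3, wind_sdlog = 0.45,
                                 temp_mean = 24, temp_sd = 4,
                                 precip_mean = 0.14,
                                 constant = FALSE) {
  if (n_days < 2) stop("n_days must be >= 2 (median split undefined otherwise)")
  with_seed(seed, {
    if (constant) {
      wind <- rep(wind_mean, n_days)
      temp <- rep(temp_mean, n_days)
      precip <- rep(precip_mean, n_days)
    } else {
      # meanlog chosen so E[wind] = wind_mean exactly
      wind <- stats::rlnorm(n_days, log(wind_mean) - wind_sdlog^2 / 2,
                            wind_sdlog)
      temp <- stats::rnorm(n_days, temp_mean, temp_sd)
      precip <- stats::rexp(n_days, 1 / precip_mean)
    }
    data.frame(date = start_date + seq_len(n_days) - 1L,
               morning_wind = wind, morning_temp = temp,
               daily_precip = precip)
  })
}

# Fixed quadrature for footprint-averaging the truth field: a 5x5 lattice
# over the ellipse's bounding box in the rotated frame, weighted by the
# sharp-edged (k = 18) footprint response.
FOOTPRINT_QUAD <- local({
  u <- seq(-0.8, 0.8, by = 0.4)
  g <- expand.grid(u = u, v = u)
  w <- exp(-log(2) * (abs(g$u)^18 + abs(g$v)^18))
  list(u = g$u, v = g$v, w = w / sum(w))
})

#' Simulate Level-2-like satellite pixels over a scene
#'
#' For each meteorological day, `pixels_per_day` soundings are placed
#' uniformly in the scene bounds with elliptical footprints (12 km diameter
#' at nadir, elongated off-nadir with a random orientation). Each pixel's
#' column is the footprint-averaged truth field times `(1 + e)`,
#' `e ~ N(0, noise_cv)`; its 1-sigma uncertainty is
#' `max(noise_cv, 0.001) x` the footprint-averaged truth (so noise-free runs
#' still carry positive, equal-information uncertainties). Random cloud
#' fractions and sensitivity flags emulate the Level-2 quality fields.
#'
#' Per-day truth modulation gives the meteorological strata a known signal:
#' on hot days (morning temperature above the record's median) source
#' strengths are multiplied by the scene's `hot_source_multiplier`; on calm
#' days (wind at or below the median) the decay length is multiplied by
#' `calm_decay_multiplier`, so enhancements reach farther downfield when
#' dilution is weak.
#'
#' @param scene an `nh3_scene`
#' @param met meteorology data frame from [generate_meteorology()]
#' @param pixels_per_day soundings per day
#' @param noise_cv coefficient of variation of multiplicative retrieval
#'   noise (>= 0)
#' @param seed integer RNG seed
#' @param platform platform label stamped on every pixel
#' @return data frame of pixels: time, lat, lon, semi_major_km,
#'   semi_minor_km, orientation_deg, column, uncertainty, cloud_fraction,
#'   sensitivity_ok, platform
#' @export
simulate_columns <- function(scene, met, pixels_per_day = 200,
                             noise_cv = 0.1, seed = 1L, platform = "A") {
  stopifnot(inherits(scene, "nh3_scene"), noise_cv >= 0, pixels_per_day >= 1)
  if (is.null(met) || nrow(met) == 0L) stop("met record list is empty")
  b <- scene$config$region_bounds
  med_wind <- stats::median(met$morning_wind)
  med_temp <- stats::median(met$morning_temp)
  q <- FOOTPRINT_QUAD
  with_seed(seed, {
    days <- lapply(seq_len(nrow(met)), function(d) {
      strength_scale <- if (met$morning_temp[d] > med_temp)
        scene$config$hot_source_multiplier else 1
      decay_scale <- if (met$morning_wind[d] <= med_wind)
        scene$config$calm_decay_multiplier else 1

      np <- pixels_per_day
      lat <- stats::runif(np, b$lat_min, b$lat_max)
      lon <- stats::runif(np, b$lon_min, b$lon_max)
      u <- stats::runif(np)                      # off-nadir position in [0,1]
      semi_major <- 6 * (1 + 1.2 * u^2)
      semi_minor <- 6 * (1 + 0.3 * u^2)
      orient <- stats::runif(np, 0, 180)

      # footprint-averaged truth via the fixed rotated-frame quadrature
      th <- orient * pi / 180
      nq <- length(q$u)
      dx <- outer(semi_major, q$u)               # np x nq, along major axis
      dy <- outer(semi_minor, q$v)
      de <- dx * sin(th) + dy * cos(th)
      dn <- dx * cos(th) - dy * sin(th)
      plat <- lat + dn / KM_PER_DEG_LAT
      plon <- lon + de / (km_per_deg_lon(lat) %o% rep(1, nq))
      tv <- scene$truth_field(as.vector(plat), as.vector(plon),
                              strength_scale = strength_scale,
                              decay_scale = decay_scale)
      truth_avg <- as.vector(matrix(tv, np, nq) %*% q$w)

      col <- truth_avg * (1 + stats::rnorm(np, 0, noise_cv))
      data.frame(time = met$date[d], lat = lat, lon = lon,
                 semi_major_km = semi_major, semi_minor_km = semi_minor,
                 orientation_deg = orient,
                 column = col,
                 uncertainty = pmax(noise_cv, 1e-3) * truth_avg,
                 cloud_fraction = stats::rbeta(np, 1, 9),
                 sensitivity_ok = stats::runif(np) < 0.9,
                 platform = platform,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, days)
  })
}
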