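# Shared fixtures and independent oracles, built in code at test time.

# Small, fast scene configuration: ~33 km square region, 6x6 block groups.
tiny_scene_config <- function(...) {
  defaults <- list(
    region_bounds = list(lon_min = -78.3, lon_max = -78.0,
                         lat_min = 34.8, lat_max = 35.1),
    n_facilities = 10,
    facility_cluster_sd = 5,
    blockgroup_grid_n = 6,
    seed = 42L)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_config, args)
}

# Build an nh3_grid by hand (all cells valid, unit weight).
manual_grid <- function(values, lat0 = 35, lon0 = -78, spacing = 0.01) {
  values <- as.matrix(values)
  gs <- grid_spec(lat0, lon0, spacing, nrow(values), ncol(values))
  structure(list(values = values,
                 total_weight = matrix(1, nrow(values), ncol(values)),
                 n_contrib = matrix(1L, nrow(values), ncol(values)),
                 valid = matrix(TRUE, nrow(values), ncol(values)),
                 grid = gs, k = 2, weight_threshold = 0,
                 support_cutoff = 1e-4),
            class = "nh3_grid")
}

# Build an nh3_enhancement directly from a delta matrix (NA = not enhanced).
manual_enhancement <- function(delta, lat0 = 35, lon0 = -78, spacing = 0.01,
                               background = 0) {
  delta <- as.matrix(delta)
  gs <- grid_spec(lat0, lon0, spacing, nrow(delta), ncol(delta))
  structure(list(delta = delta, enhanced = !is.na(delta),
                 background = background, grid = gs, source_k = 2),
            class = "nh3_enhancement")
}

# Random well-formed pixel table over a small domain.
random_pixels <- function(n, seed, lat_c = 35, lon_c = -78, spread = 0.15) {
  set.seed(seed)
  data.frame(
    time = as.Date("2016-05-01") + sample(0:9, n, replace = TRUE),
    lat = runif(n, lat_c - spread, lat_c + spread),
    lon = runif(n, lon_c - spread, lon_c + spread),
    semi_major_km = runif(n, 6, 14),
    semi_minor_km = runif(n, 6, 8),
    orientation_deg = runif(n, 0, 180),
    column = runif(n, 1e15, 3e16),
    uncertainty = runif(n, 5e14, 3e15),
    cloud_fraction = runif(n),
    sensitivity_ok = runif(n) < 0.8,
    platform = "A",
    stringsAsFactors = FALSE)
}

# Independent brute-force oversampling oracle: plain double loop over cells
# and pixels, sharing only the published geometric conventions.
brute_oversample <- function(pixels, grid, k, support_cutoff = 1e-4) {
  r_earth <- 6371.0088
  km_lat <- r_earth * pi / 180
  num <- matrix(0, grid$n_lat, grid$n_lon)
  den <- matrix(0, grid$n_lat, grid$n_lon)
  for (i in seq_len(grid$n_lat)) {
    for (j in seq_len(grid$n_lon)) {
      for (p in seq_len(nrow(pixels))) {
        de <- (grid$lon[j] - pixels$lon[p]) * km_lat *
          cos(pixels$lat[p] * pi / 180)
        dn <- (grid$lat[i] - pixels$lat[p]) * km_lat
        th <- pixels$orientation_deg[p] * pi / 180
        dx <- de * sin(th) + dn * cos(th)
        dy <- de * cos(th) - dn * sin(th)
        s <- exp(-log(2) * (abs(dx / pixels$semi_major_km[p])^k +
                              abs(dy / pixels$semi_minor_km[p])^k))
        if (s < support_cutoff) next
        w <- s / pixels$uncertainty[p]^2
        num[i, j] <- num[i, j] + w * pixels$column[p]
        den[i, j] <- den[i, j] + w
      }
    }
  }
  list(values = ifelse(den > 0, num / den, NA_real_), total_weight = den)
}

# Independent percentile oracle: sort and interpolate linearly between the
# two closest order statistics.
sort_interp_pctl <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# Independent great-circle oracle (spherical law of cosines).
slc_distance_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  6371.0088 * acos(pmin(1, sin(lat1 * r) * sin(lat2 * r) +
                          cos(lat1 * r) * cos(lat2 * r) *
                          cos((lon2 - lon1) * r)))
}

# Axis-aligned rectangular polygon ring.
rect_poly <- function(lon_min, lon_max, lat_min, lat_max) {
  cbind(lon = c(lon_min, lon_max, lon_max, lon_min),
        lat = c(lat_min, lat_min, lat_max, lat_max))
}
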