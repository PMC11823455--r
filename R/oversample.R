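# Oversampling of irregular elliptical satellite footprints onto a regular
# lat/lon grid.
#
# Each Level-2 sounding is an ellipse (semi-axes in km, major-axis azimuth in
# degrees from north). Its spatial response is a generalized Gaussian
#   S(dx, dy) = exp(-ln2 * (|dx/a|^k + |dy/b|^k))
# in the footprint's rotated frame, normalised so S = 1 at the centre and
# S = 0.5 at the footprint edge along each principal axis (half-max at edge:
# the response FWHM equals the footprint diameter). k = 2 is the smooth
# standard-Gaussian representation; k ~ 18 approximates the sharp-edged
# instrument response; k -> Inf is a top-hat.
#
# Grid-cell values are inverse-variance weighted means over all contributing
# pixels, with per-cell weight S_ij / sigma_i^2.

#' Define a regular lat/lon analysis grid
#'
#' Cells are squares of `spacing_deg` on a side; `lat0`/`lon0` are the centre
#' of the lower-left cell. The default spacing of 0.01 degrees (~1 km) is much
#' finer than a nominal 12 km footprint, which is what makes oversampling
#' informative.
#'
#' @param lat0,lon0 centre of the lower-left cell, decimal degrees
#' @param spacing_deg cell size in degrees (> 0)
#' @param n_lat,n_lon number of rows / columns (>= 1)
#' @return an object of class `nh3_gridspec`
#' @export
#' @examples
#' grid_spec(35, -78.5, 0.01, 50, 50)
grid_spec <- function(lat0, lon0, spacing_deg = 0.01, n_lat, n_lon) {
  stopifnot(spacing_deg > 0, n_lat >= 1, n_lon >= 1)
  structure(list(
    lat0 = lat0, lon0 = lon0, spacing_deg = spacing_deg,
    n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
    lat = lat0 + spacing_deg * (seq_len(n_lat) - 1L),
    lon = lon0 + spacing_deg * (seq_len(n_lon) - 1L)
  ), class = "nh3_gridspec")
}

#' Grid spec covering a lat/lon rectangle
#' @param bounds list or vector with lon_min, lon_max, lat_min, lat_max
#' @param spacing_deg cell size in degrees
#' @return an `nh3_gridspec` whose cells tile the bounds
#' @export
grid_spec_for_bounds <- function(bounds, spacing_deg = 0.01) {
  b <- as.list(bounds)
  n_lat <- max(1L, ceiling((b$lat_max - b$lat_min) / spacing_deg))
  n_lon <- max(1L, ceiling((b$lon_max - b$lon_min) / spacing_deg))
  grid_spec(b$lat_min + spacing_deg / 2, b$lon_min + spacing_deg / 2,
            spacing_deg, n_lat, n_lon)
}

#' Quality-control postfilter for Level-2 pixels
#'
#' Retains pixels with cloud fraction at or below `max_cloud` and a passing
#' retrieval-sensitivity flag (low thermal contrast degrades infrared
#' retrievals and such soundings are excluded). The threshold default is a
#' package choice; set `max_cloud = 1` to keep all cloud states.
#'
#' @param pixels data frame of pixels (see [simulate_columns()] for schema)
#' @param max_cloud maximum allowed cloud fraction in `[0, 1]`
#' @return the retained subset, with attribute `n_removed`
#' @export
filter_pixels <- function(pixels, max_cloud = 0.1) {
  stopifnot(is.data.frame(pixels), max_cloud >= 0, max_cloud <= 1)
  keep <- pixels$cloud_fraction <= max_cloud & pixels$sensitivity_ok
  out <- pixels[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("postfilter removed every pixel")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Generalized-Gaussian footprint spatial response
#'
#' `S = exp(-ln2 * (|dx/a|^k + |dy/b|^k))` with `a`, `b` the footprint
#' semi-axes. By construction `S = 1` at the centre and `S = 0.5` at the
#' footprint edge along each principal axis, for any exponent `k >= 1`.
#'
#' @param dx_km,dy_km offsets along the major / minor axes (km); vectorised
#' @param semi_major_km,semi_minor_km footprint semi-axes (km, > 0)
#' @param k response exponent (2 = Gaussian, ~18 = super-Gaussian)
#' @return response weights in `(0, 1]`
#' @export
#' @examples
#' spatial_response(0, 0, 6, 6, k = 2)    # 1
#' spatial_response(6, 0, 6, 6, k = 18)   # 0.5 at the edge for any k
spatial_response <- function(dx_km, dy_km, semi_major_km, semi_minor_km, k = 2) {
  if (any(semi_major_km <= 0) || any(semi_minor_km <= 0))
    stop("footprint semi-axes must be positive")
  stopifnot(k >= 1)
  exp(-log(2) * (abs(dx_km / semi_major_km)^k + abs(dy_km / semi_minor_km)^k))
}

# Radius (in units of the semi-axis) beyond which S < cutoff along an axis.
support_radius_factor <- function(k, cutoff) (log(1 / cutoff) / log(2))^(1 / k)

#' Oversample pixels onto a regular grid
#'
#' Computes, for every grid cell j, the uncertainty-and-response weighted mean
#' column `sum_i(S_ij C_i / sigma_i^2) / sum_i(S_ij / sigma_i^2)` over all
#' pixels i whose footprint response at the cell centre exceeds
#' `support_cutoff`. Cells whose accumulated weight falls below
#' `weight_threshold` are marked invalid. Offsets between cell centres and
#' pixel centres are evaluated in km in each pixel's rotated frame using
#' equirectangular scaling at the pixel latitude (sub-metre error at footprint
#' scale).
#'
#' @param pixels data frame with columns `lat`, `lon`, `semi_major_km`,
#'   `semi_minor_km`, `orientation_deg` (major-axis azimuth, degrees clockwise
#'   from north), `column`, `uncertainty`
#' @param grid an [grid_spec()] object
#' @param k response exponent (2 or ~18)
#' @param weight_threshold minimum accumulated weight for a valid cell. The
#'   default (`NULL`) requires the weight equivalent of one pixel observed at
#'   half response, `0.5 / median(sigma)^2`.
#' @param support_cutoff response level below which a pixel's influence is
#'   truncated (bounds cost; default 1e-4)
#' @return an object of class `nh3_grid` with matrices `values`,
#'   `total_weight`, `n_contrib`, `valid` (rows = latitudes, columns =
#'   longitudes), the grid spec and the exponent used
#' @export
oversample <- function(pixels, grid, k = 2, weight_threshold = NULL,
                       support_cutoff = 1e-4) {
  stopifnot(inherits(grid, "nh3_gridspec"), k >= 1, support_cutoff > 0)
  num <- matrix(0, grid$n_lat, grid$n_lon)
  den <- matrix(0, grid$n_lat, grid$n_lon)
  cnt <- matrix(0L, grid$n_lat, grid$n_lon)

  if (nrow(pixels) == 0L) {
    warning("no pixels to oversample; all cells invalid")
  } else {
    if (any(pixels$uncertainty <= 0)) stop("pixel uncertainties must be positive")
    rf <- support_radius_factor(k, support_cutoff)
    lat <- grid$lat; lon <- grid$lon; sp <- grid$spacing_deg
    for (i in seq_len(nrow(pixels))) {
      p <- pixels[i, ]
      # bounding box of the truncated support, in degrees; the support set
      # {|dx/a|^k + |dy/b|^k <= log2(1/cutoff)} lies in the rotated rectangle
      # [-rf*a, rf*a] x [-rf*b, rf*b], so its circumscribed circle has
      # radius rf*sqrt(a^2+b^2) for any orientation
      r_km <- rf * sqrt(p$semi_major_km^2 + p$semi_minor_km^2)
      dlat <- r_km / KM_PER_DEG_LAT
      dlon <- r_km / km_per_deg_lon(p$lat)
      i0 <- max(1L, ceiling((p$lat - dlat - lat[1]) / sp) + 1L)
      i1 <- min(grid$n_lat, floor((p$lat + dlat - lat[1]) / sp) + 1L)
      j0 <- max(1L, ceiling((p$lon - dlon - lon[1]) / sp) + 1L)
      j1 <- min(grid$n_lon, floor((p$lon + dlon - lon[1]) / sp) + 1L)
      if (i0 > i1 || j0 > j1) next
      ii <- i0:i1; jj <- j0:j1
      de <- rep((lon[jj] - p$lon) * km_per_deg_lon(p$lat), each = length(ii))
      dn <- rep((lat[ii] - p$lat) * KM_PER_DEG_LAT, times = length(jj))
      th <- p$orientation_deg * pi / 180
      dx <- de * sin(th) + dn * cos(th)   # along major axis
      dy <- de * cos(th) - dn * sin(th)   # along minor axis
      s <- spatial_response(dx, dy, p$semi_major_km, p$semi_minor_km, k)
      s[s < support_cutoff] <- 0
      w <- s / p$uncertainty^2
      num[ii, jj] <- num[ii, jj] + w * p$column
      den[ii, jj] <- den[ii, jj] + w
      cnt[ii, jj] <- cnt[ii, jj] + (s > 0)
    }
  }

  if (is.null(weight_threshold)) {
    weight_threshold <- if (nrow(pixels)) 0.5 / stats::median(pixels$uncertainty)^2 else Inf
  }
  valid <- den >= weight_threshold & den > 0
  values <- num / den
  values[!valid] <- NA_real_
  structure(list(values = values, total_weight = den, n_contrib = cnt,
                 valid = valid, grid = grid, k = k,
                 weight_threshold = weight_threshold,
                 support_cutoff = support_cutoff),
            class = "nh3_grid")
}

#' @export
print.nh3_grid <- function(x, ...) {
  cat(sprintf("<nh3_grid> %d x %d cells at %.3f deg, k = %g; %d valid (%.1f%%)\n",
              x$grid$n_lat, x$grid$n_lon, x$grid$spacing_deg, x$k,
              sum(x$valid), 100 * mean(x$valid)))
  if (any(x$valid))
    cat(sprintf("  column range on valid cells: [%.3g, %.3g]\n",
                min(x$values[x$valid]), max(x$values[x$valid])))
  invisible(x)
}
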