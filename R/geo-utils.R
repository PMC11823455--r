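# Local planar geometry on small WGS84 domains.
#
# All polygon work in this package happens on regional (~100 km) scenes, so
# areas and offsets use an equirectangular projection at a local reference
# latitude; great-circle point distances go through geosphere.

# Kilometres per degree of latitude (spherical earth, R = 6371.0088 km).
KM_PER_DEG_LAT <- 6371.0088 * pi / 180

#' Kilometres per degree of longitude at a given latitude
#' @param lat latitude in decimal degrees
#' @return scalar km per degree
#' @keywords internal
km_per_deg_lon <- function(lat) KM_PER_DEG_LAT * cos(lat * pi / 180)

#' Great-circle distance between points (haversine)
#'
#' Vectorised over both arguments; inputs recycle as in [geosphere::distHaversine()].
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees
#' @return distances in kilometres
#' @keywords internal
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371.0088)
}

#' Signed area of a lon/lat polygon ring in km^2
#'
#' Shoelace formula after equirectangular scaling at the ring's mean latitude.
#' Adequate below ~1 degree extent where projection distortion is negligible.
#'
#' @param ring two-column matrix of (lon, lat) vertices, open or closed
#' @return unsigned area in km^2
#' @keywords internal
ring_area_km2 <- function(ring) {
  if (is.null(ring) || nrow(ring) < 3) return(0)
  lat0 <- mean(ring[, 2])
  x <- ring[, 1] * km_per_deg_lon(lat0)
  y <- ring[, 2] * KM_PER_DEG_LAT
  n <- length(x)
  j <- c(n, seq_len(n - 1L))  # previous vertex index (wraps)
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Clip a polygon ring to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of
#' `[xmin, xmax] x [ymin, ymax]`. The subject ring may be convex or concave;
#' the clip region is convex so the result is a single ring (possibly empty).
#'
#' @param ring two-column matrix of (x, y) vertices (not necessarily closed)
#' @param xmin,xmax,ymin,ymax rectangle bounds
#' @return clipped ring matrix (possibly 0 rows)
#' @keywords internal
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_halfplane <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, intersect(prev, cur))
      }
      prev <- cur
      prev_in <- cur_in
    }
    out
  }
  ix <- function(p, q, val, coord) {
    # intersection of segment p-q with the line coord = val
    t <- (val - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  r <- ring
  r <- clip_halfplane(r, function(p) p[1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  r <- clip_halfplane(r, function(p) p[1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  r <- clip_halfplane(r, function(p) p[2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  r <- clip_halfplane(r, function(p) p[2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  r
}

#' Build a rectangular lon/lat ring
#' @keywords internal
rect_ring <- function(lon_min, lon_max, lat_min, lat_max) {
  cbind(lon = c(lon_min, lon_max, lon_max, lon_min),
        lat = c(lat_min, lat_min, lat_max, lat_max))
}

#' Representative point (vertex centroid) of a ring
#' @keywords internal
ring_centroid <- function(ring) c(lon = mean(ring[, 1]), lat = mean(ring[, 2]))
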