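# Readers and writers for the pipeline's plain-text interchange formats:
# pixel/facility/demographic/meteorology CSVs, block-group GeoJSON, and
# background / scene-truth JSON.

#' Write / read a pixel table
#' @param pixels pixel data frame (see [simulate_columns()])
#' @param path CSV path
#' @export
write_pixels_csv <- function(pixels, path) {
  utils::write.csv(pixels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pixels_csv
#' @export
read_pixels_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  p$time <- as.Date(p$time)
  p$sensitivity_ok <- as.logical(p$sensitivity_ok)
  p
}

#' Write / read block-group polygons as GeoJSON (WGS84)
#' @param blockgroups an `nh3_blockgroups`
#' @param path GeoJSON path
#' @export
write_blockgroups_geojson <- function(blockgroups, path) {
  polys <- blockgroup_polygons(blockgroups)
  features <- lapply(blockgroups$id, function(id) {
    ring <- polys[[id]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(id = id),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) unname(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blockgroups_geojson
#' @export
read_blockgroups_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  ids <- character(0); polys <- list()
  for (f in gj$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("lon", "lat")
    ids <- c(ids, f$properties$id)
    polys[[length(polys) + 1L]] <- ring
  }
  blockgroup_set(ids, polys)
}

#' Write / read simple CSV tables (facilities, demographics, meteorology)
#' @param df data frame
#' @param path CSV path
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an oversampled grid in long CSV format
#' @param grid an `nh3_grid`
#' @param path CSV path
#' @export
write_grid_csv <- function(grid, path) {
  g <- grid$grid
  df <- data.frame(
    lat = rep(g$lat, times = g$n_lon),
    lon = rep(g$lon, each = g$n_lat),
    value = as.vector(grid$values),
    total_weight = as.vector(grid$total_weight),
    n_contrib = as.vector(grid$n_contrib),
    valid = as.vector(grid$valid))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a background specification as JSON
#' @param background an `nh3_background`
#' @param path JSON path
#' @export
write_background_json <- function(background, path) {
  jsonlite::write_json(unclass(background), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write scene truth (designed inequality and key parameters) as JSON
#' @param scene an `nh3_scene`
#' @param path JSON path
#' @export
write_scene_truth_json <- function(scene, path) {
  cfg <- scene$config
  jsonlite::write_json(list(
    designed_inequality = scene$designed_inequality,
    truth_background = scene$truth_background,
    parameters = list(
      n_facilities = cfg$n_facilities,
      decay_length_km = cfg$decay_length_km,
      background_column = cfg$background_column,
      proximity_bias = cfg$proximity_bias,
      reference_group = cfg$reference_group,
      seed = cfg$seed)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
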