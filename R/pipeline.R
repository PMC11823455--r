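# End-to-end orchestration: postfilter -> oversample -> background ->
# enhancement -> block-group aggregation -> inequality -> stratification ->
# distance profiles, per period and platform, with stage outputs optionally
# persisted as plain-text files.

#' Build a pipeline run configuration
#'
#' @param periods named list of two-element date vectors (inclusive ranges);
#'   default a single "all" period spanning the meteorology record
#' @param months integer months to keep (e.g. 4:8); NULL keeps all
#' @param platform platform label to keep; NULL keeps all
#' @param k oversampling response exponent
#' @param percentile background percentile
#' @param max_cloud postfilter cloud threshold
#' @param stratify run calm/windy and cool/hot stratified analyses
#' @param grid_spacing_deg analysis-grid spacing in degrees
#' @param bin_width_km distance-profile bin width
#' @param out_dir directory for persisted stage outputs (NULL: in-memory only)
#' @param seed integer seed recorded in the report
#' @return list of class `nh3_run_config`
#' @export
run_config <- function(periods = NULL, months = NULL, platform = NULL,
                       k = 2, percentile = 10, max_cloud = 0.2,
                       stratify = TRUE, grid_spacing_deg = 0.01,
                       bin_width_km = 1, out_dir = NULL, seed = 1L) {
  structure(list(periods = periods, months = months, platform = platform,
                 k = k, percentile = percentile, max_cloud = max_cloud,
                 stratify = stratify, grid_spacing_deg = grid_spacing_deg,
                 bin_width_km = bin_width_km, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "nh3_run_config")
}

subset_period <- function(df, dates, range, months = NULL) {
  keep <- dates >= range[1] & dates <= range[2]
  if (!is.null(months)) keep <- keep & as.integer(format(dates, "%m")) %in% months
  df[keep, , drop = FALSE]
}

#' Run the full analysis over prepared inputs
#'
#' Executes every stage for each configured period: QC postfilter,
#' oversampling at exponent `k`, percentile background, enhancement,
#' area-weighted block-group aggregation, population-weighted inequalities,
#' optional meteorological stratification (stratified oversampling reuses
#' the period's all-days background), and facility-distance profiles with
#' the SNR = 2 spatial extent.
#'
#' @param pixels Level-2-like pixel data frame
#' @param blockgroups an `nh3_blockgroups`
#' @param demographics demographic long table
#' @param facilities facility data frame (id, lat, lon, type)
#' @param met meteorology data frame
#' @param reference reference group label
#' @param config an [run_config()]
#' @return an `nh3_report`: per-period list with `background`, `inequality`,
#'   `profile`, `extent_km`, `pw_distance`, `strata`, plus `config` and the
#'   region bounds
#' @export
run_pipeline <- function(pixels, blockgroups, demographics, facilities, met,
                         reference, config = run_config()) {
  stopifnot(inherits(config, "nh3_run_config"))
  if (!is.null(config$platform))
    pixels <- pixels[pixels$platform == config$platform, , drop = FALSE]
  periods <- config$periods
  if (is.null(periods)) periods <- list(all = range(met$date))

  polys <- blockgroup_polygons(blockgroups)
  all_lon <- unlist(lapply(polys, function(p) p[, 1]))
  all_lat <- unlist(lapply(polys, function(p) p[, 2]))
  bounds <- list(lon_min = min(all_lon), lon_max = max(all_lon),
                 lat_min = min(all_lat), lat_max = max(all_lat))
  gs <- grid_spec_for_bounds(bounds, config$grid_spacing_deg)

  centers <- data.frame(id = blockgroups$id, lat = blockgroups$center_lat,
                        lon = blockgroups$center_lon)
  dists <- nearest_facility_distance(centers, facilities)
  groups <- setdiff(unique(demographics$group), reference)

  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  run_stage_set <- function(px, label, background = NULL, noise_2sigma = NULL) {
    grid <- oversample(px, gs, k = config$k)
    if (is.null(background))
      background <- compute_background(grid, config$percentile,
                                       period_label = label)
    enh <- compute_enhancement(grid, background)
    tab <- aggregate_blockgroups(enh, blockgroups)
    ineq <- inequality_table(tab, demographics, groups, reference)
    prof <- tryCatch(distance_profile(tab, dists, config$bin_width_km,
                                      noise_2sigma = noise_2sigma),
                     error = function(e) NULL)
    if (!is.null(out_dir)) {
      write_grid_csv(grid, file.path(out_dir, paste0("grid_", label, ".csv")))
      write_table_csv(as.data.frame(tab),
                      file.path(out_dir, paste0("blockgroups_", label, ".csv")))
      write_table_csv(ineq,
                      file.path(out_dir, paste0("inequality_", label, ".csv")))
      write_background_json(background,
                            file.path(out_dir, paste0("background_", label, ".json")))
      if (!is.null(prof))
        write_table_csv(cbind(as.data.frame(prof),
                              noise_2sigma = attr(prof, "noise_2sigma"),
                              extent_km = attr(prof, "extent_km")),
                        file.path(out_dir, paste0("profile_", label, ".csv")))
    }
    list(label = label, n_pixels = nrow(px), background = background,
         grid = grid, table = tab, inequality = ineq, profile = prof,
         extent_km = if (!is.null(prof)) attr(prof, "extent_km") else NA_real_)
  }

  report_periods <- list()
  for (pname in names(periods)) {
    rng <- periods[[pname]]
    met_p <- subset_period(met, met$date, rng, config$months)
    px_p <- subset_period(pixels, pixels$time, rng, config$months)
    px_p <- filter_pixels(px_p, config$max_cloud)
    if (nrow(px_p) == 0L) {
      warning("period ", pname, ": no pixels after filtering; skipped")
      next
    }
    alldays <- run_stage_set(px_p, paste0(pname, "_alldays"))

    strata <- list()
    if (config$stratify && nrow(met_p) >= 2) {
      for (variable in c("wind", "temp")) {
        labels <- tryCatch(median_split(met_p, variable),
                           error = function(e) NULL)
        if (is.null(labels)) next
        for (s in unique(labels$stratum)) {
          days <- labels$date[labels$stratum == s]
          px_s <- px_p[px_p$time %in% days, , drop = FALSE]
          if (nrow(px_s) == 0L) next
          # stratified runs share the period's all-days background and the
          # all-days far-field noise floor
          strata[[s]] <- run_stage_set(
            px_s, paste0(pname, "_", s),
            background = alldays$background,
            noise_2sigma = if (!is.null(alldays$profile))
              attr(alldays$profile, "noise_2sigma") else NULL)
        }
      }
    }

    pw_dist <- vapply(c(groups, reference), function(g)
      population_weighted_distance(dists, demographics, g), numeric(1))

    report_periods[[pname]] <- list(
      alldays = alldays, strata = strata, pw_distance = pw_dist,
      n_days = nrow(met_p))
  }

  structure(list(periods = report_periods, config = config, bounds = bounds,
                 distances = dists, reference = reference, groups = groups),
            class = "nh3_report")
}

#' Generate a synthetic scene and run the full pipeline on it
#'
#' Convenience wrapper: builds the scene from `scene_cfg`, simulates
#' meteorology and satellite pixels, and calls [run_pipeline()].
#' Deterministic for fixed configuration and seeds.
#'
#' @param scene_cfg an [scene_config()]
#' @param n_days days of meteorology to simulate
#' @param pixels_per_day soundings per day
#' @param noise_cv retrieval noise coefficient of variation
#' @param config an [run_config()]
#' @return an `nh3_report` with the scene attached as `$scene`
#' @export
run_all <- function(scene_cfg = scene_config(), n_days = 60,
                    pixels_per_day = 200, noise_cv = 0.1,
                    config = run_config()) {
  scene <- generate_scene(scene_cfg)
  met <- generate_meteorology(n_days, seed = config$seed)
  pixels <- simulate_columns(scene, met, pixels_per_day, noise_cv,
                             seed = config$seed + 1L)
  rep <- run_pipeline(pixels, scene$blockgroups, scene$demographics,
                      scene$facilities, met,
                      reference = scene_cfg$reference_group, config = config)
  rep$scene <- scene
  rep
}

#' Compare inequalities between two platform reports
#'
#' For every period label present in both reports, the per-group absolute
#' inequalities are differenced and flagged as statistically equivalent when
#' the difference is within `z` combined standard mean errors.
#'
#' @param report_a,report_b `nh3_report` objects
#' @param z equivalence width (default 1.96)
#' @return data frame (period, group, abs_a, abs_b, diff, sem_diff, equivalent)
#' @export
compare_platforms <- function(report_a, report_b, z = 1.96) {
  common <- intersect(names(report_a$periods), names(report_b$periods))
  if (!length(common)) stop("no overlapping period labels between reports")
  rows <- list()
  for (p in common) {
    ia <- report_a$periods[[p]]$alldays$inequality
    ib <- report_b$periods[[p]]$alldays$inequality
    m <- merge(ia[, c("group", "absolute", "sem_abs")],
               ib[, c("group", "absolute", "sem_abs")],
               by = "group", suffixes = c("_a", "_b"))
    m$diff <- m$absolute_b - m$absolute_a
    m$sem_diff <- sqrt(m$sem_abs_a^2 + m$sem_abs_b^2)
    m$equivalent <- abs(m$diff) <= z * m$sem_diff
    m$period <- p
    rows[[p]] <- m[, c("period", "group", "absolute_a", "absolute_b",
                       "diff", "sem_diff", "equivalent")]
  }
  do.call(rbind, rows)
}

#' Reported concentration from a time-integrating passive sampler
#'
#' Passive diffusion samplers integrate over a deployment window, so a short
#' high-concentration episode is diluted into the window mean; a documented
#' instrument low bias reduces the reported value further. Computes the
#' time-weighted mean mixing ratio of a `peak_ppm` episode lasting
#' `peak_hours` against a `baseline_ppb` background over `window_days`,
#' multiplied by `(1 - low_bias_fraction)`, in ppb. An acute episode at the
#' 1.7 ppm respiratory-effects standard for 8 h in a 2-week window with
#' 10 ppb otherwise and a 40% low bias reports only ~30 ppb.
#'
#' @param peak_ppm episode mixing ratio in ppm
#' @param peak_hours episode duration in hours
#' @param baseline_ppb mixing ratio for the rest of the window, in ppb
#' @param window_days deployment window in days
#' @param low_bias_fraction fractional low bias in `[0, 1)`
#' @return reported mixing ratio in ppb
#' @export
#' @examples
#' passive_sampler_bias_example(1.7, 8, 10, 14, 0.40)  # ~30 ppb
passive_sampler_bias_example <- function(peak_ppm, peak_hours, baseline_ppb,
                                         window_days, low_bias_fraction) {
  if (window_days <= 0) stop("window_days must be positive")
  hours <- 24 * window_days
  if (peak_hours < 0 || peak_hours > hours)
    stop("peak_hours must lie within the deployment window")
  if (low_bias_fraction < 0 || low_bias_fraction >= 1)
    stop("low_bias_fraction must be in [0, 1)")
  twm_ppb <- (peak_ppm * 1000 * peak_hours +
                baseline_ppb * (hours - peak_hours)) / hours
  (1 - low_bias_fraction) * twm_ppb
}

#' @export
print.nh3_report <- function(x, ...) {
  cat(sprintf("<nh3_report> %d period(s); reference group: %s\n",
              length(x$periods), x$reference))
  for (p in names(x$periods)) {
    per <- x$periods[[p]]
    cat(sprintf("  %s: %d pixels, background %.3g, extent %.0f km\n",
                p, per$alldays$n_pixels, per$alldays$background$value,
                per$alldays$extent_km))
    ineq <- per$alldays$inequality
    for (i in seq_len(nrow(ineq)))
      cat(sprintf("    %-16s %+6.1f%% (abs %+.3g, sem %.2g)\n",
                  ineq$group[i], ineq$relative[i], ineq$absolute[i],
                  ineq$sem_abs[i]))
  }
  invisible(x)
}
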