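# Orchestration: simulate -> read -> filter -> project -> FPT -> segment ->
# trips/areas -> summaries, behind one structured config with seeded runs.
# Conservation identities (segment lengths vs track length, CF+FF time vs
# moving time) are asserted at run time so a broken stage fails loudly.

#' Build a pipeline configuration
#'
#' All analysis parameters in one structured list; any field can be
#' overridden.  The config is echoed into the output directory so every
#' reported statistic is traceable to its parameters.
#'
#' @param seed Master seed for every random stage.
#' @param out_dir Output directory.
#' @param simulation `NULL`, or a list with `n_nights` (and any
#'   [random_night_config()]/[sim_config()] overrides) to generate the
#'   input tracks.
#' @param tracks_csv Movebank-style CSV of fixes (when not simulating).
#' @param roost_lon,roost_lat Roost coordinates, degrees.
#' @param crs Projected frame identifier.
#' @param landcover_asc,elevation_asc Optional raster paths (when not
#'   simulating them).
#' @param filter,fpt,trips,areas Stage parameter lists; see defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("fptseg_run_"),
                            simulation = list(n_nights = 21),
                            tracks_csv = NULL,
                            roost_lon = -98.60, roost_lat = 20.40,
                            crs = "EPSG:32614",
                            landcover_asc = NULL, elevation_asc = NULL,
                            filter = list(window = c("20:00", "21:30"),
                                          proximity = 1000, utc_offset = -6),
                            fpt = list(r_min = 300, r_max = 500, step = 10,
                                       threshold = 2.7141),
                            trips = list(min_gap = 30, roost_buffer = 12400),
                            areas = list(min_duration = 30, min_fixes = 2,
                                         merge = TRUE)) {
  if (is.null(simulation) && is.null(tracks_csv))
    stop("either a simulation block or tracks_csv is required", call. = FALSE)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulation = simulation, tracks_csv = tracks_csv,
                 roost_lon = roost_lon, roost_lat = roost_lat, crs = crs,
                 landcover_asc = landcover_asc, elevation_asc = elevation_asc,
                 filter = filter, fpt = fpt, trips = trips, areas = areas),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$tracks_csv) && !"simulation" %in% names(y))
    y["simulation"] <- list(NULL)
  do.call(pipeline_config, y)
}

.msg <- function(...) message("[fptseg] ", ...)

#' Simulate the input data for a pipeline run
#'
#' Writes Movebank-style fixes, per-night ground truth, land-cover and
#' elevation rasters (in the projected frame) and the config echo into
#' `out_dir`.
#'
#' @param config A [pipeline_config()] with a `simulation` block.
#' @return Invisibly, a list with the cohort, raster paths and the fixes
#'   CSV path.
#' @export
pipeline_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$simulation
  if (is.null(sim)) stop("config has no simulation block", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  n_nights <- sim$n_nights %||% 21
  overrides <- sim[setdiff(names(sim), "n_nights")]
  cohort <- do.call(simulate_cohort,
                    c(list(n_nights = n_nights, seed = config$seed,
                           roost_lon = config$roost_lon,
                           roost_lat = config$roost_lat, crs = config$crs),
                      overrides))
  .msg("simulated ", n_nights, " night(s)")
  fixes <- do.call(rbind, lapply(cohort, `[[`, "fixes"))
  fixes_path <- file.path(config$out_dir, "tracks.csv")
  write_fixes_csv(fixes, fixes_path)
  for (id in names(cohort))
    write_truth_csv(cohort[[id]]$fixes,
                    file.path(config$out_dir, paste0("truth_", id, ".csv")))

  # rasters in the projected frame, covering roost and every patch
  frame <- utm_frame(config$crs)
  roost <- lonlat_to_xy(config$roost_lon, config$roost_lat, frame)
  patches <- list()
  for (el in cohort)
    patches <- c(patches, lapply(el$config$patches, function(p)
      patch_spec(p$center + c(roost$x, roost$y), p$radius, p$habitat)))
  cx <- vapply(patches, function(p) p$center[1], numeric(1))
  cy <- vapply(patches, function(p) p$center[2], numeric(1))
  rr <- vapply(patches, function(p) p$radius, numeric(1))
  extent <- c(min(c(cx - rr, roost$x)) - 2000, max(c(cx + rr, roost$x)) + 2000,
              min(c(cy - rr, roost$y)) - 2000, max(c(cy + rr, roost$y)) + 2000)
  lc <- generate_landcover(extent, patches, cell_size = 100,
                           seed = config$seed)
  dem <- generate_elevation(extent, cell_size = 200, seed = config$seed)
  lc_path <- file.path(config$out_dir, "landcover.asc")
  dem_path <- file.path(config$out_dir, "elevation.asc")
  write_asc(lc, lc_path)
  write_asc(dem, dem_path)
  yaml::write_yaml(.config_echo(config), file.path(config$out_dir,
                                                   "run_config.yaml"))
  invisible(list(cohort = cohort, fixes_csv = fixes_path,
                 landcover_asc = lc_path, elevation_asc = dem_path))
}

.config_echo <- function(config) {
  x <- unclass(config)
  x$package_version <- as.character(utils::packageVersion("fptseg"))
  x
}

#' Run the analysis chain on a fix table
#'
#' Reads tracks, filters and projects them, computes per-track S(r) profiles
#' and optimal radii, classifies modes at the population mean radius, builds
#' segments, trips and foraging areas, assigns habitat, and writes all stage
#' outputs plus a cohort report into `out_dir`.  Tracks that fail a stage
#' are reported and skipped; the rest continue.
#'
#' @param config A [pipeline_config()].
#' @param tracks_csv Override for the input fix table (e.g. the output of
#'   [pipeline_simulate()]).
#' @param landcover_asc,elevation_asc Raster path overrides.
#' @return A `run_report` list: per-track tables (`nights`, `segments`,
#'   `trips`, `areas`, `profiles`), cohort statistics, test tables, stage
#'   counters and the config echo.
#' @export
pipeline_analyze <- function(config, tracks_csv = NULL,
                             landcover_asc = NULL, elevation_asc = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tracks_csv <- tracks_csv %||% config$tracks_csv %||%
    file.path(config$out_dir, "tracks.csv")
  landcover_asc <- landcover_asc %||% config$landcover_asc %||%
    .maybe_file(config$out_dir, "landcover.asc")
  elevation_asc <- elevation_asc %||% config$elevation_asc %||%
    .maybe_file(config$out_dir, "elevation.asc")
  if (!file.exists(tracks_csv))
    stop("fix table not found: ", tracks_csv,
         " (run the simulate stage first or point tracks_csv at a file)",
         call. = FALSE)
  lc <- if (!is.null(landcover_asc)) read_asc(landcover_asc)
  dem <- if (!is.null(elevation_asc)) read_asc(elevation_asc)
  frame <- utm_frame(config$crs)
  roost <- lonlat_to_xy(config$roost_lon, config$roost_lat, frame)
  roost_xy <- c(roost$x, roost$y)

  raw <- read_fixes(tracks_csv)
  .msg("read ", length(raw), " track(s) from ", tracks_csv)
  counters <- list(tracks_read = length(raw),
                   fixes_read = sum(vapply(raw, function(t) nrow(t$fixes),
                                           numeric(1))))
  errors <- character(0)
  tracks <- list()
  for (tr in raw) {
    res <- tryCatch({
      t2 <- filter_track(tr, exclusion_window = config$filter$window,
                         proximity = config$filter$proximity,
                         utc_offset = config$filter$utc_offset)
      t2 <- project_track(t2, frame)
      if (!is.null(dem)) t2 <- attach_elevation(t2, dem)
      t2
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(tr$id, " [filter/project]: ",
                                 conditionMessage(res)))
    } else tracks[[res$id]] <- res
  }

  grid <- radius_grid(config$fpt$r_min, config$fpt$r_max, config$fpt$step)
  profiles <- list(); r_stars <- numeric(0)
  for (id in names(tracks)) {
    res <- tryCatch({
      prof <- var_log_fpt(tracks[[id]], grid)
      list(profile = prof, r_star = optimal_radius(prof))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(id, " [fpt]: ", conditionMessage(res)))
      tracks[[id]] <- NULL
    } else {
      profiles[[id]] <- res$profile
      r_stars[id] <- res$r_star
    }
  }
  pop <- population_radius(r_stars)
  .msg(sprintf("population mean optimal radius %.1f m (sd %.2f, n=%d)",
               pop$mean, pop$sd, length(r_stars)))

  nights <- seg_all <- trip_all <- area_all <- list()
  labels_all <- list()
  for (id in names(tracks)) {
    res <- tryCatch({
      trk <- tracks[[id]]
      fpt <- passage_times(trk, pop$mean)
      labels <- classify_modes(fpt, config$fpt$threshold)
      segs <- build_segments(labels, trk)
      trips <- split_trips(trk, roost_xy, min_gap = config$trips$min_gap,
                           roost_buffer = config$trips$roost_buffer)
      areas <- find_foraging_areas(segs, trk, r_star = r_stars[[id]],
                                   min_duration = config$areas$min_duration,
                                   min_fixes = config$areas$min_fixes,
                                   merge = config$areas$merge,
                                   roost_xy = roost_xy)
      if (!is.null(lc) && nrow(areas))
        areas <- assign_habitat(areas, trk, lc)
      ns <- night_summary(trk, labels, trips, areas)
      # run-time conservation checks: fail loudly if a stage broke identity
      fx <- trk$fixes[trk$fixes$valid, ]
      total_km <- sum(sqrt(diff(fx$x)^2 + diff(fx$y)^2)) / 1000
      stopifnot(abs(sum(segs$length_km) - total_km) <=
                  1e-9 * max(1, total_km))
      stopifnot(abs(ns$cf_time_h + ns$ff_time_h - ns$moving_time_h) <= 1e-9)
      list(night = ns, segs = segs, trips = trips, areas = areas,
           labels = labels)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(id, " [segment/trips]: ",
                                 conditionMessage(res)))
    } else {
      nights[[id]] <- res$night
      seg_all[[id]] <- res$segs
      trip_all[[id]] <- res$trips
      area_all[[id]] <- res$areas
      labels_all[[id]] <- res$labels
    }
  }
  nights <- do.call(rbind, nights)
  segments <- do.call(rbind, seg_all)
  trips <- do.call(rbind, trip_all)
  areas <- do.call(rbind, unname(area_all))

  mode_tests <- tryCatch(compare_modes(segments), error = function(e) {
    .msg("mode comparison unavailable: ", conditionMessage(e)); NULL })
  hab_tests <- if (!is.null(areas) && nrow(areas) &&
                   any(!is.na(areas$habitat)))
    tryCatch(habitat_tests(areas), error = function(e) NULL)

  report <- list(
    package_version = as.character(utils::packageVersion("fptseg")),
    config = .config_echo(config),
    counters = c(counters, list(
      tracks_analyzed = nrow(nights),
      n_segments = if (is.null(segments)) 0L else nrow(segments),
      n_trips = if (is.null(trips)) 0L else nrow(trips),
      n_areas = if (is.null(areas)) 0L else nrow(areas))),
    errors = errors,
    r_stars = r_stars,
    population_radius = pop,
    nights = nights, segments = segments, trips = trips, areas = areas,
    labels = labels_all, profiles = profiles,
    mode_tests = mode_tests, habitat_tests = hab_tests,
    cohort = cohort_stats(nights, areas, r_stars)
  )
  class(report) <- "run_report"
  .write_report(report, tracks, frame)
  report
}

.maybe_file <- function(dir, name) {
  p <- file.path(dir, name)
  if (file.exists(p)) p else NULL
}

#' Cohort-level summary statistics
#'
#' @param nights Row-bound [night_summary()] rows.
#' @param areas Row-bound foraging-area tibbles (may be `NULL`).
#' @param r_stars Per-track optimal radii.
#' @return A tibble of cohort mean +/- sd statistics.
#' @export
cohort_stats <- function(nights, areas, r_stars) {
  ms <- function(x) c(mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
  rows <- list(
    c("total_distance_km", ms(nights$total_distance_km)),
    c("mean_speed_ms", ms(nights$mean_speed_ms)),
    c("n_trips", ms(nights$n_trips)),
    c("n_areas", ms(nights$n_areas)),
    c("optimal_radius_m", ms(r_stars)),
    c("cf_time_h", ms(nights$cf_time_h)),
    c("ff_time_h", ms(nights$ff_time_h)),
    c("cf_frac_moving", ms(nights$cf_frac_moving)),
    c("fixes_per_track", ms(nights$n_fixes))
  )
  if (!is.null(areas) && nrow(areas)) {
    rows <- c(rows, list(
      c("area_km2", ms(areas$area_km2)),
      c("roost_distance_km", ms(areas$roost_distance_km)),
      c("search_time_h", ms(areas$search_time_h))))
  }
  tibble::tibble(
    statistic = vapply(rows, `[[`, character(1), 1),
    mean = as.numeric(vapply(rows, `[[`, character(1), 2)),
    sd = as.numeric(vapply(rows, `[[`, character(1), 3)),
    n = nrow(nights)
  )
}

.write_report <- function(report, tracks, frame) {
  out <- report$config$out_dir
  wr <- function(df, name) if (!is.null(df) && nrow(df))
    utils::write.csv(.flatten_list_cols(df), file.path(out, name),
                     row.names = FALSE)
  wr(report$nights, "night_summary.csv")
  wr(report$segments, "segments.csv")
  wr(report$trips, "trips.csv")
  wr(report$areas, "areas.csv")
  wr(report$cohort, "cohort_summary.csv")
  if (!is.null(report$mode_tests)) wr(report$mode_tests, "mode_tests.csv")
  if (!is.null(report$habitat_tests)) {
    wr(report$habitat_tests$counts, "habitat_summary.csv")
    wr(report$habitat_tests$tests, "habitat_tests.csv")
  }
  pro <- do.call(rbind, lapply(names(report$profiles), function(id) {
    p <- report$profiles[[id]]
    data.frame(track = id, r = p$r, s = p$s, n_defined = p$n_defined)
  }))
  if (!is.null(pro)) utils::write.csv(pro, file.path(out, "fpt_profiles.csv"),
                                      row.names = FALSE)
  if (!is.null(report$areas) && nrow(report$areas))
    write_areas_geojson(report$areas, frame, file.path(out, "areas.geojson"))
  for (id in names(tracks))
    if (!is.null(report$labels[[id]]) && id %in% report$segments$track)
      write_segments_geojson(
        report$segments[report$segments$track == id, ],
        tracks[[id]], file.path(out, paste0("segments_", id, ".geojson")),
        frame = frame)
  writeLines(format_report(report), file.path(out, "report.txt"))
  yaml::write_yaml(report$config, file.path(out, "run_config.yaml"))
}

.flatten_list_cols <- function(df) {
  for (nm in names(df))
    if (is.list(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], function(x)
        paste(x, collapse = ";"), character(1))
  df
}

#' Plain-text cohort report
#'
#' @param report A `run_report` from [pipeline_analyze()].
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  f <- function(...) sprintf(...)
  lines <- c(
    f("fptseg %s cohort report (seed %d)", report$package_version,
      report$config$seed),
    f("tracks: %d read, %d analyzed; %d segments, %d trips, %d areas",
      report$counters$tracks_read, report$counters$tracks_analyzed,
      report$counters$n_segments, report$counters$n_trips,
      report$counters$n_areas),
    f("population mean optimal radius: %.0f +/- %.2f m (n = %d)",
      report$population_radius$mean, report$population_radius$sd,
      length(report$r_stars)),
    "",
    "cohort statistics (mean +/- sd):",
    sprintf("  %-20s %10.2f +/- %.2f", report$cohort$statistic,
            report$cohort$mean, report$cohort$sd)
  )
  if (!is.null(report$mode_tests)) {
    lines <- c(lines, "", "CF vs FF (Mann-Whitney U on per-track means):",
               sprintf("  %-12s U = %6.1f  p = %.4g  (%s)",
                       report$mode_tests$variable, report$mode_tests$U,
                       report$mode_tests$p, report$mode_tests$method))
  }
  if (!is.null(report$habitat_tests)) {
    hc <- report$habitat_tests$counts
    lines <- c(lines, "", "foraging areas by habitat:",
               sprintf("  %-10s n = %2d (%.0f%%)", hc$habitat, hc$n,
                       100 * hc$fraction))
    if (!is.null(report$habitat_tests$tests)) {
      ht <- report$habitat_tests$tests
      lines <- c(lines, "Kruskal-Wallis across habitats:",
                 sprintf("  %-18s H(%d) = %.3f  p = %.4g", ht$variable,
                         ht$df, ht$H, ht$p))
    }
  }
  if (length(report$errors))
    lines <- c(lines, "", "stage errors:", paste0("  ", report$errors))
  lines
}

#' Run the full pipeline
#'
#' Simulates the cohort when the config asks for it, analyzes the tracks,
#' and returns the run report.  Identical `(config, seed)` pairs produce
#' identical reports.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return A `run_report` list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$simulation)) pipeline_simulate(config)
  pipeline_analyze(config)
}

#' Aggregate night summaries from previous runs
#'
#' @param dirs Character vector of analyze output directories.
#' @return A list with the row-bound `nights` table and a fresh cohort
#'   statistics table.
#' @export
pipeline_summarize <- function(dirs) {
  paths <- file.path(dirs, "night_summary.csv")
  missing <- dirs[!file.exists(paths)]
  if (length(missing))
    stop("no night_summary.csv in: ", paste(missing, collapse = ", "),
         " (run analyze there first)", call. = FALSE)
  nights <- do.call(rbind, lapply(paths, function(p)
    utils::read.csv(p, check.names = FALSE)))
  areas <- do.call(rbind, lapply(dirs, function(d) {
    p <- file.path(d, "areas.csv")
    if (file.exists(p)) utils::read.csv(p, check.names = FALSE)
  }))
  rstars <- unlist(lapply(dirs, function(d) {
    p <- file.path(d, "fpt_profiles.csv")
    if (!file.exists(p)) return(numeric(0))
    pr <- utils::read.csv(p)
    vapply(split(pr, pr$track), function(g)
      g$r[which.max(g$s)], numeric(1))
  }))
  list(nights = nights,
       cohort = cohort_stats(nights, areas, rstars))
}

#' @export
print.run_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Per-fix ground-truth state accuracy
#'
#' Compares CF/FF labels against simulator truth at the fix timestamps
#' (COMMUTE maps to CF, FORAGE to FF; roost fixes never reach
#' classification because they are invalid).
#'
#' @param labels Character labels from [classify_modes()].
#' @param track The corresponding filtered track.
#' @param truth A truth tibble/data.frame with `timestamp` and `state`
#'   columns (e.g. read back from `truth_*.csv`).
#' @return Fraction of fixes whose label matches the true state.
#' @export
state_accuracy <- function(labels, track, truth) {
  fx <- track$fixes[track$fixes$valid, ]
  ts <- if (inherits(truth$timestamp, "POSIXct")) truth$timestamp else
    as.POSIXct(truth$timestamp, tz = "UTC")
  idx <- match(as.numeric(fx$timestamp), as.numeric(ts))
  st <- truth$state[idx]
  keep <- !is.na(st) & st != "ROOST"
  if (!any(keep)) return(NA_real_)
  mean((st[keep] == "FORAGE") == (labels[keep] == "FF"))
}
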