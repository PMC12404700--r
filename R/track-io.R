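# Reading, validating, filtering and projecting Movebank-style GPS fix
# tables into analysis-ready planar tracks.

#' Construct a track
#'
#' @param id Individual identifier (four-digit year+bat code by convention).
#' @param fixes Tibble with columns `timestamp` (POSIXct UTC), `lon`, `lat`
#'   (degrees), `valid` (logical); optional `x`, `y` (metres), `elevation`.
#' @return An object of class `fpt_track`.
#' @export
new_track <- function(id, fixes) {
  need <- c("timestamp", "lon", "lat", "valid")
  miss <- setdiff(need, names(fixes))
  if (length(miss))
    stop("fixes is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(fixes$timestamp, strictly = TRUE))
    stop("timestamps must be strictly increasing within a track",
         call. = FALSE)
  for (col in c("x", "y", "elevation"))
    if (!col %in% names(fixes)) fixes[[col]] <- NA_real_
  structure(list(id = id, fixes = tibble::as_tibble(fixes)),
            class = "fpt_track")
}

#' @export
print.fpt_track <- function(x, ...) {
  nv <- sum(x$fixes$valid)
  cat("<fpt_track> ", x$id, ": ", nrow(x$fixes), " fixes (", nv, " valid), ",
      format(min(x$fixes$timestamp), "%Y-%m-%d %H:%M", tz = "UTC"), " - ",
      format(max(x$fixes$timestamp), "%H:%M UTC", tz = "UTC"),
      if (!all(is.na(x$fixes$x))) " [projected]", "\n", sep = "")
  invisible(x)
}

#' Read Movebank-style GPS fixes
#'
#' Expects columns `timestamp`, `location-long`, `location-lat`,
#' `individual-local-identifier`, and optionally `fix-status`
#' (`valid`/`invalid`; missing coordinates also mark a fix invalid).
#' Returns raw, unfiltered tracks: invalid fixes are retained but flagged.
#' An individual's rows are split into separate tracking episodes wherever
#' consecutive fixes are more than `episode_gap_h` apart.
#'
#' @param path CSV file path.
#' @param episode_gap_h Hours of silence that start a new episode (default 24,
#'   so consecutive tracked nights stay in one track).
#' @return A list of [new_track()] objects.
#' @export
read_fixes <- function(path, episode_gap_h = 24) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("timestamp", "location-long", "location-lat",
            "individual-local-identifier")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("input file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ts <- as.POSIXct(rep(NA_real_, nrow(df)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M")) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(strptime(df$timestamp[need], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop("unparseable timestamp '", df$timestamp[bad], "' at data row ", bad,
         call. = FALSE)
  }
  lon <- suppressWarnings(as.numeric(df$`location-long`))
  lat <- suppressWarnings(as.numeric(df$`location-lat`))
  status <- if ("fix-status" %in% names(df)) df$`fix-status` else "valid"
  valid <- (status == "valid") & !is.na(lon) & !is.na(lat)
  out <- list()
  for (id in unique(df$`individual-local-identifier`)) {
    sel <- which(df$`individual-local-identifier` == id)
    sel <- sel[order(ts[sel])]
    gaps <- diff(as.numeric(ts[sel])) / 3600
    episode <- cumsum(c(1, gaps > episode_gap_h))
    for (ep in unique(episode)) {
      rows <- sel[episode == ep]
      eid <- if (max(episode) > 1) paste0(id, ".", ep) else as.character(id)
      out[[eid]] <- new_track(eid, tibble::tibble(
        timestamp = ts[rows], lon = lon[rows], lat = lat[rows],
        valid = valid[rows]))
    }
  }
  out
}

#' Filter a track for analysis
#'
#' Drops invalid fixes, then drops fixes that fall inside the early-evening
#' exclusion window (local clock time) *and* lie within `proximity` metres of
#' the night's first valid fix — the device-activation cluster.  The anchor
#' fix itself is retained: it defines the reference location, and removing it
#' would re-anchor the rule on each application and destroy idempotence.
#' Counts removed by each rule are recorded in the `filter_counts` attribute.
#'
#' @param track An [new_track()] object.
#' @param exclusion_window Local clock interval `c("HH:MM", "HH:MM")`.
#' @param proximity Metres from the first-fix location (default 1000).
#' @param utc_offset Hours added to UTC to obtain local clock time.
#' @return The filtered track (valid fixes only).
#' @export
filter_track <- function(track, exclusion_window = c("20:00", "21:30"),
                         proximity = 1000, utc_offset = -6) {
  stopifnot(inherits(track, "fpt_track"))
  fx <- track$fixes
  n_invalid <- sum(!fx$valid)
  fx <- fx[fx$valid, , drop = FALSE]
  if (!nrow(fx)) stop("track ", track$id, ": no valid fixes", call. = FALSE)
  local_sec <- (as.numeric(fx$timestamp) + utc_offset * 3600) %% 86400
  w0 <- .hm_to_sec(exclusion_window[1])
  w1 <- .hm_to_sec(exclusion_window[2])
  in_window <- if (w1 >= w0) local_sec >= w0 & local_sec <= w1 else
    local_sec >= w0 | local_sec <= w1
  d <- geosphere::distGeo(cbind(fx$lon[1], fx$lat[1]), cbind(fx$lon, fx$lat))
  drop <- in_window & d <= proximity
  drop[1] <- FALSE  # the anchor fix defines the reference and is kept
  n_window <- sum(drop)
  fx <- fx[!drop, , drop = FALSE]
  if (!nrow(fx)) stop("track ", track$id, ": all fixes filtered out",
                      call. = FALSE)
  out <- new_track(track$id, fx)
  attr(out, "filter_counts") <- c(invalid = n_invalid, window = n_window)
  out
}

#' Project a track into planar coordinates
#'
#' Fills the `x`, `y` columns (metres) of valid fixes using the declared
#' frame; fix order and count are untouched.
#'
#' @param track An [new_track()] object.
#' @param frame A [utm_frame()] or CRS identifier string (`"EPSG:32614"`).
#' @return The track with planar coordinates filled.
#' @export
project_track <- function(track, frame) {
  stopifnot(inherits(track, "fpt_track"))
  if (is.character(frame)) frame <- utm_frame(frame)
  fx <- track$fixes
  ok <- fx$valid & !is.na(fx$lon)
  xy <- lonlat_to_xy(fx$lon[ok], fx$lat[ok], frame)
  fx$x[ok] <- xy$x
  fx$y[ok] <- xy$y
  out <- new_track(track$id, fx)
  attr(out, "frame") <- frame
  attr(out, "filter_counts") <- attr(track, "filter_counts")
  out
}

#' Inter-fix interval diagnostics
#'
#' Intervals are computed between consecutive retained (valid) fixes.
#'
#' @param track An [new_track()] object with at least 2 fixes.
#' @param gap_threshold Minutes above which an interval is reported as a gap.
#' @return A list: `mean`, `sd`, `max` (minutes) and `gaps`, a tibble of
#'   intervals exceeding the threshold, sorted by start time.
#' @export
gap_stats <- function(track, gap_threshold = 30) {
  stopifnot(inherits(track, "fpt_track"))
  fx <- track$fixes[track$fixes$valid, ]
  if (nrow(fx) < 2) stop("need at least 2 valid fixes", call. = FALSE)
  iv <- diff(as.numeric(fx$timestamp)) / 60
  gsel <- which(iv > gap_threshold)
  gaps <- tibble::tibble(start = fx$timestamp[gsel],
                         end = fx$timestamp[gsel + 1],
                         minutes = iv[gsel])
  gaps <- gaps[order(gaps$start), , drop = FALSE]
  list(mean = mean(iv), sd = stats::sd(iv), max = max(iv), gaps = gaps)
}

#' Attach elevations from a DEM
#'
#' Samples the elevation raster at each valid fix's planar position
#' (nearest cell, half-open convention).  Fixes outside the DEM get `NA`
#' with a warning.
#'
#' @param track A projected [new_track()] object.
#' @param dem A [grid_raster()] of elevations in the track's frame.
#' @return The track with the `elevation` column filled.
#' @export
attach_elevation <- function(track, dem) {
  stopifnot(inherits(track, "fpt_track"), inherits(dem, "grid_raster"))
  fx <- track$fixes
  if (all(is.na(fx$x))) stop("track must be projected first", call. = FALSE)
  z <- raster_extract(dem, fx$x, fx$y)
  if (any(is.na(z) & fx$valid & !is.na(fx$x)))
    warning("track ", track$id, ": ",
            sum(is.na(z) & fx$valid & !is.na(fx$x)),
            " fix(es) outside the DEM; elevation left missing")
  fx$elevation <- z
  out <- new_track(track$id, fx)
  attr(out, "frame") <- attr(track, "frame")
  attr(out, "filter_counts") <- attr(track, "filter_counts")
  out
}
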