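# Threshold classification of log-FPT into commuting (CF) vs foraging (FF)
# flight, maximal same-mode segments with per-segment metrics, and the
# cohort-level CF/FF comparison.

#' Classify fixes as commuting or foraging flight
#'
#' Natural-log passage time (minutes) below the threshold is commuting
#' flight (CF), above is foraging flight (FF); a value exactly at the
#' threshold is CF (conservative tie rule).  Fixes with undefined `t(r)`
#' (track ends) inherit the label of the nearest preceding defined fix, or
#' failing that the nearest following one, so trips and distances stay whole.
#'
#' @param fpt An [passage_times()] series computed at the population mean
#'   radius.
#' @param threshold Log-units threshold (default 2.7141).
#' @return Character vector of `"CF"`/`"FF"`, one per fix.
#' @export
classify_modes <- function(fpt, threshold = 2.7141) {
  lt <- log(fpt$t_min)
  lab <- ifelse(lt > threshold, "FF", "CF")
  if (all(is.na(lab)))
    stop("no defined passage time on track; cannot classify", call. = FALSE)
  # inherit from the nearest preceding defined fix
  for (i in seq_along(lab))
    if (is.na(lab[i]) && i > 1) lab[i] <- lab[i - 1]
  # leading undefined fixes inherit the first defined label
  first_def <- which(!is.na(lab))[1]
  lab[seq_len(first_def - 1)] <- lab[first_def]
  lab
}

#' Build maximal same-mode segments
#'
#' Segments partition the track's fixes into maximal runs of one mode.  The
#' step (and time) between fix i and fix i+1 is assigned to the segment
#' containing fix i, so segment lengths sum exactly to the track's total
#' step length and durations sum to the track's elapsed time.
#'
#' @param labels Character vector from [classify_modes()], one per fix.
#' @param track The projected, filtered [new_track()] the labels refer to.
#' @return A tibble of class `fpt_segments`: `track`, `segment`, `mode`,
#'   `start_fix`, `end_fix`, `n_fixes`, `start_time`, `end_time`,
#'   `length_km`, `duration_h`, `speed_ms`, `mean_elevation_m`.
#' @export
build_segments <- function(labels, track) {
  stopifnot(inherits(track, "fpt_track"))
  fx <- track$fixes[track$fixes$valid, ]
  if (length(labels) != nrow(fx))
    stop("one label per valid fix required", call. = FALSE)
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  seg <- tibble::tibble(
    track = track$id,
    segment = seq_along(runs$values),
    mode = runs$values,
    start_fix = starts,
    end_fix = ends,
    n_fixes = runs$lengths,
    start_time = fx$timestamp[starts],
    end_time = fx$timestamp[ends]
  )
  class(seg) <- c("fpt_segments", class(seg))
  segment_metrics(seg, track)
}

#' Fill per-segment metrics
#'
#' Total length is the sum of Euclidean step lengths assigned to the segment
#' (in km); duration runs from the segment's first fix to the next segment's
#' first fix (to the last fix of the track for the final segment); speed is
#' total length over duration (m/s); elevation is the mean over member fixes.
#'
#' @param segments A segment tibble from [build_segments()].
#' @param track The corresponding projected track.
#' @return The segment tibble with metric columns filled.
#' @export
segment_metrics <- function(segments, track) {
  fx <- track$fixes[track$fixes$valid, ]
  n <- nrow(fx)
  step_m <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)  # step i: fix i -> i+1
  tt <- as.numeric(fx$timestamp)
  len <- dur <- spd <- elev <- numeric(nrow(segments))
  for (k in seq_len(nrow(segments))) {
    i0 <- segments$start_fix[k]
    i1 <- segments$end_fix[k]
    last_step <- min(i1, n - 1)  # final segment has no outgoing step
    len[k] <- if (last_step >= i0) sum(step_m[i0:last_step]) else 0
    t_end <- if (i1 < n) tt[i1 + 1] else tt[n]
    dur[k] <- t_end - tt[i0]
    spd[k] <- if (dur[k] > 0) len[k] / dur[k] else NA_real_
    elev[k] <- mean(fx$elevation[i0:i1], na.rm = TRUE)
  }
  segments$length_km <- len / 1000
  segments$duration_h <- dur / 3600
  segments$speed_ms <- spd
  segments$mean_elevation_m <- ifelse(is.nan(elev), NA_real_, elev)
  if (any(dur == 0))
    warning("segment(s) with zero duration; speed undefined")
  segments
}

#' Compare commuting vs foraging flight across tracks
#'
#' The unit of analysis is the per-track mean of each variable within each
#' mode (n per group = number of tracks contributing that mode).  Groups are
#' compared with a two-sided Mann-Whitney U test via [mann_whitney()]; the
#' method used (exact, enumeration, or corrected normal approximation) is
#' reported alongside the statistic.
#'
#' @param segments Row-bound segment tibbles from several tracks.
#' @return A tibble: `variable`, `U`, `p`, `method`, `n_cf`, `n_ff`.  U is
#'   reported for the CF group.
#' @export
compare_modes <- function(segments) {
  vars <- c(length_km = "length_km", speed_ms = "speed_ms",
            elevation_m = "mean_elevation_m")
  for (m in c("CF", "FF"))
    if (!any(segments$mode == m))
      stop("mode ", m, " absent from all tracks", call. = FALSE)
  if (length(unique(segments$track)) < 2)
    stop("need segments from at least 2 tracks", call. = FALSE)
  rows <- lapply(names(vars), function(vn) {
    v <- vars[[vn]]
    agg <- stats::aggregate(segments[[v]],
                            by = list(track = segments$track,
                                      mode = segments$mode),
                            FUN = mean, na.rm = TRUE)
    cf <- agg$x[agg$mode == "CF"]
    ff <- agg$x[agg$mode == "FF"]
    cf <- cf[is.finite(cf)]; ff <- ff[is.finite(ff)]
    if (!length(cf) || !length(ff))
      return(tibble::tibble(variable = vn, U = NA_real_, p = NA_real_,
                            method = "insufficient data",
                            n_cf = length(cf), n_ff = length(ff)))
    mw <- mann_whitney(cf, ff)
    tibble::tibble(variable = vn, U = mw$U, p = mw$p, method = mw$method,
                   n_cf = length(cf), n_ff = length(ff))
  })
  do.call(rbind, rows)
}

#' Two-sided Mann-Whitney U test
#'
#' U counts pairs where the first group exceeds the second (ties count
#' half).  Without ties the exact distribution is used; with ties, full
#' enumeration of group relabelings when `choose(n1+n2, n1)` is tractable
#' (two-sided p = share of relabelings at least as far from the null mean
#' `n1*n2/2` as observed); otherwise the tie- and continuity-corrected
#' normal approximation.
#'
#' @param g1,g2 Numeric vectors.
#' @param max_enum Enumeration budget (number of relabelings).
#' @return A list with `U` (for `g1`), `p` and `method`.
#' @export
mann_whitney <- function(g1, g2, max_enum = 2e4) {
  n1 <- length(g1); n2 <- length(g2)
  U <- sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  ties <- anyDuplicated(c(g1, g2)) > 0
  if (!ties && n1 < 50 && n2 < 50) {
    wt <- stats::wilcox.test(g1, g2, exact = TRUE)
    list(U = U, p = wt$p.value, method = "exact")
  } else if (ties && choose(n1 + n2, n1) <= max_enum) {
    pool <- c(g1, g2)
    dev_obs <- abs(U - n1 * n2 / 2)
    devs <- apply(utils::combn(n1 + n2, n1), 2, function(ix) {
      u <- sum(outer(pool[ix], pool[-ix], ">")) +
        0.5 * sum(outer(pool[ix], pool[-ix], "=="))
      abs(u - n1 * n2 / 2)
    })
    list(U = U, p = mean(devs >= dev_obs - 1e-12),
         method = "exact enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                              correct = TRUE))
    list(U = U, p = wt$p.value,
         method = "normal approximation (tie-corrected)")
  }
}

#' Export segments as GeoJSON line features
#'
#' @param segments A segment tibble from [build_segments()].
#' @param track The corresponding projected track (with a `frame` attribute,
#'   or pass `frame`).
#' @param path Output path.
#' @param frame Optional [utm_frame()] override.
#' @return `path`, invisibly.
#' @export
write_segments_geojson <- function(segments, track, path, frame = NULL) {
  frame <- frame %||% attr(track, "frame")
  if (is.null(frame)) stop("no projection frame available", call. = FALSE)
  fx <- track$fixes[track$fixes$valid, ]
  feats <- lapply(seq_len(nrow(segments)), function(k) {
    i0 <- segments$start_fix[k]
    i1 <- min(segments$end_fix[k] + 1, nrow(fx))  # include the outgoing step
    ll <- xy_to_lonlat(fx$x[i0:i1], fx$y[i0:i1], frame)
    list(type = "Feature",
         properties = list(track = segments$track[k],
                           segment = segments$segment[k],
                           mode = segments$mode[k],
                           length_km = segments$length_km[k],
                           duration_h = segments$duration_h[k],
                           speed_ms = segments$speed_ms[k]),
         geometry = list(type = "LineString",
                         coordinates = Map(c, ll$lon, ll$lat)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 9)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
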