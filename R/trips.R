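# Nightly trip decomposition and foraging-area delineation for a
# central-place forager: roost-to-roost excursions split at long near-roost
# time gaps, foraging areas from qualifying FF segments, sized by the
# track's own S(r)-peak radius and characterized by roost distance,
# search-time effort and majority land-cover habitat.

#' Split a night into roost-to-roost trips
#'
#' A trip boundary is declared at any inter-fix time gap of at least
#' `min_gap` minutes whose bracketing fixes both lie within `roost_buffer`
#' metres of the roost (the animal is assumed to have entered the roost
#' during the gap).  Trips are the fix runs between boundaries.
#'
#' @param track A projected, filtered [new_track()].
#' @param roost_xy Roost planar coordinates `c(x, y)` in the track frame.
#' @param min_gap Minimum qualifying gap, minutes (default 30).
#' @param roost_buffer Metres from the roost within which a gap counts as a
#'   roost dwell (default 12400; see the package vignette for the choice).
#' @return A tibble of class `fpt_trips`: `track`, `trip`, `start_fix`,
#'   `end_fix`, `n_fixes`, `start_time`, `end_time`, `total_distance_km`,
#'   `mean_speed_ms`.
#' @export
split_trips <- function(track, roost_xy, min_gap = 30, roost_buffer = 12400) {
  stopifnot(inherits(track, "fpt_track"))
  fx <- track$fixes[track$fixes$valid, ]
  if (anyNA(fx$x)) stop("track must be projected first", call. = FALSE)
  n <- nrow(fx)
  gap_min <- diff(as.numeric(fx$timestamp)) / 60
  d_roost <- sqrt((fx$x - roost_xy[1])^2 + (fx$y - roost_xy[2])^2)
  boundary <- which(gap_min >= min_gap &
                    d_roost[-n] <= roost_buffer &
                    d_roost[-1] <= roost_buffer)
  # a round trip is an excursion: discard boundaries that cut off a run of
  # fixes that never leaves the roost buffer (e.g. the departure fix alone)
  repeat {
    starts <- c(1, boundary + 1)
    ends <- c(boundary, n)
    excursion <- vapply(seq_along(starts), function(k)
      max(d_roost[starts[k]:ends[k]]) > roost_buffer, logical(1))
    if (all(excursion) || !length(boundary)) break
    k <- which(!excursion)[1]
    drop_b <- if (k == 1) 1 else k - 1  # merge with the neighbouring run
    boundary <- boundary[-drop_b]
  }
  trips <- tibble::tibble(
    track = track$id,
    trip = seq_along(starts),
    start_fix = starts, end_fix = ends,
    n_fixes = ends - starts + 1,
    start_time = fx$timestamp[starts],
    end_time = fx$timestamp[ends]
  )
  class(trips) <- c("fpt_trips", class(trips))
  trip_metrics(trips, track)
}

#' Fill per-trip metrics
#'
#' Total distance sums the Euclidean steps strictly inside the trip (km);
#' mean speed divides it by the in-trip elapsed time (m/s).  Single-fix
#' trips are flagged with undefined metrics.
#'
#' @param trips A trip tibble from [split_trips()].
#' @param track The corresponding projected track.
#' @return The trip tibble with metrics filled.
#' @export
trip_metrics <- function(trips, track) {
  fx <- track$fixes[track$fixes$valid, ]
  step_m <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
  tt <- as.numeric(fx$timestamp)
  dist_km <- spd <- rep(NA_real_, nrow(trips))
  for (k in seq_len(nrow(trips))) {
    i0 <- trips$start_fix[k]; i1 <- trips$end_fix[k]
    if (i1 > i0) {
      d <- sum(step_m[i0:(i1 - 1)])
      dist_km[k] <- d / 1000
      spd[k] <- d / (tt[i1] - tt[i0])
    }
  }
  trips$total_distance_km <- dist_km
  trips$mean_speed_ms <- spd
  if (anyNA(dist_km)) warning("single-fix trip(s); metrics undefined")
  trips
}

#' Delineate foraging areas from FF segments
#'
#' Each foraging-flight segment lasting at least `min_duration` minutes with
#' at least `min_fixes` relocations becomes a foraging area; shorter visits
#' are treated as exploratory and discarded.  When `merge = TRUE`, areas of
#' the same track whose centroids lie within `r_star` of each other are
#' merged into one revisited area.
#'
#' @param segments A segment tibble from [build_segments()].
#' @param track The corresponding projected track.
#' @param r_star The track's own S(r)-peak radius (m), used for the
#'   characteristic area size and the merge distance.
#' @param min_duration Minimum segment duration, minutes (default 30).
#' @param min_fixes Minimum relocations (default 2).
#' @param merge Merge revisited areas (default TRUE).
#' @param roost_xy Optional roost planar coordinates; fills roost distance.
#' @return A tibble of class `foraging_areas`: `track`, `area`, `segments`
#'   (list column of member segment ids), `n_fixes`, `centroid_x`,
#'   `centroid_y`, `r_star_m`, `area_km2`, `roost_distance_km`,
#'   `search_time_h`, `habitat` (NA until [assign_habitat()]).
#' @export
find_foraging_areas <- function(segments, track, r_star,
                                min_duration = 30, min_fixes = 2,
                                merge = TRUE, roost_xy = NULL) {
  fx <- track$fixes[track$fixes$valid, ]
  cand <- segments[segments$mode == "FF" &
                   segments$duration_h * 60 >= min_duration &
                   segments$n_fixes >= min_fixes, , drop = FALSE]
  if (!nrow(cand)) return(.empty_areas())
  areas <- lapply(seq_len(nrow(cand)), function(k) {
    idx <- cand$start_fix[k]:cand$end_fix[k]
    list(segments = cand$segment[k], fixes = idx,
         cx = mean(fx$x[idx]), cy = mean(fx$y[idx]),
         search_h = cand$duration_h[k])
  })
  if (merge && length(areas) > 1) {
    repeat {
      merged <- FALSE
      for (a in seq_along(areas)) {
        for (b in seq_along(areas)) {
          if (b <= a) next
          dd <- sqrt((areas[[a]]$cx - areas[[b]]$cx)^2 +
                     (areas[[a]]$cy - areas[[b]]$cy)^2)
          if (dd <= r_star) {
            idx <- c(areas[[a]]$fixes, areas[[b]]$fixes)
            areas[[a]] <- list(
              segments = c(areas[[a]]$segments, areas[[b]]$segments),
              fixes = idx, cx = mean(fx$x[idx]), cy = mean(fx$y[idx]),
              search_h = areas[[a]]$search_h + areas[[b]]$search_h)
            areas[[b]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  out <- tibble::tibble(
    track = track$id,
    area = seq_along(areas),
    segments = I(lapply(areas, `[[`, "segments")),
    member_fixes = I(lapply(areas, `[[`, "fixes")),
    n_fixes = vapply(areas, function(a) length(a$fixes), integer(1)),
    centroid_x = vapply(areas, `[[`, numeric(1), "cx"),
    centroid_y = vapply(areas, `[[`, numeric(1), "cy"),
    r_star_m = r_star,
    area_km2 = area_size(r_star),
    roost_distance_km = NA_real_,
    search_time_h = vapply(areas, `[[`, numeric(1), "search_h"),
    habitat = NA_character_
  )
  if (!is.null(roost_xy))
    out$roost_distance_km <- roost_distance(out, roost_xy)
  class(out) <- c("foraging_areas", class(out))
  out
}

.empty_areas <- function() {
  out <- tibble::tibble(
    track = character(0), area = integer(0),
    segments = I(list()), member_fixes = I(list()), n_fixes = integer(0),
    centroid_x = numeric(0), centroid_y = numeric(0), r_star_m = numeric(0),
    area_km2 = numeric(0), roost_distance_km = numeric(0),
    search_time_h = numeric(0), habitat = character(0))
  class(out) <- c("foraging_areas", class(out))
  out
}

#' Characteristic foraging-area size
#'
#' The circle area at the track's S(r)-peak radius, pi * r*^2, converted to
#' km^2 and reported to two decimals.
#'
#' @param r_star Radius in metres.
#' @return Area in km^2 (2 decimals).
#' @export
area_size <- function(r_star) {
  round(pi * (r_star / 1000)^2, 2)
}

#' Distance from the roost to area centroids
#'
#' @param areas A [find_foraging_areas()] tibble.
#' @param roost_xy Roost planar coordinates `c(x, y)`.
#' @return Numeric vector of planar distances in km.
#' @export
roost_distance <- function(areas, roost_xy) {
  sqrt((areas$centroid_x - roost_xy[1])^2 +
       (areas$centroid_y - roost_xy[2])^2) / 1000
}

#' Search-time effort of areas
#'
#' @param areas A [find_foraging_areas()] tibble.
#' @return Summed member-segment durations, hours.
#' @export
search_time <- function(areas) {
  areas$search_time_h
}

#' Assign habitat by majority land cover
#'
#' Each area's habitat is the land-cover class under the majority of its
#' member fixes; ties break by the fixed priority shrubland > forest >
#' farmland.  Fixes outside the raster are excluded from the vote; if all
#' fall outside, the habitat stays `NA` with a warning.
#'
#' @param areas A [find_foraging_areas()] tibble.
#' @param track The corresponding projected track.
#' @param landcover A categorical [grid_raster()] with class levels.
#' @return The areas tibble with `habitat` filled.
#' @export
assign_habitat <- function(areas, track, landcover) {
  stopifnot(inherits(landcover, "grid_raster"), !is.null(landcover$levels))
  fx <- track$fixes[track$fixes$valid, ]
  for (k in seq_len(nrow(areas))) {
    idx <- areas$member_fixes[[k]]
    v <- raster_extract(landcover, fx$x[idx], fx$y[idx])
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("area ", areas$area[k], " of track ", areas$track[k],
              ": all member fixes outside the land-cover raster")
      next
    }
    counts <- vapply(seq_along(landcover$levels),
                     function(i) sum(v == i), numeric(1))
    areas$habitat[k] <- landcover$levels[which.max(counts)]
  }
  areas
}

#' Summarize foraging areas by habitat
#'
#' Counts and fractions per habitat plus mean +/- SD of roost distance, area
#' and search time, with Kruskal-Wallis tests (tie-corrected H, chi-square
#' p on groups-1 df) across habitat types when at least two habitats are
#' represented.
#'
#' @param areas Row-bound [find_foraging_areas()] tibbles (habitat assigned).
#' @return A list: `counts` tibble (habitat, n, fraction, per-variable mean
#'   and sd) and `tests` tibble (variable, H, df, p), `NULL` when fewer than
#'   two habitat groups exist.
#' @export
habitat_tests <- function(areas) {
  a <- areas[!is.na(areas$habitat), , drop = FALSE]
  if (!nrow(a)) stop("no classified areas", call. = FALSE)
  vars <- c(roost_distance_km = "roost_distance_km", area_km2 = "area_km2",
            search_time_h = "search_time_h")
  hab <- factor(a$habitat, levels = .HABITATS)
  hab <- droplevels(hab)
  counts <- do.call(rbind, lapply(levels(hab), function(h) {
    sel <- hab == h
    row <- tibble::tibble(habitat = h, n = sum(sel),
                          fraction = mean(hab == h))
    for (vn in names(vars)) {
      row[[paste0(vn, "_mean")]] <- mean(a[[vars[[vn]]]][sel])
      row[[paste0(vn, "_sd")]] <- stats::sd(a[[vars[[vn]]]][sel])
    }
    row
  }))
  tests <- NULL
  if (nlevels(hab) >= 2) {
    tests <- do.call(rbind, lapply(names(vars), function(vn) {
      kt <- stats::kruskal.test(a[[vars[[vn]]]], hab)
      tibble::tibble(variable = vn, H = unname(kt$statistic),
                     df = unname(kt$parameter), p = kt$p.value)
    }))
  }
  list(counts = counts, tests = tests)
}

#' Per-track night summary
#'
#' Total distance, overall mean speed, trip and area counts, and the split
#' of moving time into commuting vs foraging.  "Moving time" is the elapsed
#' time inside trips, excluding inter-trip roost dwells; CF/FF times are
#' computed per trip from the fix labels (the step between fixes i and i+1
#' counts toward fix i's mode) so they sum exactly to moving time.
#' Fractions over the whole night span (dwells included) are also reported.
#'
#' @param track A projected, filtered [new_track()].
#' @param labels Per-fix mode labels from [classify_modes()].
#' @param trips A [split_trips()] tibble.
#' @param areas A [find_foraging_areas()] tibble.
#' @return A one-row tibble of night statistics.
#' @export
night_summary <- function(track, labels, trips, areas) {
  fx <- track$fixes[track$fixes$valid, ]
  tt <- as.numeric(fx$timestamp)
  step_m <- sqrt(diff(fx$x)^2 + diff(fx$y)^2)
  cf_s <- ff_s <- 0
  for (k in seq_len(nrow(trips))) {
    i0 <- trips$start_fix[k]; i1 <- trips$end_fix[k]
    if (i1 == i0) next
    for (i in i0:(i1 - 1)) {
      dt <- tt[i + 1] - tt[i]
      if (labels[i] == "CF") cf_s <- cf_s + dt else ff_s <- ff_s + dt
    }
  }
  moving_h <- (cf_s + ff_s) / 3600
  night_h <- (tt[length(tt)] - tt[1]) / 3600
  main_h <- if (nrow(areas)) max(areas$search_time_h) else 0
  tibble::tibble(
    track = track$id,
    n_fixes = nrow(fx),
    total_distance_km = sum(step_m) / 1000,
    mean_speed_ms = sum(step_m) / (tt[length(tt)] - tt[1]),
    n_trips = nrow(trips),
    n_areas = nrow(areas),
    cf_time_h = cf_s / 3600,
    ff_time_h = ff_s / 3600,
    moving_time_h = moving_h,
    cf_frac_moving = if (moving_h > 0) cf_s / 3600 / moving_h else NA_real_,
    ff_frac_moving = if (moving_h > 0) ff_s / 3600 / moving_h else NA_real_,
    cf_frac_night = if (night_h > 0) cf_s / 3600 / night_h else NA_real_,
    main_area_time_h = main_h,
    main_area_frac_ff = if (ff_s > 0) main_h / (ff_s / 3600) else NA_real_
  )
}

#' Export foraging areas as GeoJSON circle polygons
#'
#' @param areas Row-bound [find_foraging_areas()] tibbles.
#' @param frame A [utm_frame()] for exporting to lon/lat.
#' @param path Output path.
#' @param n_vertices Circle discretization (default 64).
#' @return `path`, invisibly.
#' @export
write_areas_geojson <- function(areas, frame, path, n_vertices = 64) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)
  feats <- lapply(seq_len(nrow(areas)), function(k) {
    px <- areas$centroid_x[k] + areas$r_star_m[k] * cos(ang)
    py <- areas$centroid_y[k] + areas$r_star_m[k] * sin(ang)
    ll <- xy_to_lonlat(px, py, frame)
    list(type = "Feature",
         properties = list(track = areas$track[k], area = areas$area[k],
                           r_star_m = areas$r_star_m[k],
                           area_km2 = areas$area_km2[k],
                           roost_distance_km = areas$roost_distance_km[k],
                           search_time_h = areas$search_time_h[k],
                           habitat = areas$habitat[k]),
         geometry = list(type = "Polygon",
                         coordinates = list(Map(c, ll$lon, ll$lat))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = 9)
  invisible(path)
}
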