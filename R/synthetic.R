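# Synthetic central-place-forager nights: a two-mode composite correlated
# random walk (fast, directed commuting; slow, tortuous within-patch
# foraging) sampled through a GPS duty-cycle / error / dropout model, plus
# matching categorical land-cover and smooth elevation rasters.  Every
# downstream stage of the package is validated against the ground truth
# these functions emit.
#
# The simulation frame is planar with the roost at the origin; export to
# longitude/latitude goes through the declared UTM frame in the config.

.HABITATS <- c("shrubland", "forest", "farmland")

#' Specify a foraging patch
#'
#' @param center Numeric length-2, patch centre in metres (roost at origin).
#' @param radius Patch radius in metres (> 0); the field-typical window is
#'   300-500 m.
#' @param habitat One of `"shrubland"`, `"forest"`, `"farmland"`.
#' @return A `patch_spec` list.
#' @export
patch_spec <- function(center, radius, habitat = "shrubland") {
  stopifnot(length(center) == 2, is.finite(center))
  if (!is.numeric(radius) || radius <= 0)
    stop("patch radius must be > 0", call. = FALSE)
  habitat <- match.arg(habitat, .HABITATS)
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 habitat = habitat), class = "patch_spec")
}

#' Simulation configuration for one night
#'
#' Defaults emulate a lactating nectar-feeding bat commuting from a maternity
#' roost in central Mexico to flower patches 13-40 km away: fixes every
#' 10 min from 20:30 to 05:30 local time, commuting at ~7 m/s, foraging at
#' ~1.5 m/s inside patches of 300-500 m radius, 1-3 round trips separated by
#' 30-90 min roost dwells, and ~47% fix failure.
#'
#' @param roost_lon,roost_lat Roost position, degrees WGS84.
#' @param crs Declared projected frame (`"EPSG:326zz"`/`"EPSG:327zz"`).
#' @param date Calendar date (local) on which the night starts.
#' @param night_start,night_end Local clock times, `"HH:MM"`.
#' @param utc_offset Hours to add to UTC to obtain local time (default -6).
#' @param fix_interval GPS schedule interval, minutes (10 or 15).
#' @param n_trips Number of roost-to-roost round trips (1-3).
#' @param patches List of [patch_spec()]; centres in metres, roost at origin.
#' @param trip_patches List of length `n_trips`; element i is the ordered
#'   integer vector of patch indices visited on trip i.
#' @param commute_speed_mean,commute_speed_sd Commuting speed, m/s.
#' @param forage_speed_mean,forage_speed_sd Foraging speed, m/s.
#' @param commute_turn_concentration,forage_turn_concentration Dimensionless
#'   directional-persistence parameters; per-second turning angles are drawn
#'   with standard deviation `1/sqrt(concentration)` radians.
#' @param roost_dwell_range Inter-trip roost dwell duration range, minutes.
#' @param forage_time_mean,forage_time_sd Total nightly foraging time, hours
#'   (normal draw truncated to what the night can hold); the remainder of
#'   the night after the last return is spent inside the roost.
#' @param dropout_prob Probability that a scheduled airborne fix is invalid.
#'   Fixes scheduled while the bat is inside the roost are always invalid
#'   (the logger cannot see satellites indoors), so the whole-night invalid
#'   fraction slightly exceeds this value.
#' @param position_error_sd Isotropic Gaussian GPS error, metres.
#' @param min_forage_min Minimum duration allocated to a patch visit, minutes.
#' @param speed_floor Lower truncation bound for drawn speeds, m/s.
#' @param individual_id Four-digit track code (year + bat number).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(roost_lon = -98.60, roost_lat = 20.40,
                       crs = "EPSG:32614",
                       date = "2022-05-15",
                       night_start = "20:30", night_end = "05:30",
                       utc_offset = -6,
                       fix_interval = 10,
                       n_trips = 1,
                       patches = list(patch_spec(c(0, 16000), 400, "shrubland")),
                       trip_patches = NULL,
                       commute_speed_mean = 7, commute_speed_sd = 1.7,
                       forage_speed_mean = 1.5, forage_speed_sd = 1.0,
                       commute_turn_concentration = 50,
                       forage_turn_concentration = 2,
                       roost_dwell_range = c(30, 90),
                       forage_time_mean = 2.65, forage_time_sd = 1.12,
                       dropout_prob = 0.47,
                       position_error_sd = 20,
                       min_forage_min = 35,
                       speed_floor = 0.1,
                       individual_id = "2201") {
  if (!length(patches)) stop("patches must be nonempty", call. = FALSE)
  if (!(commute_speed_mean > forage_speed_mean))
    stop("commute_speed_mean must exceed forage_speed_mean", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)", call. = FALSE)
  if (fix_interval <= 0) stop("fix_interval must be > 0", call. = FALSE)
  if (n_trips < 1) stop("n_trips must be >= 1", call. = FALSE)
  if (is.null(trip_patches)) trip_patches <- default_visit_plan(
    length(patches), n_trips)
  if (length(trip_patches) != n_trips)
    stop("trip_patches must have one element per trip", call. = FALSE)
  idx <- unlist(trip_patches)
  if (any(idx < 1 | idx > length(patches)))
    stop("trip_patches refers to a patch that does not exist", call. = FALSE)
  frame <- utm_frame(crs)
  roost_xy <- lonlat_to_xy(roost_lon, roost_lat, frame)
  cfg <- list(
    roost_lon = roost_lon, roost_lat = roost_lat, crs = crs,
    roost_easting = roost_xy$x, roost_northing = roost_xy$y,
    date = date, night_start = night_start, night_end = night_end,
    utc_offset = utc_offset, fix_interval = fix_interval,
    n_trips = as.integer(n_trips), patches = patches,
    trip_patches = lapply(trip_patches, as.integer),
    commute_speed_mean = commute_speed_mean,
    commute_speed_sd = commute_speed_sd,
    forage_speed_mean = forage_speed_mean,
    forage_speed_sd = forage_speed_sd,
    commute_turn_concentration = commute_turn_concentration,
    forage_turn_concentration = forage_turn_concentration,
    roost_dwell_range = roost_dwell_range,
    forage_time_mean = forage_time_mean, forage_time_sd = forage_time_sd,
    dropout_prob = dropout_prob,
    position_error_sd = position_error_sd, min_forage_min = min_forage_min,
    speed_floor = speed_floor, individual_id = individual_id
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Default patch visit plan
#'
#' Patches are spread over trips in order: with at least as many patches as
#' trips, each trip takes a consecutive chunk; with fewer patches than
#' trips, the spare trips revisit the main patch (patch 1), emulating
#' revisits of one dominant foraging area across a night.
#'
#' @param n_patches,n_trips Counts.
#' @return List of integer vectors, one per trip.
#' @export
default_visit_plan <- function(n_patches, n_trips) {
  if (n_patches >= n_trips) {
    cut_idx <- sort(rep_len(seq_len(n_trips), n_patches))
    unname(split(seq_len(n_patches), cut_idx))
  } else {
    c(lapply(seq_len(n_patches), identity),
      rep(list(1L), n_trips - n_patches))
  }
}

# Night timing helpers ------------------------------------------------------

.hm_to_sec <- function(hm) {
  p <- as.numeric(strsplit(hm, ":")[[1]])
  p[1] * 3600 + p[2] * 60
}

#' Night duration in seconds (start to end of the GPS schedule)
#' @param config A [sim_config()].
#' @return Number of seconds from `night_start` to `night_end`.
#' @export
night_seconds <- function(config) {
  s <- .hm_to_sec(config$night_start)
  e <- .hm_to_sec(config$night_end)
  if (e <= s) e <- e + 86400
  e - s
}

#' UTC timestamp of the start of the night
#' @param config A [sim_config()].
#' @return A `POSIXct` in UTC.
#' @export
night_start_utc <- function(config) {
  local <- as.POSIXct(paste(config$date, config$night_start), tz = "UTC")
  local - config$utc_offset * 3600
}

# Movement primitives -------------------------------------------------------

.trunc_speeds <- function(n, mean, sd, floor) {
  v <- stats::rnorm(n, mean, sd)
  while (any(bad <- v < floor)) v[bad] <- stats::rnorm(sum(bad), mean, sd)
  v
}

# Directed correlated walk toward a target; returns an n x 2 position matrix
# (1-s steps), stopping once within stop_dist of the target.  Headings are
# re-biased toward the target in short chunks so persistence stays high while
# the walk homes in.
.walk_commute <- function(pos, target, cfg, stop_dist, max_steps) {
  turn_sd <- 1 / sqrt(cfg$commute_turn_concentration)
  xs <- numeric(max_steps); ys <- numeric(max_steps)
  n <- 0L; x <- pos[1]; y <- pos[2]
  repeat {
    dx <- target[1] - x; dy <- target[2] - y
    d <- sqrt(dx * dx + dy * dy)
    if (d <= stop_dist || n >= max_steps) break
    chunk <- max(1L, min(30L, as.integer(d / (2 * cfg$commute_speed_mean))))
    h <- atan2(dy, dx) + stats::rnorm(chunk, 0, turn_sd)
    v <- .trunc_speeds(chunk, cfg$commute_speed_mean, cfg$commute_speed_sd,
                       cfg$speed_floor)
    take <- min(chunk, max_steps - n)
    xs[n + seq_len(take)] <- x + cumsum(v * cos(h))[seq_len(take)]
    ys[n + seq_len(take)] <- y + cumsum(v * sin(h))[seq_len(take)]
    n <- n + take
    x <- xs[n]; y <- ys[n]
  }
  cbind(xs[seq_len(n)], ys[seq_len(n)])
}

# Tortuous walk confined to a patch circle; positions are reflected radially
# back inside when a step crosses the boundary.
.walk_forage <- function(pos, heading, patch, cfg, n_steps) {
  if (n_steps <= 0) return(cbind(numeric(0), numeric(0)))
  turn_sd <- 1 / sqrt(cfg$forage_turn_concentration)
  dh <- stats::rnorm(n_steps, 0, turn_sd)
  v <- .trunc_speeds(n_steps, cfg$forage_speed_mean, cfg$forage_speed_sd,
                     cfg$speed_floor)
  xs <- numeric(n_steps); ys <- numeric(n_steps)
  x <- pos[1]; y <- pos[2]; h <- heading
  cx <- patch$center[1]; cy <- patch$center[2]; R <- patch$radius
  for (i in seq_len(n_steps)) {
    h <- h + dh[i]
    nx <- x + v[i] * cos(h); ny <- y + v[i] * sin(h)
    ddx <- nx - cx; ddy <- ny - cy
    d2 <- ddx * ddx + ddy * ddy
    if (d2 > R * R) {
      d <- sqrt(d2)
      fold <- (2 * R - d) / d
      nx <- cx + ddx * fold; ny <- cy + ddy * fold
      h <- atan2(cy - ny, cx - nx) + stats::rnorm(1, 0, 0.5)
    }
    xs[i] <- nx; ys[i] <- ny
    x <- nx; y <- ny
  }
  cbind(xs, ys)
}

#' Simulate one night of central-place foraging
#'
#' Produces a continuous 1-s resolution path starting and ending at the roost
#' together with per-second ground-truth labels (state, trip index, patch).
#' Each trip is ROOST -> COMMUTE -> (FORAGE / COMMUTE ...) -> ROOST; roost
#' dwells between trips are stationary.  The same `(config, seed)` pair is
#' bit-reproducible.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `sim_night` with elements `path` (tibble:
#'   `time_s`, `x`, `y`; metres, roost at origin), `truth` (tibble: `time_s`,
#'   `state` in ROOST/COMMUTE/FORAGE, `trip`, `patch`), and `config`.
#' @export
simulate_night <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cfg <- config
  N <- night_seconds(cfg)
  cs <- cfg$commute_speed_mean

  # feasibility: every patch must be reachable out-and-back within the night
  for (i in seq_along(cfg$patches)) {
    d <- sqrt(sum(cfg$patches[[i]]$center^2))
    if (2 * d / cs > N)
      stop("patch ", i, " is unreachable within the night (round trip ",
           round(2 * d / cs / 3600, 1), " h of commuting)", call. = FALSE)
  }

  # time budget: commuting estimated with a tortuosity margin, dwells drawn
  # up front, the remainder split across patch visits (main patch weighted
  # heaviest, emulating one dominant foraging area per night)
  dwell_s <- if (cfg$n_trips > 1)
    round(stats::runif(cfg$n_trips - 1, cfg$roost_dwell_range[1],
                       cfg$roost_dwell_range[2]) * 60) else numeric(0)
  legs <- list()
  for (tr in seq_len(cfg$n_trips)) {
    seqi <- cfg$trip_patches[[tr]]
    pts <- lapply(cfg$patches[seqi], `[[`, "center")
    way <- c(list(c(0, 0)), pts, list(c(0, 0)))
    legs[[tr]] <- vapply(seq_len(length(way) - 1), function(k)
      sqrt(sum((way[[k + 1]] - way[[k]])^2)), numeric(1))
  }
  commute_est <- sum(unlist(legs)) / cs * 1.15
  visits <- unlist(lapply(seq_len(cfg$n_trips), function(tr)
    lapply(cfg$trip_patches[[tr]], function(p) c(tr, p))), recursive = FALSE)
  nv <- length(visits)
  budget <- N - commute_est - sum(dwell_s) - 120
  if (budget < nv * cfg$min_forage_min * 60)
    stop("night too short to forage at all scheduled patch visits",
         call. = FALSE)
  w <- vapply(visits, function(v) if (v[2] == 1L) 4 else 1, numeric(1))
  w <- w * stats::runif(nv, 0.8, 1.25)
  total_forage <- stats::rnorm(1, cfg$forage_time_mean * 3600,
                               cfg$forage_time_sd * 3600)
  total_forage <- min(max(total_forage, nv * cfg$min_forage_min * 60),
                      0.95 * budget)
  forage_s <- round(total_forage * w / sum(w))
  forage_s <- pmax(forage_s, cfg$min_forage_min * 60)

  # assemble the path phase by phase
  chunks <- list(); nch <- 0L
  add <- function(xy, state, trip, patch) {
    if (!nrow(xy)) return(invisible(NULL))
    nch <<- nch + 1L
    chunks[[nch]] <<- list(xy = xy, state = state, trip = trip, patch = patch)
    invisible(NULL)
  }
  pos <- c(0, 0); heading <- pi / 2; t_now <- 0
  add(cbind(0, 0), "COMMUTE", 1L, NA_integer_)  # departure instant, t = 0
  t_now <- 1
  vi <- 0L
  legv <- unlist(legs)
  li <- 0L  # commute legs already flown
  for (tr in seq_len(cfg$n_trips)) {
    for (p in cfg$trip_patches[[tr]]) {
      vi <- vi + 1L
      patch <- cfg$patches[[p]]
      xy <- .walk_commute(pos, patch$center, cfg, stop_dist = patch$radius,
                          max_steps = 4 * N)
      li <- li + 1L
      add(xy, "COMMUTE", tr, NA_integer_)
      if (nrow(xy)) {
        heading <- atan2(xy[nrow(xy), 2] - pos[2], xy[nrow(xy), 1] - pos[1])
        pos <- xy[nrow(xy), ]
        t_now <- t_now + nrow(xy)
      }
      # shrink the visit if commuting ran over its estimate, keeping the
      # later visits' allocations and all remaining legs/dwells reserved
      remaining_est <- sum(legv[-seq_len(li)]) / cs * 1.25
      later_forage <- if (vi < nv) sum(forage_s[(vi + 1):nv]) else 0
      cap <- N - t_now - remaining_est - later_forage -
        sum(dwell_s[seq_len(cfg$n_trips - 1) >= tr])
      steps <- max(0, min(forage_s[vi], floor(cap)))
      xy <- .walk_forage(pos, heading, patch, cfg, steps)
      add(xy, "FORAGE", tr, p)
      if (nrow(xy)) {
        pos <- xy[nrow(xy), ]
        t_now <- t_now + nrow(xy)
      }
    }
    xy <- .walk_commute(pos, c(0, 0), cfg, stop_dist = cs, max_steps = 4 * N)
    xy <- rbind(xy, c(0, 0))  # final sub-step snap onto the roost
    li <- li + 1L
    add(xy, "COMMUTE", tr, NA_integer_)
    pos <- c(0, 0)
    t_now <- t_now + nrow(xy)
    if (tr < cfg$n_trips) {
      ns <- dwell_s[tr]
      add(cbind(rep(0, ns), rep(0, ns)), "ROOST", NA_integer_, NA_integer_)
      t_now <- t_now + ns
    }
  }
  if (t_now <= N) {
    ns <- N - t_now + 1
    add(cbind(rep(0, ns), rep(0, ns)), "ROOST", NA_integer_, NA_integer_)
  }

  xy <- do.call(rbind, lapply(chunks, `[[`, "xy"))
  n <- nrow(xy)
  path <- tibble::tibble(time_s = seq_len(n) - 1, x = xy[, 1], y = xy[, 2])
  truth <- tibble::tibble(
    time_s = path$time_s,
    state = rep(vapply(chunks, `[[`, character(1), "state"),
                vapply(chunks, function(c) nrow(c$xy), integer(1))),
    trip = rep(vapply(chunks, `[[`, integer(1), "trip"),
               vapply(chunks, function(c) nrow(c$xy), integer(1))),
    patch = rep(vapply(chunks, `[[`, integer(1), "patch"),
                vapply(chunks, function(c) nrow(c$xy), integer(1)))
  )
  structure(list(path = path, truth = truth, config = cfg),
            class = "sim_night")
}

#' Sample a simulated night through the GPS duty cycle
#'
#' One fix per schedule slot (`night_start` to `night_end` inclusive, every
#' `fix_interval` minutes).  Fixes scheduled during roost dwells are invalid
#' (the device is indoors); airborne fixes are invalid independently with
#' probability `dropout_prob`.  Valid fixes are the true position plus
#' isotropic Gaussian error, exported to lon/lat through the declared frame.
#'
#' @param night A `sim_night` from [simulate_night()].
#' @param seed Integer seed (independent of the path seed).
#' @return A tibble in Movebank-style columns (`timestamp`, `location-long`,
#'   `location-lat`, `individual-local-identifier`, `fix-status`) plus
#'   ground-truth annotation columns `true-state`, `true-trip`, `true-patch`.
#' @export
sample_gps <- function(night, seed) {
  stopifnot(inherits(night, "sim_night"))
  cfg <- night$config
  set.seed(as.integer(seed))
  N <- night_seconds(cfg)
  slots <- seq(0, N, by = cfg$fix_interval * 60)
  if (max(night$path$time_s) < N)
    stop("path does not cover the scheduled window", call. = FALSE)
  idx <- slots + 1  # 1-s path rows are time_s = row - 1
  st <- night$truth$state[idx]
  valid <- st != "ROOST" & stats::runif(length(slots)) >= cfg$dropout_prob
  ex <- night$path$x[idx] + stats::rnorm(length(slots), 0, cfg$position_error_sd)
  ey <- night$path$y[idx] + stats::rnorm(length(slots), 0, cfg$position_error_sd)
  frame <- utm_frame(cfg$crs)
  ll <- xy_to_lonlat(cfg$roost_easting + ex, cfg$roost_northing + ey, frame)
  lon <- ifelse(valid, ll$lon, NA_real_)
  lat <- ifelse(valid, ll$lat, NA_real_)
  tibble::tibble(
    timestamp = night_start_utc(cfg) + slots,
    `location-long` = lon,
    `location-lat` = lat,
    `individual-local-identifier` = cfg$individual_id,
    `fix-status` = ifelse(valid, "valid", "invalid"),
    `true-state` = st,
    `true-trip` = night$truth$trip[idx],
    `true-patch` = night$truth$patch[idx]
  )
}

# Rasters -------------------------------------------------------------------

#' Generate a categorical land-cover raster
#'
#' Cells whose centre falls inside a patch circle take the patch habitat
#' class; all other cells take the background class.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres (simulation frame).
#' @param patches List of [patch_spec()].
#' @param background_class Background habitat class.
#' @param cell_size Cell edge, metres.
#' @param seed Accepted for interface symmetry; the raster is deterministic.
#' @return A [grid_raster()] with `levels = c("shrubland","forest","farmland")`
#'   and cell values that index into it.
#' @export
generate_landcover <- function(extent, patches, background_class = "shrubland",
                               cell_size = 50, seed = 0) {
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  background_class <- match.arg(background_class, .HABITATS)
  for (p in patches) {
    if (p$center[1] - p$radius < extent[1] ||
        p$center[1] + p$radius > extent[2] ||
        p$center[2] - p$radius < extent[3] ||
        p$center[2] + p$radius > extent[4])
      stop("extent does not contain all patches", call. = FALSE)
  }
  nc <- ceiling((extent[2] - extent[1]) / cell_size)
  nr <- ceiling((extent[4] - extent[3]) / cell_size)
  xc <- extent[1] + (seq_len(nc) - 0.5) * cell_size
  yc <- extent[3] + (seq_len(nr) - 0.5) * cell_size  # bottom to top
  v <- matrix(match(background_class, .HABITATS), nrow = nr, ncol = nc)
  for (p in patches) {
    code <- match(p$habitat, .HABITATS)
    dx2 <- outer(rep(1, nr), (xc - p$center[1])^2)
    dy2 <- outer((yc - p$center[2])^2, rep(1, nc))
    v[dx2 + dy2 <= p$radius^2] <- code
  }
  grid_raster(v[nr:1, , drop = FALSE], extent[1], extent[3], cell_size,
              levels = .HABITATS)
}

#' Generate a smooth seeded elevation raster
#'
#' A sum of low-frequency cosine ridges over a base elevation, emulating
#' gentle highland relief; deterministic under the seed.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size Cell edge, metres.
#' @param base Base elevation, metres above sea level.
#' @param amplitude Total relief amplitude scale, metres.
#' @param n_waves Number of cosine components.
#' @param seed Integer seed.
#' @return A [grid_raster()] of elevations in metres.
#' @export
generate_elevation <- function(extent, cell_size = 100, base = 1900,
                               amplitude = 120, n_waves = 6, seed = 0) {
  if (cell_size <= 0) stop("cell_size must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  nc <- ceiling((extent[2] - extent[1]) / cell_size)
  nr <- ceiling((extent[4] - extent[3]) / cell_size)
  xc <- extent[1] + (seq_len(nc) - 0.5) * cell_size
  yc <- extent[3] + (seq_len(nr) - 0.5) * cell_size
  wl <- stats::runif(n_waves, 5e3, 3e4)      # wavelengths 5-30 km
  th <- stats::runif(n_waves, 0, 2 * pi)     # ridge orientations
  ph <- stats::runif(n_waves, 0, 2 * pi)
  a <- amplitude * stats::runif(n_waves, 0.3, 1) / n_waves
  v <- matrix(base, nrow = nr, ncol = nc)
  X <- outer(rep(1, nr), xc)
  Y <- outer(yc, rep(1, nc))
  for (k in seq_len(n_waves))
    v <- v + a[k] * cos(2 * pi * (X * cos(th[k]) + Y * sin(th[k])) / wl[k] + ph[k])
  grid_raster(v[nr:1, , drop = FALSE], extent[1], extent[3], cell_size)
}

# Cohort generation ---------------------------------------------------------

#' Draw a random night configuration from the study conditions
#'
#' Trip counts follow an emulated 10/8/3 split over one/two/three trips;
#' patch distances are right-skewed over 13-40 km north of the roost; patch
#' radii are uniform on 300-500 m; habitats follow an emulated 46/27/27
#' shrubland/forest/farmland mix.  2021-style tracks (ids `21xx`) use the
#' 15-min schedule from 20:00, 2022-style tracks (`22xx`) the 10-min schedule
#' from 20:30.
#'
#' @param individual_id Four-digit track code; the first two digits choose
#'   the schedule.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
random_night_config <- function(individual_id = "2201", seed = 1, ...) {
  set.seed(as.integer(seed))
  n_trips <- sample(1:3, 1, prob = c(10, 8, 3) / 21)
  n_patches <- sample(1:3, 1, prob = c(0.50, 0.35, 0.15))
  dist <- 13000 + 27000 * stats::rbeta(n_patches, 1, 3)
  brg <- stats::runif(n_patches, -60, 60) * pi / 180  # sector north of roost
  radius <- stats::runif(n_patches, 300, 500)
  habitat <- sample(.HABITATS, n_patches, replace = TRUE,
                    prob = c(0.46, 0.27, 0.27))
  is_2021 <- startsWith(individual_id, "21")
  build <- function(dist) {
    patches <- lapply(seq_along(dist), function(i)
      patch_spec(c(dist[i] * sin(brg[i]), dist[i] * cos(brg[i])),
                 radius[i], habitat[i]))
    sim_config(
      individual_id = individual_id,
      n_trips = n_trips, patches = patches,
      fix_interval = if (is_2021) 15 else 10,
      night_start = if (is_2021) "20:00" else "20:30",
      ...
    )
  }
  # the night has a fixed time budget: a plan whose commuting (with
  # tortuosity margin), worst-case roost dwells and minimum patch visits
  # cannot fit is not one a bat would fly.  Drop the farthest extra patch,
  # then pull patches closer, until the night is feasible -- mirroring the
  # behaviour that nights with more trips stay closer to the roost.
  repeat {
    cfg <- build(dist)
    if (.night_feasible(cfg)) return(cfg)
    if (length(dist) > 1) {
      keep <- -which.max(dist)
      dist <- dist[keep]; brg <- brg[keep]
      radius <- radius[keep]; habitat <- habitat[keep]
      n_patches <- length(dist)
    } else {
      dist <- pmax(13000, dist * 0.85)
      if (dist <= 13000 && !.night_feasible(build(dist)))
        n_trips <- n_trips - 1L  # cannot occur for <= 3 trips at 13 km
    }
  }
}

# worst-case budget check mirroring simulate_night's allocation
.night_feasible <- function(cfg) {
  N <- night_seconds(cfg)
  legs <- 0
  for (tr in seq_len(cfg$n_trips)) {
    way <- c(list(c(0, 0)), lapply(cfg$patches[cfg$trip_patches[[tr]]],
                                   `[[`, "center"), list(c(0, 0)))
    for (k in seq_len(length(way) - 1))
      legs <- legs + sqrt(sum((way[[k + 1]] - way[[k]])^2))
  }
  commute_est <- legs / cfg$commute_speed_mean * 1.15
  dwell_max <- (cfg$n_trips - 1) * cfg$roost_dwell_range[2] * 60
  n_visits <- length(unlist(cfg$trip_patches))
  commute_est + dwell_max + n_visits * cfg$min_forage_min * 60 + 120 <= N
}

#' Simulate a cohort of one-night tracks
#'
#' @param n_nights Number of individual-nights (default 21: five 15-min
#'   schedule tracks and sixteen 10-min schedule tracks).
#' @param seed Integer master seed; per-night seeds are derived from it.
#' @param ... Overrides passed to [random_night_config()]/[sim_config()].
#' @return A list with one element per night: `night` (the `sim_night`),
#'   `fixes` (the sampled GPS tibble) and `config`.
#' @export
simulate_cohort <- function(n_nights = 21, seed = 1, ...) {
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1, 3 * n_nights)
  n21 <- if (n_nights == 21) 5 else round(n_nights * 5 / 21)
  ids <- c(sprintf("21%02d", seq_len(n21)),
           sprintf("22%02d", seq_len(n_nights - n21)))
  out <- vector("list", n_nights)
  for (i in seq_len(n_nights)) {
    cfg <- random_night_config(individual_id = ids[i],
                               seed = seeds[3 * i - 2], ...)
    night <- simulate_night(cfg, seeds[3 * i - 1])
    fixes <- sample_gps(night, seeds[3 * i])
    out[[i]] <- list(night = night, fixes = fixes, config = cfg)
  }
  names(out) <- ids
  out
}

# Text serialization --------------------------------------------------------

#' Write fixes as Movebank-style CSV
#'
#' Only the five standard columns are written; ground-truth annotation
#' columns, if present, are dropped.
#'
#' @param fixes A tibble from [sample_gps()] (or several row-bound together).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixes_csv <- function(fixes, path) {
  keep <- c("timestamp", "location-long", "location-lat",
            "individual-local-identifier", "fix-status")
  df <- as.data.frame(fixes[, keep])
  df$timestamp <- format(fixes$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  df$`location-long` <- sprintf("%.9f", df$`location-long`)
  df$`location-lat` <- sprintf("%.9f", df$`location-lat`)
  df$`location-long`[is.na(fixes$`location-long`)] <- ""
  df$`location-lat`[is.na(fixes$`location-lat`)] <- ""
  names(df) <- keep
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-fix ground truth as CSV
#'
#' @param fixes A tibble from [sample_gps()] (with truth columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(fixes, path) {
  df <- data.frame(
    timestamp = format(fixes$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    state = fixes$`true-state`,
    trip = fixes$`true-trip`,
    patch = fixes$`true-patch`,
    check.names = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation config as YAML
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$patches <- lapply(x$patches, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}
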