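# Shared fixtures: all synthetic, built in code at test time.

TEST_FRAME <- utm_frame("EPSG:32614")
TEST_ROOST <- {
  xy <- lonlat_to_xy(-98.60, 20.40, TEST_FRAME)
  c(xy$x, xy$y)
}

# planar track straight from coordinates (lon/lat unused by planar stages)
make_track <- function(x, y, t_sec, id = "t1", elevation = NA_real_) {
  new_track(id, tibble::tibble(
    timestamp = as.POSIXct(t_sec, origin = "2022-05-16", tz = "UTC"),
    lon = 0, lat = 0, valid = TRUE, x = x, y = y, elevation = elevation))
}

# straight east-bound constant-speed track
straight_track <- function(n = 12, v = 7, dt = 600) {
  tt <- (seq_len(n) - 1) * dt
  make_track(x = tt * v, y = rep(0, n), t_sec = tt)
}

# seeded random-walk track for oracle comparisons
random_track <- function(seed, n_min = 8, n_max = 16, step_sd = 400) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  tt <- cumsum(c(0, round(stats::runif(n - 1, 300, 900))))
  make_track(x = cumsum(c(0, stats::rnorm(n - 1, 0, step_sd))),
             y = cumsum(c(0, stats::rnorm(n - 1, 0, step_sd))),
             t_sec = tt)
}

# brute-force FPT oracle: dense 1-s linear resampling + index scan
oracle_passage <- function(track, i, r) {
  fx <- track$fixes[track$fixes$valid, ]
  tt <- as.numeric(fx$timestamp); tt <- tt - tt[1]
  ts <- seq(0, tt[length(tt)])
  dx <- stats::approx(tt, fx$x, ts)$y
  dy <- stats::approx(tt, fx$y, ts)$y
  ci <- which(ts == tt[i])
  d <- sqrt((dx - dx[ci])^2 + (dy - dy[ci])^2)
  fw <- which(d[ci:length(ts)] > r)
  bw <- which(rev(d[1:ci]) > r)
  c(if (length(fw)) fw[1] - 1 else NA_real_,
    if (length(bw)) bw[1] - 1 else NA_real_)
}

# simulate one night and return the analysis-ready track plus its raw fixes
sim_track <- function(cfg, seed_night, seed_gps) {
  night <- simulate_night(cfg, seed_night)
  fixes <- sample_gps(night, seed_gps)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_fixes_csv(fixes, path)
  tr <- read_fixes(path)[[1]]
  tr <- suppressWarnings(filter_track(tr))
  tr <- project_track(tr, TEST_FRAME)
  list(track = tr, fixes = fixes, night = night)
}

# small single-patch night used by most integration tests
quick_config <- function(dropout_prob = 0.3, ...) {
  sim_config(n_trips = 1,
             patches = list(patch_spec(c(0, 15000), 400, "shrubland")),
             dropout_prob = dropout_prob, ...)
}

# validation configuration for scale-recovery experiments: one patch, one
# trip, foraging long enough that the night's search fills the whole patch
scale_config <- function(...) {
  sim_config(n_trips = 1,
             patches = list(patch_spec(c(0, 16000), 400, "shrubland")),
             dropout_prob = 0.3, forage_time_mean = 6.5, forage_time_sd = 0.5,
             ...)
}
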