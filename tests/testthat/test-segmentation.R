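fake_series <- function(t_min) {
  s <- tibble::tibble(fix = seq_along(t_min), forward_min = NA_real_,
                      backward_min = NA_real_, t_min = t_min)
  class(s) <- c("fpt_series", class(s))
  s
}

test_that("log-FPT thresholding follows the declared rules", {
  thr <- 2.7141
  ser <- fake_series(exp(c(2.80, 2.60, thr, 2.9)))
  expect_equal(classify_modes(ser, thr), c("FF", "CF", "CF", "FF"))
  # undefined fixes inherit the nearest preceding label, else the following
  ser2 <- fake_series(c(NA, exp(2.8), NA, exp(2.6), NA))
  expect_equal(classify_modes(ser2, thr), c("FF", "FF", "FF", "CF", "CF"))
  expect_error(classify_modes(fake_series(c(NA, NA)), thr), "no defined")
  # raising the threshold never converts CF to FF
  set.seed(4)
  lt <- runif(40, 1, 4.5)
  for (k in 1:10) {
    t1 <- runif(1, 1, 4.5); t2 <- t1 + runif(1, 0, 1)
    l1 <- classify_modes(fake_series(exp(lt)), t1)
    l2 <- classify_modes(fake_series(exp(lt)), t2)
    expect_false(any(l1 == "CF" & l2 == "FF"))
  }
})

test_that("segments are maximal runs partitioning the fixes", {
  tr <- straight_track(n = 5, v = 5, dt = 600)
  # final 1-fix segment has zero duration by construction; warning expected
  expect_warning(segs <- build_segments(c("CF", "CF", "FF", "FF", "CF"), tr),
                 "zero duration")
  expect_equal(nrow(segs), 3)
  expect_equal(segs$mode, c("CF", "FF", "CF"))
  expect_equal(segs$start_fix, c(1, 3, 5))
  expect_equal(segs$end_fix, c(2, 4, 5))
  # partition + alternation
  expect_equal(sum(segs$n_fixes), 5)
  expect_false(any(diff(match(segs$mode, c("CF", "FF"))) == 0))
  # all one mode -> single segment
  one <- build_segments(rep("CF", 5), tr)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_fixes, 5)
  expect_error(build_segments(c("CF", "FF"), tr), "one label per")
})

test_that("segment metrics: lengths, durations, speeds and conservation", {
  # two fixes 3000 m apart, 10 min -> 3 km, 5 m/s
  tr <- make_track(x = c(0, 3000), y = c(0, 0), t_sec = c(0, 600))
  segs <- build_segments(c("CF", "CF"), tr)
  expect_equal(segs$length_km, 3)
  expect_equal(segs$duration_h, 1 / 6)
  expect_equal(segs$speed_ms, 5)
  # step at a mode boundary belongs to the left segment; totals conserve
  for (s in 1:6) {
    st <- sim_track(quick_config(), 900 + s, 950 + s)
    fpt <- passage_times(st$track, 339)
    labels <- classify_modes(fpt)
    segs <- build_segments(labels, st$track)
    fx <- st$track$fixes
    total_km <- sum(sqrt(diff(fx$x)^2 + diff(fx$y)^2)) / 1000
    total_h <- as.numeric(max(fx$timestamp) - min(fx$timestamp),
                          units = "hours")
    expect_equal(sum(segs$length_km), total_km, tolerance = 1e-9)
    expect_equal(sum(segs$duration_h), total_h, tolerance = 1e-9)
  }
  # single-fix final segment carries no outgoing step
  tr3 <- make_track(x = c(0, 1000, 1500), y = c(0, 0, 0),
                    t_sec = c(0, 600, 1200))
  segs3 <- suppressWarnings(build_segments(c("CF", "CF", "FF"), tr3))
  expect_equal(segs3$length_km, c(1.5, 0))
})

test_that("simulated commute segments recover the configured speed", {
  # long commutes so the one boundary step into the patch barely dilutes
  # the per-segment mean
  cfg <- sim_config(n_trips = 1, dropout_prob = 0,
                    patches = list(patch_spec(c(0, 25000), 400, "shrubland")))
  speeds <- numeric(0)
  for (s in 1:6) {
    st <- sim_track(cfg, 700 + s, 750 + s)
    labels <- classify_modes(passage_times(st$track, 339))
    segs <- build_segments(labels, st$track)
    cf <- segs[segs$mode == "CF" & segs$n_fixes >= 4, ]
    speeds <- c(speeds, cf$speed_ms)
  }
  expect_equal(mean(speeds), 7, tolerance = 0.10)
})

test_that("mode labels agree with simulator ground truth", {
  acc <- numeric(0)
  for (s in 1:10) {
    st <- sim_track(quick_config(), 1100 + s, 1150 + s)
    labels <- classify_modes(passage_times(st$track, 339))
    truth <- data.frame(timestamp = st$fixes$timestamp,
                        state = st$fixes$`true-state`)
    acc <- c(acc, state_accuracy(labels, st$track, truth))
  }
  expect_gte(mean(acc), 0.9)
})

test_that("Mann-Whitney comparison matches exhaustive enumeration", {
  seg <- function(track, mode, val) tibble::tibble(
    track = track, mode = mode, length_km = val, speed_ms = val,
    mean_elevation_m = val)
  segs <- rbind(seg("a", "CF", 1), seg("b", "CF", 2),
                seg("a", "FF", 3), seg("b", "FF", 4))
  res <- compare_modes(segs)
  # enumeration oracle: all C(4,2) relabelings of the pooled values
  u_of <- function(g1, g2) sum(outer(g1, g2, ">"))
  obs_u <- u_of(c(1, 2), c(3, 4))
  devs <- apply(utils::combn(4, 2), 2, function(ix)
    abs(u_of(c(1:4)[ix], c(1:4)[-ix]) - 2))
  p_exact <- mean(devs >= abs(obs_u - 2))
  expect_equal(obs_u, 0)
  expect_equal(p_exact, 1 / 3)
  expect_equal(res$U, rep(0, 3))
  expect_equal(res$p, rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(res$method, rep("exact", 3))
  # identical groups separate nothing (ties -> enumeration convention)
  segs2 <- rbind(seg("a", "CF", 1), seg("b", "CF", 2),
                 seg("a", "FF", 1), seg("b", "FF", 2))
  res2 <- compare_modes(segs2)
  expect_equal(res2$p, rep(1, 3))
  expect_equal(res2$method, rep("exact enumeration", 3))
  # a missing mode is an error
  expect_error(compare_modes(rbind(seg("a", "CF", 1), seg("b", "CF", 2))),
               "FF absent")
})
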