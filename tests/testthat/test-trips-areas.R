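# straight out-and-back night with an optional near-roost dwell gap
out_back_track <- function(gap_min = 0, far = 15000, v = 7, dt = 600) {
  # out to `far`, back to roost, (gap), out again, back
  leg_t <- ceiling(far / v / dt) * dt
  t_out <- seq(0, leg_t, by = dt)
  x_out <- pmin(t_out * v, far)
  t_back <- seq(leg_t + dt, 2 * leg_t, by = dt)
  x_back <- pmax(far - (t_back - leg_t) * v, 0)
  tt <- c(t_out, t_back)
  xx <- c(x_out, x_back)
  if (gap_min > 0) {
    t2 <- tt[length(tt)] + gap_min * 60 + (tt - tt[1])
    tt <- c(tt, t2)
    xx <- c(xx, xx)
  }
  make_track(x = xx, y = rep(0, length(tt)), t_sec = tt)
}

test_that("trip boundaries need a long gap with both flanks near the roost", {
  roost <- c(0, 0)
  # no qualifying gap -> one trip
  t1 <- out_back_track(gap_min = 0)
  expect_equal(nrow(split_trips(t1, roost)), 1)
  # 45-min near-roost gap (flanks at the roost, buffer 5 km) -> two trips
  t2 <- out_back_track(gap_min = 45)
  tr2 <- split_trips(t2, roost, min_gap = 30, roost_buffer = 5000)
  expect_equal(nrow(tr2), 2)
  # flanks 2 km out qualify with a 5-km buffer but not with a tight one
  leg <- c(2000, 6200, 10400, 14600, 10400, 6200, 2000)
  tt <- c(seq(0, by = 600, length.out = 7),
          45 * 60 + seq(4200, by = 600, length.out = 7))
  t2b <- make_track(x = c(leg, leg), y = rep(0, 14), t_sec = tt)
  expect_equal(nrow(split_trips(t2b, roost, 30, roost_buffer = 5000)), 2)
  expect_equal(nrow(split_trips(t2b, roost, 30, roost_buffer = 100)), 1)
  # a 45-min gap far from the roost (mid-foraging) never splits
  fx <- t1$fixes
  mid <- which.max(fx$x)
  fx$timestamp[mid:nrow(fx)] <- fx$timestamp[mid:nrow(fx)] + 45 * 60
  t4 <- new_track("t", fx)
  expect_equal(nrow(split_trips(t4, roost, roost_buffer = 5000)), 1)
})

test_that("degenerate near-roost runs merge into their neighbouring trip", {
  # gap right after the departure fix: the lone roost fix is not a trip
  tt <- c(0, 45 * 60 + c(0, 600, 1200, 1800, 2400, 3000, 3600))
  xx <- c(0, 4200 * c(1, 2, 3, 2.2, 1.4, 0.6, 0))
  tr <- make_track(x = xx, y = rep(0, 8), t_sec = tt)
  trips <- split_trips(tr, c(0, 0), min_gap = 30, roost_buffer = 12400)
  expect_equal(nrow(trips), 1)
  expect_equal(trips$n_fixes, 8)
})

test_that("trip metrics: distance sums in-trip steps; speed uses elapsed time", {
  # 36 km in 2.5 h -> 4 m/s
  tr <- make_track(x = cumsum(c(0, rep(4500, 8))), y = rep(0, 9),
                   t_sec = seq(0, 2.5 * 3600, length.out = 9))
  trips <- split_trips(tr, c(0, 0))
  expect_equal(trips$total_distance_km, 36)
  expect_equal(trips$mean_speed_ms, 4)
  # out-and-back 15 km each way -> ~30 km
  t2 <- out_back_track()
  expect_equal(split_trips(t2, c(0, 0))$total_distance_km, 30,
               tolerance = 0.01)
  # conservation: trip distances + inter-trip steps = night distance
  t3 <- out_back_track(gap_min = 45)
  trips3 <- split_trips(t3, c(0, 0), roost_buffer = 5000)
  fx <- t3$fixes
  step_km <- sqrt(diff(fx$x)^2 + diff(fx$y)^2) / 1000
  inter <- sum(step_km[trips3$end_fix[-nrow(trips3)]])
  expect_equal(sum(trips3$total_distance_km) + inter, sum(step_km),
               tolerance = 1e-9)
})

test_that("foraging areas require 30 min and two relocations", {
  mk_segs <- function(durations_h, n_fixes, modes, dt = 900) {
    n <- sum(n_fixes)
    tt <- seq(0, by = dt, length.out = n)
    tr <- make_track(x = seq(0, by = 100, length.out = n), y = rep(0, n),
                     t_sec = tt)
    labels <- rep(modes, n_fixes)
    list(track = tr, segs = build_segments(labels, tr))
  }
  # 2-fix FF segment spanning 30 min on the 15-min schedule qualifies
  z <- mk_segs(NULL, c(2, 2, 2), c("CF", "FF", "CF"), dt = 900)
  ff <- z$segs[z$segs$mode == "FF", ]
  expect_equal(ff$duration_h * 60, 30)  # 15 min in-run + 15 min outgoing
  areas <- find_foraging_areas(z$segs, z$track, r_star = 340)
  expect_equal(nrow(areas), 1)
  expect_equal(areas$n_fixes, 2)
  # a single-fix FF segment is rejected
  z1 <- mk_segs(NULL, c(2, 1, 2), c("CF", "FF", "CF"), dt = 900)
  expect_equal(nrow(find_foraging_areas(z1$segs, z1$track, r_star = 340)), 0)
  # 2-fix FF run on the 10-min schedule spans 20 min: too short
  z2 <- mk_segs(NULL, c(2, 2, 2), c("CF", "FF", "CF"), dt = 600)
  expect_equal(nrow(find_foraging_areas(z2$segs, z2$track, r_star = 340)), 0)
})

test_that("revisited areas merge when centroids are within r*", {
  n <- 12
  # two FF bouts at the same place separated by a CF excursion
  x <- c(0, 5000, 5050, 5100, 5000, 9000, 12000, 5020, 5080, 5010, 5060, 0)
  labels <- c("CF", "FF", "FF", "FF", "FF", "CF", "CF", "FF", "FF", "FF",
              "FF", "CF")
  tr <- make_track(x = x, y = rep(0, n), t_sec = seq(0, by = 900,
                                                     length.out = n))
  segs <- suppressWarnings(build_segments(labels, tr))  # 1-fix tail segment
  merged <- find_foraging_areas(segs, tr, r_star = 340, roost_xy = c(0, 0))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$search_time_h * 60, 60 + 60)
  unmerged <- find_foraging_areas(segs, tr, r_star = 340, merge = FALSE)
  expect_equal(nrow(unmerged), 2)
})

test_that("area size, roost distance and search time follow their definitions", {
  expect_equal(area_size(300), 0.28)
  expect_equal(area_size(339), 0.36)
  expect_equal(area_size(500), 0.79)
  expect_equal(area_size(0), 0)
  r <- c(300, 350, 400, 450, 500)
  expect_true(all(diff(area_size(r)) > 0))
  areas <- tibble::tibble(centroid_x = 16410, centroid_y = 0,
                          search_time_h = 1.5)
  expect_equal(roost_distance(areas, c(0, 0)), 16.41)
  expect_equal(search_time(areas), 1.5)
})

test_that("habitat assignment is a majority vote with declared tie order", {
  lc <- generate_landcover(c(-1000, 3000, -1000, 1000),
                           list(patch_spec(c(2000, 0), 500, "forest")),
                           background_class = "farmland", cell_size = 20)
  n <- 4
  tr <- make_track(x = c(1900, 2100, 2000, 2050), y = rep(0, n),
                   t_sec = seq(0, by = 900, length.out = n))
  areas <- find_foraging_areas(build_segments(rep("FF", n), tr), tr,
                               r_star = 340)
  a <- assign_habitat(areas, tr, lc)
  expect_equal(a$habitat, "forest")
  # 2 shrubland vs 2 forest cells -> shrubland by declared priority
  lc2 <- grid_raster(matrix(c(1, 1, 2, 2), 1), xll = 0, yll = -50,
                     cellsize = 100, levels = c("shrubland", "forest",
                                                "farmland"))
  tr2 <- make_track(x = c(50, 150, 250, 350), y = rep(0, 4),
                    t_sec = seq(0, by = 900, length.out = 4))
  a2 <- assign_habitat(find_foraging_areas(build_segments(rep("FF", 4), tr2),
                                           tr2, r_star = 340), tr2, lc2)
  expect_equal(a2$habitat, "shrubland")
  # all fixes outside the raster -> warning, habitat stays missing
  tr3 <- make_track(x = c(5e4, 5e4 + 100, 5e4 + 50, 5e4), y = rep(0, 4),
                    t_sec = seq(0, by = 900, length.out = 4))
  expect_warning(
    a3 <- assign_habitat(find_foraging_areas(
      build_segments(rep("FF", 4), tr3), tr3, r_star = 340), tr3, lc2),
    "outside")
  expect_true(is.na(a3$habitat))
})

test_that("Kruskal-Wallis summary matches the hand rank computation", {
  areas <- tibble::tibble(
    track = "t", area = 1:6,
    roost_distance_km = c(1, 2, 3, 4, 5, 6),
    area_km2 = c(1, 2, 3, 4, 5, 6),
    search_time_h = c(1, 2, 3, 4, 5, 6),
    habitat = rep(c("shrubland", "forest", "farmland"), each = 2))
  res <- habitat_tests(areas)
  # groups {1,2},{3,4},{5,6}: rank sums 3,7,11 ->
  # H = 12/(6*7) * (9+49+121)/2 - 3*7 = 32/7
  expect_equal(res$tests$H, rep(32 / 7, 3), tolerance = 1e-12)
  expect_equal(res$tests$df, rep(2, 3))
  expect_equal(res$tests$p,
               rep(stats::pchisq(32 / 7, 2, lower.tail = FALSE), 3))
  expect_equal(sum(res$counts$fraction), 1)
  # identical groups -> H = 0, p = 1
  areas2 <- areas
  areas2$roost_distance_km <- rep(c(1, 2), 3)
  areas2$area_km2 <- rep(c(1, 2), 3)
  areas2$search_time_h <- rep(c(1, 2), 3)
  res2 <- habitat_tests(areas2)
  expect_equal(res2$tests$H, rep(0, 3))
  expect_equal(res2$tests$p, rep(1, 3))
  # single habitat -> tests omitted, summary still produced
  areas3 <- areas
  areas3$habitat <- "shrubland"
  res3 <- habitat_tests(areas3)
  expect_null(res3$tests)
  expect_equal(res3$counts$n, 6)
})

test_that("night summary conserves time and identifies the main area", {
  # all-CF night -> zero foraging fraction
  tr <- straight_track(n = 8, v = 7, dt = 600)
  labels <- rep("CF", 8)
  trips <- split_trips(tr, c(0, 0))
  ns <- night_summary(tr, labels, trips, find_foraging_areas(
    build_segments(labels, tr), tr, r_star = 340))
  expect_equal(ns$ff_time_h, 0)
  expect_equal(ns$cf_frac_moving, 1)
  # synthetic nights: CF + FF time equals moving time exactly
  for (s in 1:4) {
    st <- sim_track(quick_config(), 1300 + s, 1350 + s)
    labels <- classify_modes(passage_times(st$track, 339))
    segs <- build_segments(labels, st$track)
    trips <- split_trips(st$track, TEST_ROOST)
    areas <- find_foraging_areas(segs, st$track, r_star = 340,
                                 roost_xy = TEST_ROOST)
    ns <- night_summary(st$track, labels, trips, areas)
    expect_equal(ns$cf_time_h + ns$ff_time_h, ns$moving_time_h,
                 tolerance = 1e-9)
    if (nrow(areas) > 1)
      expect_gte(ns$main_area_time_h, max(areas$search_time_h))
  }
})
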