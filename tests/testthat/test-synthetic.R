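test_that("identical (config, seed) reproduces paths, truth and fixes bit-for-bit", {
  cfg <- quick_config()
  n1 <- simulate_night(cfg, 5)
  n2 <- simulate_night(cfg, 5)
  expect_identical(n1$path, n2$path)
  expect_identical(n1$truth, n2$truth)
  expect_false(identical(n1$path, simulate_night(cfg, 6)$path))
  expect_identical(sample_gps(n1, 9), sample_gps(n2, 9))
})

test_that("trip structure follows the configured plan", {
  cfg3 <- sim_config(n_trips = 3,
                     patches = list(patch_spec(c(0, 13000), 400, "shrubland")),
                     dropout_prob = 0)
  night <- simulate_night(cfg3, 21)
  # exactly 3 maximal ROOST -> ... -> ROOST excursions
  airborne <- night$truth$state != "ROOST"
  runs <- rle(airborne)
  expect_equal(sum(runs$values), 3)
  # path starts and ends at the roost
  expect_equal(unlist(night$path[1, c("x", "y")]), c(x = 0, y = 0))
  n <- nrow(night$path)
  expect_equal(unlist(night$path[n, c("x", "y")]), c(x = 0, y = 0))
  # roost dwells between trips are stationary and 30-90 min long
  dwell <- rle(night$truth$state)
  inner <- which(dwell$values == "ROOST")
  inner <- inner[inner > 1 & inner < length(dwell$values)]
  expect_length(inner, 2)
  expect_true(all(dwell$lengths[inner] >= 30 * 60 - 1 &
                  dwell$lengths[inner] <= 90 * 60 + 1))
})

test_that("commute duration approximates distance over commuting speed", {
  cfg <- sim_config(n_trips = 1,
                    patches = list(patch_spec(c(0, 15000), 400, "shrubland")),
                    dropout_prob = 0)
  night <- simulate_night(cfg, 31)
  leg <- rle(paste(night$truth$state, night$truth$trip))
  out_leg <- leg$lengths[leg$values == "COMMUTE 1"][1]
  # outbound: ~15000 m at ~7 m/s, directional persistence costs a little
  expect_gt(out_leg, 15000 / 7 * 0.95)
  expect_lt(out_leg, 15000 / 7 * 1.3)
})

test_that("simulated speeds match their configured distributions", {
  cfg <- quick_config(dropout_prob = 0)
  sp_c <- sp_f <- numeric(0)
  for (s in 1:20) {
    night <- simulate_night(cfg, 100 + s)
    v <- sqrt(diff(night$path$x)^2 + diff(night$path$y)^2)
    st <- night$truth$state[-1]
    sp_c <- c(sp_c, v[st == "COMMUTE"])
    sp_f <- c(sp_f, v[st == "FORAGE"])
  }
  # per-second speeds: commute ~ N(7, 1.7), forage ~ N(1.5, 1) truncated
  expect_equal(mean(sp_c), 7, tolerance = 2 * 1.7 / sqrt(length(sp_c)) + 0.02)
  expect_gt(mean(sp_f), 1.3)
  expect_lt(mean(sp_f), 1.9)
  expect_true(all(sp_c > 0))
})

test_that("GPS sampling honours the schedule, dropout and error model", {
  # 9-h window at 10-min interval -> 55 slots, endpoints inclusive
  cfg <- quick_config(dropout_prob = 0, position_error_sd = 0)
  night <- simulate_night(cfg, 41)
  fixes <- sample_gps(night, 42)
  expect_equal(nrow(fixes), 55)
  expect_equal(as.numeric(diff(fixes$timestamp), units = "mins"),
               rep(10, 54))
  # with zero dropout and zero error every airborne fix lies on the path
  frame <- utm_frame(cfg$crs)
  v <- fixes$`fix-status` == "valid"
  xy <- lonlat_to_xy(fixes$`location-long`[v], fixes$`location-lat`[v], frame)
  slot_s <- as.numeric(fixes$timestamp - fixes$timestamp[1], units = "secs")
  px <- night$path$x[slot_s[v] + 1] + cfg$roost_easting
  py <- night$path$y[slot_s[v] + 1] + cfg$roost_northing
  expect_lt(max(abs(xy$x - px)), 1e-3)
  expect_lt(max(abs(xy$y - py)), 1e-3)
  # roost-dwell slots are always invalid
  expect_true(all(fixes$`true-state`[!v] == "ROOST"))
})

test_that("airborne dropout matches the configured probability", {
  cfg <- quick_config(dropout_prob = 0.47)
  night <- simulate_night(cfg, 51)
  airborne <- valid <- 0
  for (s in 1:30) {
    fx <- sample_gps(night, 600 + s)
    fly <- fx$`true-state` != "ROOST"
    airborne <- airborne + sum(fly)
    valid <- valid + sum(fx$`fix-status`[fly] == "valid")
  }
  # mean valid share of airborne slots ~ 0.53 (binomial, ~1300 draws)
  expect_equal(valid / airborne, 0.53, tolerance = 0.06)
})

test_that("ground-truth foraging stays inside its patch; trips are round trips", {
  cfg <- sim_config(n_trips = 2,
                    patches = list(patch_spec(c(0, 14000), 400, "shrubland"),
                                   patch_spec(c(6000, 18000), 350, "forest")),
                    dropout_prob = 0.3)
  night <- simulate_night(cfg, 61)
  for (p in seq_along(cfg$patches)) {
    sel <- !is.na(night$truth$patch) & night$truth$patch == p
    d <- sqrt((night$path$x[sel] - cfg$patches[[p]]$center[1])^2 +
              (night$path$y[sel] - cfg$patches[[p]]$center[2])^2)
    expect_lte(max(d), cfg$patches[[p]]$radius + 1e-9)
  }
  # sampled foraging fixes fall within radius + 4 sd of GPS error
  fixes <- sample_gps(night, 62)
  frame <- utm_frame(cfg$crs)
  for (p in seq_along(cfg$patches)) {
    sel <- fixes$`fix-status` == "valid" & !is.na(fixes$`true-patch`) &
      fixes$`true-patch` == p
    if (!any(sel)) next
    xy <- lonlat_to_xy(fixes$`location-long`[sel], fixes$`location-lat`[sel],
                       frame)
    d <- sqrt((xy$x - cfg$roost_easting - cfg$patches[[p]]$center[1])^2 +
              (xy$y - cfg$roost_northing - cfg$patches[[p]]$center[2])^2)
    expect_lte(max(d), cfg$patches[[p]]$radius + 4 * cfg$position_error_sd)
  }
  # each trip's path distance is at least the out-and-back straight line
  for (tr in 1:2) {
    sel <- !is.na(night$truth$trip) & night$truth$trip == tr
    v <- sqrt(diff(night$path$x[sel])^2 + diff(night$path$y[sel])^2)
    first_patch <- cfg$trip_patches[[tr]][1]
    straight <- sqrt(sum(cfg$patches[[first_patch]]$center^2))
    expect_gte(sum(v), 2 * straight * 0.98)
  }
})

test_that("configs are validated and infeasible nights are refused", {
  expect_error(sim_config(commute_speed_mean = 1, forage_speed_mean = 1.5),
               "commute_speed_mean")
  expect_error(sim_config(dropout_prob = 1), "dropout_prob")
  expect_error(sim_config(patches = list()), "nonempty")
  expect_error(patch_spec(c(0, 0), -5), "radius")
  expect_error(patch_spec(c(0, 0), 300, "ocean"), "arg")
  far <- sim_config(patches = list(patch_spec(c(0, 2e5), 400, "forest")))
  expect_error(simulate_night(far, 1), "patch 1 is unreachable")
})

test_that("random night configs respect the study condition distributions", {
  set.seed(1)
  cfgs <- lapply(1:40, function(i) random_night_config(seed = i))
  trips <- vapply(cfgs, `[[`, integer(1), "n_trips")
  expect_true(all(trips %in% 1:3))
  for (cfg in cfgs) {
    d <- vapply(cfg$patches, function(p) sqrt(sum(p$center^2)), numeric(1))
    expect_true(all(d >= 13000 - 1e-6 & d <= 40000))
    r <- vapply(cfg$patches, `[[`, numeric(1), "radius")
    expect_true(all(r >= 300 & r <= 500))
  }
  # cohort: 21 nights, 5 on the 15-min schedule, deterministic under seed
  co1 <- simulate_cohort(n_nights = 4, seed = 3)
  co2 <- simulate_cohort(n_nights = 4, seed = 3)
  expect_identical(lapply(co1, `[[`, "fixes"), lapply(co2, `[[`, "fixes"))
  ints <- vapply(co1, function(el) el$config$fix_interval, numeric(1))
  expect_equal(unname(ints[startsWith(names(co1), "21")]),
               rep(15, sum(startsWith(names(co1), "21"))))
})
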