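test_that("baseline_rmr averages the pre-breakfast window", {
  s <- make_session("07:00", 120, ee = 1.2)
  expect_equal(baseline_rmr(s), 1.2)
  ee <- rep(1.2, 120)
  ee[16:45] <- rep(c(1.0, 1.4), 15)   # 07:15-07:44 alternating
  s2 <- calorimetry_session(grid_times("07:00", 120), ee, rep(2000, 120))
  expect_equal(baseline_rmr(s2), 1.2)
  expect_error(baseline_rmr(make_session("09:00", 60)), "outside session span")
})

test_that("baseline_smr averages the 480-min sleep period", {
  s <- make_chamber_session(1.0, 2250)
  expect_equal(baseline_smr(s), 1.0)
  sl <- slice_session(s, period("23:00", "07:00", "sleep"))
  expect_length(sl$ee, 480L)
})

test_that("simulated SMR sits below RMR when the sleep dip is on", {
  sim <- simulate_session(simulation_params(seed = 31))
  expect_lt(baseline_smr(sim$session), baseline_rmr(sim$session))
  # and RMR exceeds the latent basal because it includes pre-breakfast NEAT
  pre <- period_indices(sim$session, period("07:15", "07:45", "pre"))
  expect_gt(baseline_rmr(sim$session), mean(sim$truth$basal[pre]))
})

test_that("preprandial NEAT-free baseline never exceeds the RMR", {
  for (seed in 32:34) {
    sim <- simulate_session(simulation_params(seed = seed))
    s <- sim$session
    res <- suppressWarnings(
      tef_original(s, period("08:00", "12:00", "morning"),
                   689, details = TRUE))
    expect_lte(attr(res, "details")$baseline, baseline_rmr(s))
  }
  # with NEAT identically zero the two baselines coincide
  s0 <- make_chamber_session(1.2, 2000)   # constant activity -> NEAT == 0
  res0 <- suppressWarnings(
    tef_original(s0, period("08:00", "12:00", "m"), 689, details = TRUE))
  expect_equal(attr(res0, "details")$baseline, baseline_rmr(s0))
})

test_that("tef_delta_ee accumulates the fed-fasted gap", {
  fed <- make_chamber_session(1.355, 2500)
  fasted <- make_chamber_session(1.2, 2500)
  p <- period("08:00", "12:00", "morning")
  r <- tef_delta_ee(fed, fasted, p, 689)
  expect_equal(r$tef_kcal, 0.155 * 240)          # 37.2 kcal
  expect_equal(r$tef_percent, 100 * 37.2 / 689)  # 5.4% of breakfast
  expect_equal(tef_delta_ee(fed, fed, p, 689)$tef_kcal, 0)
  # antisymmetry
  r2 <- tef_delta_ee(fasted, fed, p, 689)
  expect_equal(r2$tef_kcal, -r$tef_kcal)
  # a fasted session that does not cover the period is rejected
  short <- make_session("07:00", 180, ee = 1.2, activity = 2500)
  expect_error(tef_delta_ee(fed, short, p, 689), "outside session span")
})

test_that("ee0_intercept recovers exact regression lines", {
  n <- 240L
  set.seed(41)
  act <- rpois(n, 3000)
  s <- calorimetry_session(grid_times("08:00", n), 0.8 + 2e-4 * act, act)
  p <- period("08:00", "12:00", "m")
  expect_equal(ee0_intercept(s, p), 0.8, tolerance = 1e-9)
  # adding then subtracting a constant leaves the intercept unchanged
  s2 <- calorimetry_session(grid_times("08:00", n), 0.8 + 2e-4 * act + 0.5 - 0.5, act)
  expect_equal(ee0_intercept(s2, p), ee0_intercept(s, p))
  # two-point closed form: line through (x1,y1),(x2,y2)
  s3 <- calorimetry_session(grid_times("08:00", 2), c(1.0, 1.4), c(1000, 3000))
  b <- (1.4 - 1.0) / (3000 - 1000)
  expect_equal(ee0_intercept(s3, period("08:00", "08:02", "two")),
               1.0 - b * 1000 + 0)
  expect_error(ee0_intercept(make_chamber_session(1.2, 2000), p),
               "zero activity variance")
})

test_that("tef_schutz applies the intercept-minus-baseline arithmetic", {
  n <- 240L
  set.seed(42)
  act <- rpois(n, 3000)
  s <- calorimetry_session(grid_times("08:00", n), 1.3 + 1e-4 * act, act)
  p <- period("08:00", "12:00", "m")
  r <- tef_schutz(s, p, baseline_kcal_min = 1.3, intake_kcal = 689, "rmr")
  expect_equal(r$tef_kcal, 0, tolerance = 1e-6)
  expect_equal(r$ee0_kcal_min, 1.3, tolerance = 1e-9)
  expect_warning(
    r2 <- tef_schutz(s, p, baseline_kcal_min = 1.5, intake_kcal = 689, "smr"),
    "negative TEF")
  expect_equal(r2$tef_kcal, (1.3 - 1.5) * 240, tolerance = 1e-4)
  expect_equal(r2$method, "schutz_smr")
})

test_that("tef_percent is invariant to joint EE/intake rescaling", {
  sim <- simulate_session(simulation_params(seed = 43))
  s <- sim$session
  p <- period("08:00", "12:00", "morning")
  k <- 4.184   # e.g. kcal -> kJ
  s_k <- calorimetry_session(s$time, s$ee * k, s$activity,
                             meals = s$meals, condition = s$condition)
  expect_equal(tef_schutz(s_k, p, k * baseline_smr(s), k * 689, "smr")$tef_percent,
               tef_schutz(s, p, baseline_smr(s), 689, "smr")$tef_percent)
  expect_equal(suppressWarnings(tef_original(s_k, p, k * 689)$tef_percent),
               suppressWarnings(tef_original(s, p, 689)$tef_percent),
               tolerance = 1e-9)
  pair <- simulate_pair(simulation_params(seed = 43))
  f_k <- calorimetry_session(pair$fasted$time, pair$fasted$ee * k,
                             pair$fasted$activity)
  expect_equal(tef_delta_ee(s_k, f_k, p, k * 689)$tef_percent,
               tef_delta_ee(pair$fed, pair$fasted, p, 689)$tef_percent)
})

test_that("constant activity reduces tef_original to the plain area", {
  n <- 1980L
  t <- grid_times("22:00", n)
  ee <- rep(1.1, n)
  p <- period("08:00", "12:00", "morning")
  # add a bump after 08:00 (a fake TEF response), constant activity
  s0 <- calorimetry_session(t, ee, rep(2000, n))
  bump_idx <- period_indices(s0, p)[1:120]
  ee[bump_idx] <- ee[bump_idx] + 0.2
  s <- calorimetry_session(t, ee, rep(2000, n))
  w <- capture_warnings(r <- tef_original(s, p, 689))
  expect_match(w, "constant activity", all = FALSE)
  expect_true(r$degenerate)
  pre <- period_indices(s, period("07:15", "07:45", "pre"))
  plain_area <- sum(ee[period_indices(s, p)] - mean(ee[pre]))
  expect_equal(r$tef_kcal, plain_area)
  expect_equal(r$tef_kcal, 0.2 * 120)
})

test_that("per_meal_tef normalizes each window by its own meal", {
  p <- flat_params(seed = 51)
  p$meals$tef_fraction <- c(0.06, 0.06, 0.06)
  sim <- simulate_session(p)
  res <- suppressWarnings(per_meal_tef(sim$session))
  expect_length(res, 3L)
  expect_equal(vapply(res, function(r) r$meal, ""),
               c("breakfast", "lunch", "dinner"))
  expect_equal(vapply(res, function(r) r$intake_kcal, 1),
               c(689, 761, 741))
  pct <- vapply(res, function(r) r$tef_percent, 1)
  # equal true fractions -> comparable estimates across meals
  expect_lt(max(pct) - min(pct), 2.5)
  expect_error(per_meal_tef(make_chamber_session(1.1, 2000)), "no meals")
})

test_that("per_meal_tef recovers a dinner > lunch ordering", {
  p <- flat_params(seed = 52)
  p$meals$tef_fraction <- c(0.05, 0.04, 0.10)
  sim <- simulate_session(p)
  res <- suppressWarnings(per_meal_tef(sim$session))
  pct <- setNames(vapply(res, function(r) r$tef_percent, 1),
                  vapply(res, function(r) r$meal, ""))
  expect_gt(pct[["dinner"]], pct[["lunch"]])
})

test_that("tef_from_components does the printed-value arithmetic", {
  r <- tef_from_components(1.3, 1.1, 240, 689)
  expect_equal(r$tef_kcal, 48)
  expect_equal(r$tef_percent, 100 * 48 / 689)
  expect_error(tef_result("x", period("08:00", "09:00"), 1, 0, 1),
               "positive")
})
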