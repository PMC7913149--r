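test_that("dose event lists enforce ordering and sign invariants", {
  expect_error(dose_events(c(0, 0), 20), "strictly increasing")
  expect_error(dose_events(c(-1, 24), 20), "non-negative")
  expect_error(dose_events(0, -5), ">= 0")
  expect_identical(nrow(dose_events()), 0L)
})

test_that("no doses means zero concentrations everywhere", {
  prof <- simulate_profile(toy_ind(), dose_events(), times = c(0, 24, 100))
  expect_equal(prof$conc_tam, rep(0, 3))
  expect_equal(prof$conc_endx, rep(0, 3))
})

test_that("concentrations are zero before the first dose plus lag time", {
  ind <- toy_ind()
  prof <- simulate_profile(ind, dose_events(10, 20),
                           times = c(0, 5, 10, 10 + ind$tlag * 0.99))
  expect_equal(prof$conc_tam, rep(0, 4))
  expect_equal(prof$conc_endx, rep(0, 4))
})

test_that("single-dose profile matches the frozen ODE oracle values", {
  # frozen from deSolve::lsoda (rtol 1e-11) on the toy parameter set,
  # 20 mg single dose at t = 0
  prof <- simulate_profile(toy_ind(), dose_events(0, 20),
                           times = c(24, 48, 168))
  expect_equal(prof$conc_tam,
               c(17.88527622, 15.78699866, 8.458625851), tolerance = 1e-6)
  expect_equal(prof$conc_endx,
               c(0.1643432429, 0.2611450676, 0.261071007),
               tolerance = 1e-6)
})

test_that("closed-form superposition matches numerical ODE integration", {
  set.seed(42)
  for (r in 1:5) {
    m <- tam_model(ka = runif(1, 0.2, 1.5), tlag = runif(1, 0, 1),
                   V_TAM = runif(1, 500, 1500), CL20 = runif(1, 2, 8),
                   CL23 = runif(1, 0.05, 0.5), V_ENDX = runif(1, 200, 600),
                   CL30 = runif(1, 1, 8))
    ind <- random_patient(m)
    nd <- sample(2:8, 1)
    dt <- sort(sample(0:300, nd)) * 1.0
    da <- runif(nd, 10, 40)
    tt <- sort(runif(12, 1, 400))
    cf <- simulate_profile(ind, dose_events(dt, da), tt)
    od <- ode_profile(ind, dt, da, tt)
    keep <- od$conc_endx > 1e-8
    expect_lt(max(abs(cf$conc_endx[keep] - od$conc_endx[keep]) /
                    od$conc_endx[keep]), 1e-6)
    keep <- od$conc_tam > 1e-8
    expect_lt(max(abs(cf$conc_tam[keep] - od$conc_tam[keep]) /
                    od$conc_tam[keep]), 1e-6)
  }
})

test_that("coincident rate constants are handled, not returned as NaN", {
  tt <- c(24, 168, 500)
  # ka equal to the tamoxifen elimination rate constant
  m1 <- tam_model(ka = 0.0052, V_TAM = 1000, CL20 = 5, CL23 = 0.2,
                  V_ENDX = 400, CL30 = 8)
  ind1 <- individual_params(m1, 2, m1$age_ref, m1$wt_ref)
  cf1 <- simulate_profile(ind1, dose_events(0, 20), tt)
  od1 <- ode_profile(ind1, 0, 20, tt)
  expect_true(all(is.finite(cf1$conc_endx)))
  expect_equal(cf1$conc_endx, od1$conc_endx, tolerance = 1e-5)
  expect_equal(cf1$conc_tam, od1$conc_tam, tolerance = 1e-5)
  # ka equal to the endoxifen elimination rate constant
  m2 <- tam_model(ka = 0.008, V_TAM = 1000, CL20 = 5, CL23 = 0.2,
                  V_ENDX = 1000, CL30 = 8)
  ind2 <- individual_params(m2, 2, m2$age_ref, m2$wt_ref)
  cf2 <- simulate_profile(ind2, dose_events(0, 20), tt)
  od2 <- ode_profile(ind2, 0, 20, tt)
  expect_equal(cf2$conc_endx, od2$conc_endx, tolerance = 1e-5)
  # pathological triple coincidence: resolved by wider node spreading at
  # reduced (but finite and bounded) accuracy
  m3 <- tam_model(ka = 0.0052, V_TAM = 1000, CL20 = 5, CL23 = 0.2,
                  V_ENDX = 1000, CL30 = 5.2)
  ind3 <- individual_params(m3, 2, m3$age_ref, m3$wt_ref)
  cf3 <- simulate_profile(ind3, dose_events(0, 20), tt)
  od3 <- ode_profile(ind3, 0, 20, tt)
  expect_true(all(is.finite(cf3$conc_endx)))
  expect_true(all(cf3$conc_endx >= 0))
  expect_equal(cf3$conc_endx, od3$conc_endx, tolerance = 5e-3)
})

test_that("linear PK: concentrations are exactly dose-proportional", {
  ind <- toy_ind()
  tt <- c(12, 36, 200)
  p1 <- simulate_profile(ind, dose_events(c(0, 24, 48), 10), tt)
  p3 <- simulate_profile(ind, dose_events(c(0, 24, 48), 30), tt)
  expect_equal(p3$conc_endx, 3 * p1$conc_endx, tolerance = 1e-9)
  expect_equal(ss_min_endx(ind, 40), 2 * ss_min_endx(ind, 20),
               tolerance = 1e-9)
})

test_that("steady-state minimum is zero without drug", {
  ind <- toy_ind()
  expect_identical(ss_min_endx(ind, 0), 0)
  expect_identical(ss_min_endx(ind, 20, rep(0, 7)), 0)
})

test_that("periodic steady state matches a 52-week brute-force simulation", {
  ind <- toy_ind()
  pat <- c(1, 1, 1, 1, 1, 1, 0)
  tl <- build_timeline(20, 20, adherence_scenario(1))
  grid <- seq(51 * 168, 52 * 168 - 0.25, by = 0.25)
  brute <- min(simulate_profile(ind, tl, grid)$conc_endx)
  expect_equal(ss_min_endx(ind, 20, pat), brute, tolerance = 1e-3)
})

test_that("26 weeks suffice to attain the periodic steady state", {
  ind <- toy_ind()
  day <- 1:(52 * 7)
  pat <- weekly_pattern(2)
  taken <- pat[(day - 1) %% 7 + 1] == 1
  tl <- dose_events((day[taken] - 1) * 24, 20)
  min_cycle <- function(week) {
    grid <- seq((week - 1) * 168, week * 168 - 0.25, by = 0.25)
    min(simulate_profile(ind, tl, grid)$conc_endx)
  }
  expect_equal(min_cycle(26), min_cycle(52), tolerance = 5e-3)
})

test_that("each additional missed dose strictly lowers the cycle minimum", {
  set.seed(7)
  m <- tam_model()
  for (r in 1:20) {
    ind <- random_patient(m)
    c0 <- ss_min_endx(ind, 20, weekly_pattern(0))
    c1 <- ss_min_endx(ind, 20, weekly_pattern(1))
    c2 <- ss_min_endx(ind, 20, weekly_pattern(2))
    expect_true(c2 < c1 && c1 < c0)
  }
})

test_that("reduced CYP2D6 activity strictly lowers the trough at fixed dose", {
  m <- tam_model()
  troughs <- vapply(c(2, 1.5, 1, 0.5, 0), function(as) {
    ss_min_endx(individual_params(m, as, m$age_ref, m$wt_ref), 20)
  }, numeric(1))
  expect_true(all(diff(troughs) < 0))
})
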