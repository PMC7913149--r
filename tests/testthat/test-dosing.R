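test_that("strategy configuration enforces its invariants", {
  expect_error(strategy_config("mipd", target_trough = 0), "target_trough")
  expect_error(strategy_config("mipd", dose_grid = c(1, 20)), "dose_grid")
  expect_error(strategy_config("mipd", dose_grid = c(20, 150)), "dose_grid")
  expect_error(strategy_config("mipd", tdm_days = c(14, 35)), "tdm_days")
  s <- default_strategies()
  expect_length(s, 5)
  expect_identical(s$mipd_597_plus10$dose_increment, 10)
  expect_identical(s$mipd_9$target_trough, 9)
})

test_that("conventional dosing gives every phenotype 20 mg", {
  expect_equal(conventional_dose(c("gNM", "gIM", "gPM")), c(20, 20, 20))
})

test_that("CYP2D6-guided starting doses are stratified by phenotype", {
  expect_equal(genotype_guided_dose(c("gNM", "gIM", "gPM")), c(20, 30, 60))
  expect_error(genotype_guided_dose("gUM"), "unknown phenotype")
})

test_that("noise-free TDM samples equal the model's trough predictions", {
  ind <- toy_ind()
  obs <- simulate_tdm(ind, 20, sigma_prop = 0)
  doses <- dose_events((0:27) * 24, 20)
  ref <- simulate_profile(ind, doses, c(14, 21, 28) * 24)$conc_endx
  expect_equal(obs$conc, ref)
  expect_equal(obs$time, c(336, 504, 672))
  expect_true(all(obs$conc > 0))
})

test_that("TDM noise is reproducible under a seed and has the right spread", {
  ind <- toy_ind()
  o1 <- simulate_tdm(ind, 20, sigma_prop = 0.2, seed = 3)
  o2 <- simulate_tdm(ind, 20, sigma_prop = 0.2, seed = 3)
  expect_identical(o1, o2)
  set.seed(17)
  eps <- unlist(replicate(334, simulate_tdm(ind, 20, sigma_prop = 0.2)$eps,
                          simplify = FALSE))
  # ~1,000 draws: sample SD of the log-scale noise within 5% of sigma
  expect_lt(abs(sd(eps) / 0.2 - 1), 0.05)
})

test_that("MAP estimate sits at the prior mode for typical observations", {
  m <- toy_model()
  obs <- simulate_tdm(toy_ind(m), 20, sigma_prop = 0)
  est <- map_estimate(m, obs, 2, m$age_ref, m$wt_ref, 20)
  expect_true(est$converged)
  expect_equal(est$eta_cl23, 0, tolerance = 1e-5)
  expect_equal(est$eta_cl20, 0, tolerance = 1e-5)
})

test_that("MAP recovers the true random effects as sigma tends to zero", {
  m <- toy_model()
  ind <- toy_ind(m, eta_cl23 = 0.4, eta_cl20 = -0.3)
  obs <- simulate_tdm(ind, 20, sigma_prop = 0)
  est <- map_estimate(m, obs, 2, m$age_ref, m$wt_ref, 20,
                      sigma_prop = 1e-3)
  expect_true(est$converged)
  expect_equal(est$eta_cl23, 0.4, tolerance = 1e-3)
  expect_equal(est$eta_cl20, -0.3, tolerance = 1e-3)
  expect_lte(est$objective,
             map_estimate(m, obs, 2, m$age_ref, m$wt_ref, 20,
                          sigma_prop = 1e-3)$objective + 1e-9)
})

test_that("MAP shrinkage matches a dense 2-D grid-search oracle", {
  m <- toy_model()
  ind <- toy_ind(m, eta_cl23 = 0.6, eta_cl20 = 0.1)
  obs <- simulate_tdm(ind, 20, sigma_prop = 0.2, seed = 21)[1, ]
  est <- map_estimate(m, obs, 2, m$age_ref, m$wt_ref, 20)
  grid <- map_grid_oracle(m, obs, 2, m$age_ref, m$wt_ref, 20,
                          m$sigma_prop)
  expect_lt(abs(est$eta_cl23 - grid[1]), 1e-3)
  expect_lt(abs(est$eta_cl20 - grid[2]), 1e-3)
  # shrinkage: estimate lies between prior mode and the eta interpolating
  # the single observation exactly
  full <- log(obs$conc / simulate_tdm(toy_ind(m), 20,
                                      sigma_prop = 0)$conc[1])
  expect_true(est$eta_cl23 > min(0, full) && est$eta_cl23 < max(0, full))
})

test_that("MIPD selects the smallest grid dose attaining the target", {
  m <- tam_model()
  eta <- c(0, 0)
  # forward-simulation oracle at each grid dose, per patient
  set.seed(31)
  for (r in 1:5) {
    as <- sample(c(0, 1, 2), 1)
    age <- runif(1, 35, 80); wt <- runif(1, 50, 100)
    eta <- rnorm(2, 0, c(0.5, 0.24))
    grid <- c(5, 10, 20, 30, 40, 60, 80, 100, 120)
    troughs <- vapply(grid, function(d) {
      ss_min_endx(individual_params(m, as, age, wt, eta[1], eta[2]), d)
    }, numeric(1))
    expect_true(all(diff(troughs) > 0)) # strict dose monotonicity
    ok <- grid[troughs >= 5.97]
    want <- if (length(ok)) min(ok) else 120
    sel <- select_mipd_dose(m, eta, as, age, wt, target_trough = 5.97)
    expect_identical(sel$dose, want)
  }
})

test_that("MIPD selection respects the trivial and capped edge cases", {
  m <- tam_model()
  sel0 <- select_mipd_dose(m, c(0, 0), 2, 55, 70, target_trough = 1e-9)
  expect_identical(sel0$dose, 5)
  # deep poor metaboliser with strongly negative eta cannot reach a high
  # target at any grid dose
  sel <- select_mipd_dose(m, c(-2, 0), 0, 55, 70, target_trough = 20)
  expect_identical(sel$dose, 120)
  expect_true(sel$capped)
  sel10 <- select_mipd_dose(m, c(-2, 0), 0, 55, 70, target_trough = 20,
                            dose_increment = 10)
  expect_identical(sel10$dose, 130) # increment applied after the cap
  expect_true(sel10$capped)
})

test_that("higher targets never select lower doses; +10 strategy is exact", {
  m <- tam_model()
  set.seed(41)
  for (r in 1:10) {
    as <- sample(c(0, 0.5, 1, 1.5, 2), 1)
    age <- runif(1, 30, 85); wt <- runif(1, 45, 110)
    eta <- rnorm(2, 0, c(0.5, 0.24))
    d597 <- select_mipd_dose(m, eta, as, age, wt, target_trough = 5.97)
    d9 <- select_mipd_dose(m, eta, as, age, wt, target_trough = 9)
    dplus <- select_mipd_dose(m, eta, as, age, wt, target_trough = 5.97,
                              dose_increment = 10)
    expect_gte(d9$dose, d597$dose)
    expect_identical(dplus$dose, d597$dose + 10)
  }
})

test_that("without IIV or noise MIPD is deterministic per covariate class", {
  m <- tam_model()
  dose_for <- function() {
    obs <- simulate_tdm(individual_params(m, 1, 60, 75), 30,
                        sigma_prop = 0)
    est <- map_estimate(m, obs, 1, 60, 75, 30)
    select_mipd_dose(m, est, 1, 60, 75)$dose
  }
  expect_identical(dose_for(), dose_for())
  # and the MAP estimate is the prior mode, so the dose is covariate-based
  obs <- simulate_tdm(individual_params(m, 1, 60, 75), 30, sigma_prop = 0)
  est <- map_estimate(m, obs, 1, 60, 75, 30)
  expect_equal(est$eta_cl23, 0, tolerance = 1e-5)
})
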