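# Shared fixtures and independent oracles for the test suite.

# Toy parameter set used for the frozen single-dose examples; covariate
# effects neutral at the reference patient.
toy_model <- function(...) {
  tam_model(ka = 0.5, tlag = 0.5, V_TAM = 1000, CL20 = 5, CL23 = 0.2,
            V_ENDX = 400, CL30 = 8, ...)
}

toy_ind <- function(model = toy_model(), activity_score = 2,
                    age = model$age_ref, weight = model$wt_ref,
                    eta_cl23 = 0, eta_cl20 = 0) {
  individual_params(model, activity_score, age, weight, eta_cl23, eta_cl20)
}

# Independent brute-force oracle: stiff-safe numerical integration of the
# depot -> tamoxifen -> endoxifen cascade with dose events added to the
# depot at time + tlag.
ode_profile <- function(ind, dose_time, dose_amount, times) {
  k23 <- ind$CL23_i / ind$V_TAM
  k20 <- ind$CL20_i / ind$V_TAM
  kM <- ind$CL30 / ind$V_ENDX
  deriv <- function(t, y, p) {
    list(c(-ind$ka * y[1],
           ind$ka * y[1] - (k20 + k23) * y[2],
           k23 * y[2] - kM * y[3]))
  }
  ev <- data.frame(var = "depot", time = dose_time + ind$tlag,
                   value = dose_amount, method = "add")
  tt <- sort(unique(c(0, times, ev$time)))
  out <- deSolve::lsoda(c(depot = 0, a_tam = 0, a_endx = 0), tt, deriv,
                        NULL, events = list(data = ev),
                        rtol = 1e-11, atol = 1e-13, maxsteps = 100000)
  i <- match(times, out[, 1])
  data.frame(time = times,
             conc_tam = 1000 * out[i, "a_tam"] / ind$V_TAM,
             conc_endx = 1000 * out[i, "a_endx"] / ind$V_ENDX)
}

# Predicted endoxifen troughs through the public simulation interface
# (used by the MAP grid-search oracle so it does not share the optimiser's
# code path).
pred_troughs_public <- function(model, activity_score, age, weight, eta,
                                dose, times, n_days = 28) {
  ind <- individual_params(model, activity_score, age, weight,
                           eta[1], eta[2])
  doses <- dose_events((seq_len(n_days) - 1) * 24, dose)
  simulate_profile(ind, doses, times)$conc_endx
}

# Dense two-stage 2-D grid search minimising the MAP objective.
map_grid_oracle <- function(model, obs, activity_score, age, weight, dose,
                            sigma_prop, lim = 1.2) {
  jfun <- function(e1, e2) {
    f <- pred_troughs_public(model, activity_score, age, weight,
                             c(e1, e2), dose, obs$time)
    sum((log(obs$conc) - log(f))^2) / sigma_prop^2 +
      e1^2 / model$omega2_CL23 + e2^2 / model$omega2_CL20
  }
  search <- function(c1, c2, half, step) {
    g1 <- seq(c1 - half, c1 + half, by = step)
    g2 <- seq(c2 - half, c2 + half, by = step)
    jm <- outer(g1, g2, Vectorize(jfun))
    k <- arrayInd(which.min(jm), dim(jm))
    c(g1[k[1]], g2[k[2]])
  }
  coarse <- search(0, 0, lim, 0.02)
  fine <- search(coarse[1], coarse[2], 0.03, 5e-4)
  fine
}

# Random patient draw for property-style tests (seed managed by caller).
random_patient <- function(model) {
  as_pool <- c(0, 0.5, 1, 1.5, 2)
  individual_params(model,
                    activity_score = sample(as_pool, 1),
                    age = runif(1, 30, 85),
                    weight = runif(1, 45, 110),
                    eta_cl23 = rnorm(1, 0, sqrt(model$omega2_CL23)),
                    eta_cl20 = rnorm(1, 0, sqrt(model$omega2_CL20)))
}
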