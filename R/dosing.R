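#' Dosing-strategy configuration
#'
#' Describes one of the evaluated once-daily dosing strategies:
#' `conventional` (flat 20 mg), `cyp2d6_guided` (phenotype-stratified
#' starting dose) or `mipd` (genotype-guided initial dose for 4 weeks, TDM
#' troughs at 2/3/4 weeks, MAP-Bayesian selection of the maintenance dose
#' from a discrete grid against a trough target, optionally plus a fixed
#' increment).
#'
#' @param strategy one of `"conventional"`, `"cyp2d6_guided"`, `"mipd"`.
#' @param target_trough endoxifen steady-state trough target (ng/mL); the
#'   therapeutic threshold 5.97 or the safeguard 9.0.
#' @param dose_increment mg added to each selected maintenance dose
#'   (0 or 10).
#' @param dose_grid ordered candidate once-daily doses (mg), within
#'   `[5, 120]` (the highest dose tested without additional toxicities).
#' @param tdm_days TDM sampling days after treatment start.
#' @param initial_phase_days length of the genotype-guided initial phase
#'   (days).
#' @param label short identifier used in result tables.
#' @return Object of class `strategy_config`.
#' @export
strategy_config <- function(strategy = c("conventional", "cyp2d6_guided",
                                         "mipd"),
                            target_trough = 5.97,
                            dose_increment = 0,
                            dose_grid = c(5, 10, 20, 30, 40, 60, 80, 100, 120),
                            tdm_days = c(14, 21, 28),
                            initial_phase_days = 28,
                            label = NULL) {
  strategy <- match.arg(strategy)
  if (!is.numeric(target_trough) || target_trough <= 0) {
    stop("strategy_config: target_trough must be > 0", call. = FALSE)
  }
  if (dose_increment < 0) {
    stop("strategy_config: dose_increment must be >= 0", call. = FALSE)
  }
  if (is.unsorted(dose_grid, strictly = TRUE) || any(dose_grid < 5) ||
      any(dose_grid > 120)) {
    stop("strategy_config: dose_grid must be strictly increasing within [5, 120] mg",
         call. = FALSE)
  }
  if (any(tdm_days <= 0) || any(tdm_days > initial_phase_days)) {
    stop("strategy_config: tdm_days must lie within the initial phase",
         call. = FALSE)
  }
  if (is.null(label)) label <- strategy
  structure(list(strategy = strategy, target_trough = target_trough,
                 dose_increment = dose_increment, dose_grid = dose_grid,
                 tdm_days = tdm_days,
                 initial_phase_days = initial_phase_days, label = label),
            class = "strategy_config")
}

#' The five evaluated dosing strategies
#'
#' (i) conventional 20 mg QD; (ii) CYP2D6-guided (gNM 20 / gIM 30 /
#' gPM 60 mg); (iii) MIPD targeting 5.97 ng/mL; (iv) MIPD targeting
#' 5.97 ng/mL plus a fixed 10 mg increment on each selected dose;
#' (v) MIPD targeting 9 ng/mL (the lowest reported mean steady-state
#' endoxifen trough in gNM) as a non-adherence safeguard.
#'
#' @return Named list of five [strategy_config()] objects.
#' @export
default_strategies <- function() {
  list(
    conventional    = strategy_config("conventional",
                                      label = "conventional"),
    cyp2d6_guided   = strategy_config("cyp2d6_guided",
                                      label = "cyp2d6_guided"),
    mipd_597        = strategy_config("mipd", target_trough = 5.97,
                                      label = "mipd_597"),
    mipd_597_plus10 = strategy_config("mipd", target_trough = 5.97,
                                      dose_increment = 10,
                                      label = "mipd_597_plus10"),
    mipd_9          = strategy_config("mipd", target_trough = 9,
                                      label = "mipd_9")
  )
}

#' Conventional tamoxifen dose
#'
#' The standard flat regimen: 20 mg once daily for every patient.
#'
#' @param phenotype ignored; accepted so all strategy dose rules share one
#'   signature.
#' @return 20 (mg), recycled to the length of `phenotype`.
#' @export
conventional_dose <- function(phenotype = "gNM") {
  rep(20, length(phenotype))
}

#' CYP2D6 genotype-guided starting dose
#'
#' gNM 20 mg, gIM 30 mg, gPM 60 mg once daily.
#'
#' @param phenotype character vector with values `gNM`, `gIM`, `gPM`.
#' @return Dose(s) in mg QD.
#' @export
genotype_guided_dose <- function(phenotype) {
  map <- c(gNM = 20, gIM = 30, gPM = 60)
  if (!all(phenotype %in% names(map))) {
    stop("genotype_guided_dose: unknown phenotype ",
         paste(setdiff(unique(phenotype), names(map)), collapse = ", "),
         call. = FALSE)
  }
  unname(map[phenotype])
}

# Predicted endoxifen trough concentrations during the initial once-daily
# phase: doses on days 1..n_days, samples taken pre-dose ("end of a dosing
# interval", i.e. 24 h after the previous intake). A dose given exactly at
# a sampling time contributes nothing there because of the absorption lag.
tdm_pred_times <- function(tdm_days) tdm_days * 24

predict_tdm_troughs <- function(ind, dose_mg, tdm_days,
                                initial_phase_days = 28) {
  co <- conc_coefs(ind)
  dt <- (seq_len(initial_phase_days) - 1) * 24
  endx_superpose(co, ind$tlag, dt, rep(dose_mg, length(dt)),
                 tdm_pred_times(tdm_days))
}

#' Simulate virtual TDM samples
#'
#' Endoxifen trough samples at the configured days (default 2, 3 and 4
#' weeks after treatment start, pre-dose) under the genotype-guided initial
#' dose, with multiplicative log-normal residual error
#' `y = f * exp(eps)`, `eps ~ N(0, sigma_prop^2)`.
#'
#' @param ind individual parameters from [individual_params()] (the
#'   patient's true parameters, including random effects).
#' @param initial_dose initial once-daily dose (mg).
#' @param tdm_days sampling days.
#' @param sigma_prop residual log-scale SD; 0 gives noise-free samples.
#' @param initial_phase_days length of the initial phase (days).
#' @param seed optional RNG seed for the noise draws.
#' @return `data.frame` with columns `time` (h), `conc` (ng/mL, observed)
#'   and `eps` (the noise realisation).
#' @export
simulate_tdm <- function(ind, initial_dose, tdm_days = c(14, 21, 28),
                         sigma_prop = 0.20, initial_phase_days = 28,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- predict_tdm_troughs(ind, initial_dose, tdm_days, initial_phase_days)
  eps <- stats::rnorm(length(f), 0, sigma_prop)
  data.frame(time = tdm_pred_times(tdm_days), conc = f * exp(eps),
             eps = eps)
}

#' MAP-Bayesian estimation of individual random effects
#'
#' Maximum a posteriori estimate of `(eta_CL23, eta_CL20)` given observed
#' endoxifen troughs, minimising
#' \deqn{J(\eta) = \sum_j \frac{(\ln y_j - \ln f_j(\eta))^2}{\sigma^2}
#'   + \frac{\eta_{CL23}^2}{\omega^2_{CL23}}
#'   + \frac{\eta_{CL20}^2}{\omega^2_{CL20}},}
#' the standard MAP objective for a log-transformed proportional residual
#' model with log-normal IIV priors. Optimised with Nelder-Mead from the
#' prior mode; on failure the estimate falls back to `eta = 0` with a
#' warning (the patient then keeps the genotype-guided dose).
#'
#' @param model a [tam_model()] (supplies priors and residual SD).
#' @param obs TDM observations (`data.frame` with `time`, `conc`) as from
#'   [simulate_tdm()].
#' @param activity_score,age,weight the patient's covariates.
#' @param initial_dose the once-daily dose under which `obs` were sampled.
#' @param initial_phase_days length of the initial dosing phase (days).
#' @param sigma_prop residual SD used in the objective (defaults to the
#'   model's).
#' @return List of class `map_estimate`: `eta_cl23`, `eta_cl20`,
#'   `objective`, `converged`.
#' @export
map_estimate <- function(model, obs, activity_score, age, weight,
                         initial_dose, initial_phase_days = 28,
                         sigma_prop = model$sigma_prop) {
  stopifnot(nrow(obs) >= 1, all(obs$conc > 0), sigma_prop > 0)
  if (model$omega2_CL23 <= 0 || model$omega2_CL20 <= 0) {
    stop("map_estimate: IIV variances must be > 0 to define the prior",
         call. = FALSE)
  }
  typ <- apply_covariates(model, activity_score, age, weight)
  base <- structure(list(ka = model$ka, tlag = model$tlag,
                         V_TAM = model$V_TAM, V_ENDX = model$V_ENDX,
                         CL30 = model$CL30, CL23_i = typ$CL23_typ,
                         CL20_i = typ$CL20_typ), class = "tam_ind")
  log_y <- log(obs$conc)
  dt <- (seq_len(initial_phase_days) - 1) * 24
  amt <- rep(initial_dose, length(dt))
  obj <- function(eta) {
    ind <- base
    ind$CL23_i <- base$CL23_i * exp(eta[1])
    ind$CL20_i <- base$CL20_i * exp(eta[2])
    f <- endx_superpose(conc_coefs(ind), ind$tlag, dt, amt, obs$time)
    if (any(f <= 0)) return(1e12)
    sum((log_y - log(f))^2) / sigma_prop^2 +
      eta[1]^2 / model$omega2_CL23 + eta[2]^2 / model$omega2_CL20
  }
  fit <- try(stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 2000)),
             silent = TRUE)
  j0 <- obj(c(0, 0))
  if (inherits(fit, "try-error") || fit$convergence != 0 ||
      !all(is.finite(fit$par)) || fit$value > j0 + 1e-9) {
    warning("map_estimate: optimiser did not converge; falling back to eta = 0")
    return(structure(list(eta_cl23 = 0, eta_cl20 = 0, objective = j0,
                          converged = FALSE), class = "map_estimate"))
  }
  structure(list(eta_cl23 = fit$par[1], eta_cl20 = fit$par[2],
                 objective = fit$value, converged = TRUE),
            class = "map_estimate")
}

#' Select the MIPD maintenance dose
#'
#' Returns the smallest dose in the grid whose predicted full-adherence
#' steady-state endoxifen trough (forecast with the MAP random effects)
#' reaches the target; if no grid dose qualifies, the maximum grid dose
#' (120 mg) is used and flagged as capped. Any configured fixed increment
#' is added after the cap, so a capped strategy-(iv) patient can receive
#' 130 mg — above the tested maximum, hence the flag. Linear PK makes the
#' predicted trough exactly proportional to dose, so the selection is
#' well-defined and unique.
#'
#' @param model a [tam_model()].
#' @param eta MAP estimate (list with `eta_cl23`, `eta_cl20`) or numeric
#'   length-2 vector.
#' @param activity_score,age,weight patient covariates.
#' @param dose_grid ordered candidate doses (mg).
#' @param target_trough trough target (ng/mL).
#' @param dose_increment mg added to the selected dose.
#' @return List: `dose` (mg, maintenance), `base_dose` (before increment),
#'   `capped` (logical), `predicted_trough` (ng/mL at `dose`, full
#'   adherence).
#' @export
select_mipd_dose <- function(model, eta, activity_score, age, weight,
                             dose_grid = c(5, 10, 20, 30, 40, 60, 80, 100, 120),
                             target_trough = 5.97, dose_increment = 0) {
  if (is.list(eta)) eta <- c(eta$eta_cl23, eta$eta_cl20)
  ind <- individual_params(model, activity_score, age, weight,
                           eta_cl23 = eta[1], eta_cl20 = eta[2])
  trough_per_mg <- ss_min_endx(ind, 1)
  ok <- dose_grid * trough_per_mg >= target_trough
  capped <- !any(ok)
  base_dose <- if (capped) max(dose_grid) else min(dose_grid[ok])
  dose <- base_dose + dose_increment
  list(dose = dose, base_dose = base_dose, capped = capped,
       predicted_trough = dose * trough_per_mg)
}
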