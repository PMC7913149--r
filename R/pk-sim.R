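#' Dose event list
#'
#' Ordered oral tamoxifen dose records. Times are hours since treatment
#' start; amounts are mg.
#'
#' @param time numeric vector of dose times (h), non-negative, strictly
#'   increasing.
#' @param amount numeric vector of dose amounts (mg), `>= 0`, recycled if
#'   scalar.
#' @return A `data.frame` of class `dose_events` with columns `time`,
#'   `amount`.
#' @examples
#' dose_events(time = (0:6) * 24, amount = 20)
#' @export
dose_events <- function(time = numeric(), amount = numeric()) {
  if (length(amount) == 1L) amount <- rep(amount, length(time))
  stopifnot(length(time) == length(amount))
  if (length(time)) {
    if (any(time < 0)) stop("dose_events: times must be non-negative",
                            call. = FALSE)
    if (any(diff(time) <= 0)) stop("dose_events: times must be strictly increasing",
                                   call. = FALSE)
    if (any(amount < 0)) stop("dose_events: amounts must be >= 0",
                              call. = FALSE)
  }
  structure(data.frame(time = as.numeric(time), amount = as.numeric(amount)),
            class = c("dose_events", "data.frame"))
}

# Per-unit-dose tri-exponential coefficients (ng/mL per mg).
# Amount-to-concentration conversion: dose mg into V litres gives mg/L;
# 1 mg/L = 1000 ng/mL, hence the factor 1000.
conc_coefs <- function(ind) {
  rc <- rate_constants(ind)
  l1 <- rc$l1; l2 <- rc$l2; l3 <- rc$l3
  cT <- 1000 * ind$ka / (ind$V_TAM * (l2 - l1))
  cM <- 1000 * ind$ka * rc$k23 / ind$V_ENDX
  list(l1 = l1, l2 = l2, l3 = l3,
       tam1 = cT, tam2 = -cT,
       e1 = cM / ((l2 - l1) * (l3 - l1)),
       e2 = cM / ((l1 - l2) * (l3 - l2)),
       e3 = cM / ((l1 - l3) * (l2 - l3)))
}

# Endoxifen concentration (ng/mL) at arbitrary times under a finite dose
# history, by superposition of the closed-form single-dose solution.
# Internal fast path used by simulate_profile(), TDM prediction and the
# MAP objective.
endx_superpose <- function(co, tlag, dose_time, dose_amount, times) {
  out <- numeric(length(times))
  for (i in seq_along(dose_time)) {
    if (dose_amount[i] <= 0) next
    u <- times - dose_time[i] - tlag
    ok <- u >= 0
    if (!any(ok)) next
    uu <- u[ok]
    out[ok] <- out[ok] + dose_amount[i] *
      (co$e1 * exp(-co$l1 * uu) + co$e2 * exp(-co$l2 * uu) +
         co$e3 * exp(-co$l3 * uu))
  }
  pmax(out, 0)
}

#' Simulate a tamoxifen/endoxifen concentration-time profile
#'
#' Evaluates the closed-form solution of the linear absorption cascade
#' (depot -> tamoxifen central -> endoxifen central) for an arbitrary dose
#' event list, by superposition of per-dose tri-exponential terms shifted by
#' the absorption lag time. Concentrations are exactly zero before
#' `first dose time + tlag`.
#'
#' @param ind individual parameters from [individual_params()].
#' @param doses a [dose_events()] object.
#' @param times numeric vector of evaluation times (h), sorted,
#'   non-negative.
#' @return `data.frame` with columns `time`, `conc_tam`, `conc_endx`
#'   (ng/mL).
#' @examples
#' ind <- individual_params(tam_model(), 2, 55, 70)
#' simulate_profile(ind, dose_events(0, 20), times = c(24, 48, 168))
#' @export
simulate_profile <- function(ind, doses, times) {
  stopifnot(inherits(ind, "tam_ind"), inherits(doses, "dose_events"))
  if (is.unsorted(times) || any(times < 0)) {
    stop("simulate_profile: times must be sorted and non-negative",
         call. = FALSE)
  }
  co <- conc_coefs(ind)
  tam <- numeric(length(times))
  for (i in seq_len(nrow(doses))) {
    if (doses$amount[i] <= 0) next
    u <- times - doses$time[i] - ind$tlag
    ok <- u >= 0
    if (!any(ok)) next
    uu <- u[ok]
    tam[ok] <- tam[ok] + doses$amount[i] *
      (co$tam1 * exp(-co$l1 * uu) + co$tam2 * exp(-co$l2 * uu))
  }
  endx <- endx_superpose(co, ind$tlag, doses$time, doses$amount, times)
  data.frame(time = times, conc_tam = pmax(tam, 0), conc_endx = endx)
}

#' Endoxifen concentration over the periodic steady-state weekly cycle
#'
#' Under a weekly-repeating intake pattern the concentration approaches a
#' periodic steady state. Each exponential term of the single-dose solution
#' then sums over past weeks as a geometric series:
#' `sum_w exp(-lambda (u + 168 w)) = exp(-lambda u) / (1 - exp(-168 lambda))`,
#' which this function evaluates directly.
#'
#' @param ind individual parameters from [individual_params()].
#' @param dose_mg dose per intake (mg).
#' @param pattern length-7 binary vector; `pattern[d] == 1` means the dose
#'   on cycle day `d` is taken.
#' @param t_cycle times within the cycle (h in `[0, 168)`).
#' @return Numeric vector of endoxifen concentrations (ng/mL).
#' @export
ss_endx_cycle <- function(ind, dose_mg, pattern, t_cycle) {
  stopifnot(inherits(ind, "tam_ind"), length(pattern) == 7L,
            all(pattern %in% c(0, 1)), dose_mg >= 0)
  if (dose_mg == 0 || sum(pattern) == 0) return(numeric(length(t_cycle)))
  P <- 168
  tau <- 24 * (which(pattern == 1) - 1)
  co <- conc_coefs(ind)
  g1 <- 1 / (1 - exp(-co$l1 * P))
  g2 <- 1 / (1 - exp(-co$l2 * P))
  g3 <- 1 / (1 - exp(-co$l3 * P))
  out <- numeric(length(t_cycle))
  for (tj in tau) {
    u <- (t_cycle - tj - ind$tlag) %% P
    out <- out + dose_mg *
      (co$e1 * g1 * exp(-co$l1 * u) + co$e2 * g2 * exp(-co$l2 * u) +
         co$e3 * g3 * exp(-co$l3 * u))
  }
  pmax(out, 0)
}

#' Minimum steady-state endoxifen concentration over a weekly cycle
#'
#' The study endpoint: the minimum endoxifen concentration (C_ss,min) over
#' one 7-day cycle at the periodic steady state of a weekly-repeating
#' once-daily regimen with possibly missed doses. Computed from the
#' closed-form periodic solution on a dense within-cycle grid; because PK is
#' linear, the result is exactly proportional to `dose_mg`.
#'
#' @inheritParams ss_endx_cycle
#' @param dt grid resolution within the cycle (h).
#' @return Minimum endoxifen concentration (ng/mL); 0 for a zero dose or an
#'   all-missed pattern.
#' @examples
#' ind <- individual_params(tam_model(), 2, 55, 70)
#' ss_min_endx(ind, 20)                         # full adherence
#' ss_min_endx(ind, 20, weekly_pattern(2))      # 2 consecutive missed
#' @export
ss_min_endx <- function(ind, dose_mg, pattern = rep(1, 7), dt = 0.25) {
  if (dose_mg == 0 || sum(pattern) == 0) return(0)
  tg <- seq(0, 168 - dt, by = dt)
  min(ss_endx_cycle(ind, dose_mg, pattern, tg))
}
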