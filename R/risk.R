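#' Percentage of patients at risk of target non-attainment
#'
#' @param css numeric vector of steady-state minimum endoxifen
#'   concentrations (ng/mL) for one stratum.
#' @param threshold target threshold (ng/mL).
#' @return `100 * mean(css < threshold)`; `NA_real_` for an empty stratum
#'   (a flagged missing value, never silently 0).
#' @examples
#' percent_at_risk(c(4, 7, 8, 10), 5.97) # 25
#' @export
percent_at_risk <- function(css, threshold = 5.97) {
  if (length(css) == 0) return(NA_real_)
  100 * mean(css < threshold)
}

#' Relative risk increase over the full-adherence baseline
#'
#' Ratio of a scenario's risk to the baseline risk at complete adherence.
#' A zero baseline makes the ratio undefined; it is returned as `NA` with
#' `defined = FALSE` rather than infinity.
#'
#' @param risk_scenario risk (%) under the missed-dose scenario.
#' @param risk_baseline risk (%) at complete adherence.
#' @return List: `ratio`, `defined`.
#' @examples
#' relative_risk_increase(20, 10) # ratio 2
#' @export
relative_risk_increase <- function(risk_scenario, risk_baseline) {
  if (is.na(risk_scenario) || is.na(risk_baseline)) {
    return(list(ratio = NA_real_, defined = FALSE))
  }
  if (risk_baseline == 0) {
    return(list(ratio = NA_real_, defined = FALSE))
  }
  list(ratio = risk_scenario / risk_baseline, defined = TRUE)
}

#' Median and coefficient of variation of an exposure distribution
#'
#' CV% is computed as arithmetic `100 * SD / mean` on the concentration
#' scale (sample SD); a geometric CV (`100 * sqrt(exp(var(log x)) - 1)`) is
#' available as an option since the two definitions can differ appreciably
#' at large variability.
#'
#' @param x concentrations (ng/mL).
#' @param geometric use the geometric CV definition.
#' @return List: `n`, `median`, `cv_pct` (`NA` when `n < 2`).
#' @examples
#' distribution_summary(c(10, 10, 10, 30)) # median 10, CV 66.7%
#' @export
distribution_summary <- function(x, geometric = FALSE) {
  n <- length(x)
  med <- if (n) stats::median(x) else NA_real_
  cv <- if (n < 2) {
    NA_real_
  } else if (geometric) {
    100 * sqrt(exp(stats::var(log(x))) - 1)
  } else {
    100 * stats::sd(x) / mean(x)
  }
  list(n = n, median = med, cv_pct = cv)
}

#' Stratified risk and exposure summary
#'
#' Aggregates a per-patient assessment table into the study's outcome
#' strata: strategy x scenario x phenotype, plus an `Overall` row per
#' strategy x scenario.
#'
#' @param assessments `data.frame` with at least columns `strategy`,
#'   `scenario`, `phenotype`, `css_min_endx` (one row per patient x
#'   strategy x scenario).
#' @param threshold target threshold (ng/mL).
#' @return `data.frame` with columns `strategy`, `scenario`, `phenotype`,
#'   `n`, `percent_below`, `median_css`, `cv_pct`.
#' @export
risk_summary <- function(assessments, threshold = 5.97) {
  req <- c("strategy", "scenario", "phenotype", "css_min_endx")
  stopifnot(all(req %in% names(assessments)))
  strat <- unique(assessments$strategy)
  scen <- sort(unique(assessments$scenario))
  phen <- c("Overall", "gNM", "gIM", "gPM")
  rows <- list()
  for (s in strat) for (sc in scen) for (ph in phen) {
    sel <- assessments$strategy == s & assessments$scenario == sc
    if (ph != "Overall") sel <- sel & assessments$phenotype == ph
    css <- assessments$css_min_endx[sel]
    d <- distribution_summary(css)
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = s, scenario = sc, phenotype = ph, n = d$n,
      percent_below = percent_at_risk(css, threshold),
      median_css = d$median, cv_pct = d$cv_pct)
  }
  do.call(rbind, rows)
}

#' Relative-risk-increase table
#'
#' Joins scenario risks against the full-adherence baseline of the same
#' strategy x phenotype stratum.
#'
#' @param scenario_summary [risk_summary()] rows for scenarios > 0
#'   (non-adherent arms).
#' @param baseline_summary [risk_summary()] rows for the strictly adherent
#'   baseline (scenario 0).
#' @return `data.frame` with `strategy`, `scenario`, `phenotype`,
#'   `risk_pct`, `baseline_pct`, `rri` (`NA` and `rri_defined = FALSE`
#'   where the baseline risk is zero).
#' @export
relative_risk_table <- function(scenario_summary, baseline_summary) {
  base_key <- paste(baseline_summary$strategy, baseline_summary$phenotype)
  out <- scenario_summary[scenario_summary$scenario > 0,
                          c("strategy", "scenario", "phenotype")]
  out$risk_pct <- scenario_summary$percent_below[scenario_summary$scenario > 0]
  idx <- match(paste(out$strategy, out$phenotype), base_key)
  out$baseline_pct <- baseline_summary$percent_below[idx]
  rri <- mapply(function(r, b) relative_risk_increase(r, b)$ratio,
                out$risk_pct, out$baseline_pct)
  out$rri <- as.numeric(rri)
  out$rri_defined <- !is.na(out$rri)
  rownames(out) <- NULL
  out
}

fmt3 <- function(x) ifelse(is.na(x), "", formatC(signif(x, 3), format = "fg"))

pivot_risk <- function(summary_df, strategies, scenarios) {
  phen <- c("Overall", "gNM", "gIM", "gPM")
  out <- data.frame(patient_subpopulation = phen)
  for (s in strategies) for (sc in scenarios) {
    col <- if (length(scenarios) > 1) paste0(s, "_miss", sc) else s
    vals <- vapply(phen, function(ph) {
      sel <- summary_df$strategy == s & summary_df$scenario == sc &
        summary_df$phenotype == ph
      if (any(sel)) summary_df$percent_below[sel][1] else NA_real_
    }, numeric(1))
    out[[col]] <- fmt3(vals)
  }
  out
}

#' Write the study's summary tables
#'
#' Emits four CSVs mirroring the outcome tables of the analysis, values
#' formatted to 3 significant figures:
#' `table1_like.csv` (percent of strictly adherent patients at risk, rows
#' Overall/gNM/gIM/gPM x one column per strategy), `table2_like.csv`
#' (percent of non-adherent patients at risk, strategy x missed-doses
#' columns), `relative_risk.csv` and `distribution_summary.csv`.
#' Missing strata appear as empty cells, never as dropped rows.
#'
#' @param adherent_summary [risk_summary()] of the strictly adherent
#'   patients (scenario 0).
#' @param nonadherent_summary [risk_summary()] of the non-adherent
#'   patients (scenarios 1 and 2).
#' @param rri [relative_risk_table()] output.
#' @param dir output directory (created if needed).
#' @param strategies column order; defaults to the strategies present.
#' @return Invisibly, the vector of files written.
#' @export
write_risk_tables <- function(adherent_summary, nonadherent_summary, rri,
                              dir, strategies = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(strategies)) strategies <- unique(adherent_summary$strategy)
  f1 <- file.path(dir, "table1_like.csv")
  utils::write.csv(pivot_risk(adherent_summary, strategies, 0), f1,
                   row.names = FALSE)
  f2 <- file.path(dir, "table2_like.csv")
  utils::write.csv(pivot_risk(nonadherent_summary, strategies, c(1, 2)),
                   f2, row.names = FALSE)
  f3 <- file.path(dir, "relative_risk.csv")
  utils::write.csv(rri, f3, row.names = FALSE)
  f4 <- file.path(dir, "distribution_summary.csv")
  dist <- rbind(adherent_summary, nonadherent_summary)
  dist <- dist[, c("strategy", "scenario", "phenotype", "n", "median_css",
                   "cv_pct")]
  dist$median_css <- signif(dist$median_css, 3)
  dist$cv_pct <- signif(dist$cv_pct, 3)
  utils::write.csv(dist, f4, row.names = FALSE)
  invisible(c(f1, f2, f3, f4))
}
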