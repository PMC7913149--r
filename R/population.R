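#' CYP2D6 genotype-predicted phenotype from activity score
#'
#' Classification rule: missing scores are imputed to activity score 2;
#' AS >= 1.5 is a genotype-predicted normal metaboliser (gNM), AS 0.5-1 an
#' intermediate metaboliser (gIM), and AS 0 a poor metaboliser (gPM).
#'
#' @param activity_score numeric vector with values in
#'   `{0, 0.5, 1, 1.5, 2}` or `NA`.
#' @return Character vector with values `"gNM"`, `"gIM"`, `"gPM"`.
#' @examples
#' classify_phenotype(c(2, 1, 0, NA))
#' @export
classify_phenotype <- function(activity_score) {
  as_imp <- ifelse(is.na(activity_score), 2, activity_score)
  if (!all(as_imp %in% c(0, 0.5, 1, 1.5, 2))) {
    stop("classify_phenotype: activity score must be 0, 0.5, 1, 1.5, 2 or NA",
         call. = FALSE)
  }
  ifelse(as_imp >= 1.5, "gNM", ifelse(as_imp >= 0.5, "gIM", "gPM"))
}

#' Virtual population specification
#'
#' Describes the synthetic cohort emulating the model-development
#' population: a CYP2D6 phenotype mixture (default 56.6% gNM / 37.8% gIM /
#' 5.6% gPM), activity-score composition within each class, age and weight
#' marginals, and the log-normal IIV variances. Age and weight marginals are
#' configurable stand-ins (truncated normal and log-normal) for the
#' unavailable clinical covariate table that the original study resampled.
#'
#' @param n number of patients (`>= 0`).
#' @param phenotype_probs named probabilities for `gNM`, `gIM`, `gPM`
#'   (sum to 1).
#' @param as_gNM,as_gIM named probabilities over activity scores within the
#'   gNM and gIM classes (gPM is AS 0 by definition).
#' @param age_mean,age_sd,age_min,age_max truncated-normal age marginal (y).
#' @param weight_median,weight_cv log-normal body-weight marginal (kg,
#'   coefficient of variation).
#' @param omega2_CL23,omega2_CL20 IIV variances for the individual random
#'   effects.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n = 10000,
                            phenotype_probs = c(gNM = 0.566, gIM = 0.378,
                                                gPM = 0.056),
                            as_gNM = c("2" = 0.8, "1.5" = 0.2),
                            as_gIM = c("1" = 0.5, "0.5" = 0.5),
                            age_mean = 55, age_sd = 12,
                            age_min = 25, age_max = 90,
                            weight_median = 70, weight_cv = 0.20,
                            omega2_CL23 = 0.25, omega2_CL20 = 0.06) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("population_spec: n must be a non-negative integer", call. = FALSE)
  }
  for (p in list(phenotype_probs, as_gNM, as_gIM)) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("population_spec: mixture probabilities must be >= 0 and sum to 1",
           call. = FALSE)
    }
  }
  if (!setequal(names(phenotype_probs), c("gNM", "gIM", "gPM"))) {
    stop("population_spec: phenotype_probs must be named gNM, gIM, gPM",
         call. = FALSE)
  }
  if (age_min <= 0 || age_max <= age_min || age_sd <= 0 ||
      weight_median <= 0 || weight_cv <= 0) {
    stop("population_spec: invalid age/weight marginal parameters",
         call. = FALSE)
  }
  if (omega2_CL23 < 0 || omega2_CL20 < 0) {
    stop("population_spec: IIV variances must be >= 0", call. = FALSE)
  }
  structure(as.list(environment()), class = "population_spec")
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out
}

#' Generate a virtual patient population
#'
#' Samples `n` patients: phenotype class from the mixture, an activity score
#' within the class, age (truncated normal), body weight (log-normal), and
#' independent mean-zero normal random effects `eta_cl23`, `eta_cl20` with
#' the spec's variances. Reproducible under a fixed seed.
#'
#' @param spec a [population_spec()].
#' @param seed integer RNG seed (optional; the caller may also manage the
#'   RNG state itself).
#' @return `data.frame` with columns `id`, `activity_score`, `phenotype`,
#'   `age`, `weight`, `eta_cl23`, `eta_cl20`.
#' @examples
#' pop <- generate_population(population_spec(n = 100), seed = 1)
#' table(pop$phenotype)
#' @export
generate_population <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  if (n == 0) {
    return(data.frame(id = integer(), activity_score = numeric(),
                      phenotype = character(), age = numeric(),
                      weight = numeric(), eta_cl23 = numeric(),
                      eta_cl20 = numeric()))
  }
  phen <- sample(names(spec$phenotype_probs), n, replace = TRUE,
                 prob = spec$phenotype_probs)
  as_score <- numeric(n)
  for (cls in c("gNM", "gIM")) {
    idx <- which(phen == cls)
    tab <- if (cls == "gNM") spec$as_gNM else spec$as_gIM
    if (length(idx)) {
      as_score[idx] <- as.numeric(sample(names(tab), length(idx),
                                         replace = TRUE, prob = tab))
    }
  }
  as_score[phen == "gPM"] <- 0
  age <- rtruncnorm1(n, spec$age_mean, spec$age_sd, spec$age_min,
                     spec$age_max)
  sdlog <- sqrt(log(1 + spec$weight_cv^2))
  weight <- stats::rlnorm(n, meanlog = log(spec$weight_median),
                          sdlog = sdlog)
  data.frame(
    id = seq_len(n),
    activity_score = as_score,
    phenotype = classify_phenotype(as_score),
    age = age,
    weight = weight,
    eta_cl23 = stats::rnorm(n, 0, sqrt(spec$omega2_CL23)),
    eta_cl20 = stats::rnorm(n, 0, sqrt(spec$omega2_CL20))
  )
}

.pop_columns <- c("id", "activity_score", "phenotype", "age", "weight",
                  "eta_cl23", "eta_cl20")

#' Write / read a virtual population table
#'
#' CSV round-trip with the documented column order
#' (`id, activity_score, phenotype, age, weight, eta_cl23, eta_cl20`).
#' `read_population()` validates every row and reports the offending file
#' line on failure.
#'
#' @param pop population `data.frame` as from [generate_population()].
#' @param path file path.
#' @return `read_population()` returns the validated `data.frame`;
#'   `write_population()` returns `path` invisibly.
#' @export
write_population <- function(pop, path) {
  stopifnot(all(.pop_columns %in% names(pop)))
  utils::write.csv(pop[, .pop_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  header <- utils::read.csv(path, nrows = 1, check.names = FALSE)
  if (!identical(names(header), .pop_columns)) {
    stop("read_population: malformed header at line 1; expected columns ",
         paste(.pop_columns, collapse = ","), call. = FALSE)
  }
  pop <- utils::read.csv(path)
  bad_line <- function(i, what) {
    stop(sprintf("read_population: line %d: %s", i + 1L, what),
         call. = FALSE)
  }
  for (i in seq_len(nrow(pop))) {
    r <- pop[i, ]
    if (is.na(r$age) || r$age <= 0) bad_line(i, "age must be > 0")
    if (is.na(r$weight) || r$weight <= 0) bad_line(i, "weight must be > 0")
    if (!is.na(r$activity_score) &&
        !r$activity_score %in% c(0, 0.5, 1, 1.5, 2)) {
      bad_line(i, "activity_score not in {0, 0.5, 1, 1.5, 2, NA}")
    }
    if (!identical(as.character(r$phenotype),
                   classify_phenotype(r$activity_score))) {
      bad_line(i, "phenotype inconsistent with activity score")
    }
    if (!is.finite(r$eta_cl23) || !is.finite(r$eta_cl20)) {
      bad_line(i, "non-finite random effect")
    }
  }
  pop
}
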