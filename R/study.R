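#' Derive a named sub-stream seed from the master seed
#'
#' Each stochastic stage (population generation, TDM noise, adherence
#' assignment) draws from its own stream derived deterministically from the
#' master seed, so stages can be re-run independently with identical
#' streams.
#'
#' @param seed master seed (integer).
#' @param name stream name.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483646 + 1)
}

#' Full study configuration
#'
#' Bundles the PK model, the virtual-population specification, the five
#' dosing strategies, the adherence design (fraction of non-adherent
#' patients, phase durations, missed-dose scenarios) and the master seed.
#'
#' @param model a [tam_model()].
#' @param population a [population_spec()].
#' @param strategies named list of [strategy_config()]s.
#' @param nonadherent_fraction fraction of patients who become
#'   non-adherent in the second phase (default 0.40).
#' @param phase1_weeks,phase2_weeks phase durations (weeks).
#' @param scenarios missed-doses-per-week values simulated for the
#'   non-adherent subset.
#' @param seed master RNG seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(model = tam_model(),
                         population = population_spec(),
                         strategies = default_strategies(),
                         nonadherent_fraction = 0.40,
                         phase1_weeks = 26, phase2_weeks = 26,
                         scenarios = c(1, 2),
                         seed = 20210203) {
  cfg <- structure(list(model = model, population = population,
                        strategies = strategies,
                        nonadherent_fraction = nonadherent_fraction,
                        phase1_weeks = phase1_weeks,
                        phase2_weeks = phase2_weeks,
                        scenarios = scenarios, seed = seed),
                   class = "study_config")
  v <- validate_config(cfg)
  if (nrow(v)) {
    stop("study_config: invalid configuration:\n",
         paste(sprintf("  %s: %s", v$field, v$message), collapse = "\n"),
         call. = FALSE)
  }
  cfg
}

#' Validate a study configuration
#'
#' Checks every configuration invariant and reports all violations with
#' their field paths. Accepts a `study_config` object or the path of a YAML
#' config file.
#'
#' @param config `study_config`, plain list, or file path.
#' @return `data.frame` with columns `field`, `message`; zero rows when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_study_config(config, validate = FALSE)
  viol <- list()
  add <- function(field, message) {
    viol[[length(viol) + 1L]] <<- data.frame(field = field,
                                             message = message)
  }
  m <- config$model
  if (is.null(m)) {
    add("model", "missing section")
  } else {
    ok <- try(validate_tam_model(m), silent = TRUE)
    if (inherits(ok, "try-error")) {
      add("model", sub("^Error[^:]*: ", "", trimws(as.character(ok))))
    }
  }
  p <- config$population
  if (is.null(p)) {
    add("population", "missing section")
  } else if (!inherits(p, "population_spec")) {
    add("population", "not a population_spec")
  }
  if (!is.null(m) && !is.null(p) && inherits(p, "population_spec")) {
    scores <- unique(c(names(p$as_gNM), names(p$as_gIM), "0"))
    missing_as <- setdiff(scores, names(m$theta_AS))
    if (length(missing_as)) {
      add("model.theta_AS",
          paste("no fractional change defined for activity score(s)",
                paste(missing_as, collapse = ", ")))
    }
  }
  st <- config$strategies
  if (is.null(st) || !length(st)) {
    add("strategies", "at least one strategy required")
  } else {
    labels <- vapply(st, function(s) s$label, character(1))
    if (anyDuplicated(labels)) add("strategies", "strategy labels not unique")
    for (i in seq_along(st)) {
      if (!inherits(st[[i]], "strategy_config")) {
        add(paste0("strategies[", i, "]"), "not a strategy_config")
        next
      }
      if (st[[i]]$target_trough <= 0) {
        add(paste0("strategies[", i, "].target_trough"), "must be > 0")
      }
    }
  }
  if (is.null(config$nonadherent_fraction) ||
      config$nonadherent_fraction < 0 || config$nonadherent_fraction > 1) {
    add("nonadherent_fraction", "must be in [0, 1]")
  }
  for (f in c("phase1_weeks", "phase2_weeks")) {
    if (is.null(config[[f]]) || config[[f]] <= 0) add(f, "must be > 0")
  }
  if (!all(config$scenarios %in% c(1, 2))) {
    add("scenarios", "must be a subset of {1, 2}")
  }
  if (length(viol) == 0) {
    return(data.frame(field = character(), message = character()))
  }
  do.call(rbind, viol)
}

#' Read a study configuration from YAML
#'
#' The configuration file holds one section per component (`model`,
#' `population`, `strategies`, `adherence`, `seed`); unspecified fields
#' take the package defaults. The packaged default file documents every
#' field: `system.file("extdata", "default_config.yaml",
#' package = "endoxsim")`.
#'
#' @param path YAML file path.
#' @param validate validate after loading (set `FALSE` to inspect an
#'   invalid file with [validate_config()]).
#' @return A `study_config` (or unvalidated equivalent list).
#' @export
read_study_config <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    stop("read_study_config: cannot read '", path, "'", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  my <- y$model
  if (!is.null(my$theta_AS)) my$theta_AS <- unlist(my$theta_AS)
  model <- do.call(tam_model, my %||% list())
  py <- y$population
  # YAML 1.1 parses a bare `n` key as a boolean, so the file uses
  # `n_patients`; accept both spellings (and a mangled boolean key).
  names(py)[names(py) %in% c("n_patients", "FALSE")] <- "n"
  for (f in c("as_gNM", "as_gIM", "phenotype_probs")) {
    if (!is.null(py[[f]])) py[[f]] <- unlist(py[[f]])
  }
  population <- do.call(population_spec, py %||% list())
  strategies <- if (is.null(y$strategies)) {
    default_strategies()
  } else {
    out <- lapply(y$strategies, function(s) {
      s$dose_grid <- unlist(s$dose_grid %||% NULL) %||%
        c(5, 10, 20, 30, 40, 60, 80, 100, 120)
      s$tdm_days <- unlist(s$tdm_days %||% NULL) %||% c(14, 21, 28)
      do.call(strategy_config, s)
    })
    names(out) <- vapply(out, function(s) s$label, character(1))
    out
  }
  ad <- y$adherence %||% list()
  cfg <- structure(list(
    model = model, population = population, strategies = strategies,
    nonadherent_fraction = ad$nonadherent_fraction %||% 0.40,
    phase1_weeks = ad$phase1_weeks %||% 26,
    phase2_weeks = ad$phase2_weeks %||% 26,
    scenarios = unlist(ad$scenarios %||% c(1, 2)),
    seed = y$seed %||% 20210203
  ), class = "study_config")
  if (validate) {
    v <- validate_config(cfg)
    if (nrow(v)) {
      stop("read_study_config: invalid configuration:\n",
           paste(sprintf("  %s: %s", v$field, v$message), collapse = "\n"),
           call. = FALSE)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dose decisions for every patient under every strategy. MIPD strategies
# share one TDM series and one MAP estimate per patient; only the
# target/increment-specific grid selection differs.
assign_doses <- function(config, pop, seed) {
  model <- config$model
  n <- nrow(pop)
  mipd <- Filter(function(s) s$strategy == "mipd", config$strategies)
  need_map <- length(mipd) > 0 && n > 0
  eta23_hat <- eta20_hat <- rep(NA_real_, n)
  tdm_seed <- substream_seed(seed, "tdm")
  if (need_map) {
    set.seed(tdm_seed)
    tdm_days <- mipd[[1]]$tdm_days
    init_days <- mipd[[1]]$initial_phase_days
    for (i in seq_len(n)) {
      ind <- individual_params(model, pop$activity_score[i], pop$age[i],
                               pop$weight[i], pop$eta_cl23[i],
                               pop$eta_cl20[i])
      d0 <- genotype_guided_dose(pop$phenotype[i])
      obs <- simulate_tdm(ind, d0, tdm_days, model$sigma_prop, init_days)
      est <- map_estimate(model, obs, pop$activity_score[i], pop$age[i],
                          pop$weight[i], d0, init_days)
      eta23_hat[i] <- est$eta_cl23
      eta20_hat[i] <- est$eta_cl20
    }
  }
  rows <- list()
  for (s in config$strategies) {
    init <- switch(s$strategy,
                   conventional = conventional_dose(pop$phenotype),
                   cyp2d6_guided = genotype_guided_dose(pop$phenotype),
                   mipd = genotype_guided_dose(pop$phenotype))
    if (s$strategy == "mipd") {
      maint <- numeric(n); capped <- logical(n)
      for (i in seq_len(n)) {
        sel <- select_mipd_dose(model,
                                c(eta23_hat[i], eta20_hat[i]),
                                pop$activity_score[i], pop$age[i],
                                pop$weight[i], s$dose_grid,
                                s$target_trough, s$dose_increment)
        maint[i] <- sel$dose
        capped[i] <- sel$capped
      }
    } else {
      maint <- init
      capped <- rep(FALSE, n)
    }
    rows[[s$label]] <- data.frame(
      id = pop$id, strategy = s$label, initial_dose = init,
      eta_hat_cl23 = if (s$strategy == "mipd") eta23_hat else NA_real_,
      eta_hat_cl20 = if (s$strategy == "mipd") eta20_hat else NA_real_,
      selected_dose = maint, capped = capped)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the complete in-silico non-adherence study
#'
#' The full pipeline: generate the virtual population; assign each
#' strategy's doses (for MIPD: simulate TDM samples under the
#' genotype-guided initial dose, MAP-estimate the individual random
#' effects, select the maintenance dose against the trough target); assign
#' 60%/40% adherent/non-adherent status; evaluate every patient's
#' steady-state minimum endoxifen concentration at the end of the study
#' under full adherence and, for the non-adherent subset, under both
#' missed-dose scenarios (the same patients, doses and random effects in
#' both arms); and summarise risks per stratum. Deterministic under a fixed
#' master seed via named sub-streams.
#'
#' @param config a [study_config()].
#' @param seed master seed (defaults to the config's).
#' @param outdir optional output directory; when given, all result CSVs
#'   (population, dose decisions, assessments, summary tables) and a JSON
#'   run manifest are written. On any stage failure partial outputs are
#'   removed.
#' @param verbose print stage progress with patient-count checksums.
#' @return List with `population`, `doses`, `assessments`,
#'   `adherent_summary`, `nonadherent_summary`, `relative_risk`, `files`.
#' @examples
#' \donttest{
#' cfg <- study_config(population = population_spec(n = 50), seed = 1)
#' res <- run_study(cfg, verbose = FALSE)
#' head(res$adherent_summary)
#' }
#' @export
run_study <- function(config = study_config(), seed = config$seed,
                      outdir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  written <- character()
  stage <- "setup"
  say <- function(...) if (verbose) message(sprintf(...))
  res <- tryCatch({
    stage <- "generate_population"
    pop <- generate_population(config$population,
                               substream_seed(seed, "population"))
    say("stage %s: %d patients", stage, nrow(pop))

    stage <- "assign_doses"
    doses <- assign_doses(config, pop, seed)
    say("stage %s: %d dose decisions", stage, nrow(doses))

    stage <- "assign_adherence"
    set.seed(substream_seed(seed, "adherence"))
    nonadh <- stats::runif(nrow(pop)) < config$nonadherent_fraction
    say("stage %s: %d non-adherent of %d", stage, sum(nonadh), nrow(pop))

    stage <- "assess"
    scen0 <- adherence_scenario(0, config$phase1_weeks, config$phase2_weeks)
    scen_list <- lapply(config$scenarios, adherence_scenario,
                        phase1_weeks = config$phase1_weeks,
                        phase2_weeks = config$phase2_weeks)
    inds <- lapply(seq_len(nrow(pop)), function(i) {
      individual_params(config$model, pop$activity_score[i], pop$age[i],
                        pop$weight[i], pop$eta_cl23[i], pop$eta_cl20[i])
    })
    rows <- list()
    for (s in config$strategies) {
      ds <- doses[doses$strategy == s$label, ]
      ds <- ds[match(pop$id, ds$id), ]
      for (i in seq_len(nrow(pop))) {
        css0 <- ss_min_endx(inds[[i]], ds$selected_dose[i], scen0$pattern)
        rows[[length(rows) + 1L]] <- data.frame(
          id = pop$id[i], strategy = s$label, scenario = 0,
          phenotype = pop$phenotype[i], adherent = !nonadh[i],
          dose = ds$selected_dose[i], css_min_endx = css0)
        if (nonadh[i]) {
          for (sc in scen_list) {
            rows[[length(rows) + 1L]] <- data.frame(
              id = pop$id[i], strategy = s$label,
              scenario = sc$missed_per_week,
              phenotype = pop$phenotype[i], adherent = FALSE,
              dose = ds$selected_dose[i],
              css_min_endx = ss_min_endx(inds[[i]], ds$selected_dose[i],
                                         sc$pattern))
          }
        }
      }
    }
    assessments <- do.call(rbind, c(rows, make.row.names = FALSE))
    assessments$below_597 <- assessments$css_min_endx < 5.97
    assessments$below_9 <- assessments$css_min_endx < 9
    say("stage %s: %d assessments", stage, nrow(assessments))

    stage <- "summarise"
    adh <- risk_summary(assessments[assessments$scenario == 0 &
                                      assessments$adherent, ])
    nad <- risk_summary(assessments[assessments$scenario > 0, ])
    rri <- relative_risk_table(nad, adh)

    stage <- "write_outputs"
    files <- character()
    if (!is.null(outdir)) {
      if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
      wp <- file.path(outdir, "population.csv")
      write_population(pop, wp); written <<- c(written, wp)
      wd <- file.path(outdir, "dose_decisions.csv")
      utils::write.csv(doses, wd, row.names = FALSE)
      written <<- c(written, wd)
      wa <- file.path(outdir, "assessments.csv")
      utils::write.csv(assessments, wa, row.names = FALSE)
      written <<- c(written, wa)
      tf <- write_risk_tables(adh, nad, rri, outdir,
                              strategies = vapply(config$strategies,
                                                  function(s) s$label,
                                                  character(1)))
      written <<- c(written, tf)
      mf <- file.path(outdir, "run_manifest.json")
      jsonlite::write_json(list(
        package = "endoxsim",
        version = as.character(utils::packageVersion("endoxsim")),
        seed = seed, n = nrow(pop),
        strategies = vapply(config$strategies, function(s) s$label,
                            character(1)),
        scenarios = config$scenarios,
        nonadherent_fraction = config$nonadherent_fraction
      ), mf, auto_unbox = TRUE, pretty = TRUE)
      written <<- c(written, mf)
      files <- written
    }
    list(population = pop, doses = doses, assessments = assessments,
         adherent_summary = adh, nonadherent_summary = nad,
         relative_risk = rri, files = files)
  }, error = function(e) {
    unlink(written)
    stop("run_study: stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  res
}
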