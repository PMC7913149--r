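test_that("activity score maps to genotype-predicted phenotype", {
  expect_identical(classify_phenotype(2), "gNM")
  expect_identical(classify_phenotype(1.5), "gNM")
  expect_identical(classify_phenotype(1), "gIM")
  expect_identical(classify_phenotype(0.5), "gIM")
  expect_identical(classify_phenotype(0), "gPM")
  expect_identical(classify_phenotype(NA), "gNM") # missing imputed to AS 2
  expect_error(classify_phenotype(0.7), "activity score")
})

test_that("an empty population is a zero-row table", {
  pop <- generate_population(population_spec(n = 0), seed = 1)
  expect_identical(nrow(pop), 0L)
  expect_true(all(c("id", "activity_score", "phenotype", "age", "weight",
                    "eta_cl23", "eta_cl20") %in% names(pop)))
})

test_that("phenotype mixture matches the specified frequencies", {
  spec <- population_spec(n = 10000)
  pop <- generate_population(spec, seed = 11)
  p <- spec$phenotype_probs
  for (cls in names(p)) {
    obs <- mean(pop$phenotype == cls)
    se <- sqrt(p[[cls]] * (1 - p[[cls]]) / spec$n)
    expect_lt(abs(obs - p[[cls]]), 3 * se)
  }
  expect_true(all(pop$phenotype == classify_phenotype(pop$activity_score)))
  expect_true(all(pop$age >= spec$age_min & pop$age <= spec$age_max))
  expect_true(all(pop$weight > 0))
})

test_that("phenotype counts pass a chi-square GOF across seeded replicates", {
  spec <- population_spec(n = 10000)
  p <- spec$phenotype_probs[c("gNM", "gIM", "gPM")]
  pvals <- vapply(1:100, function(s) {
    pop <- generate_population(spec, seed = 1000 + s)
    counts <- table(factor(pop$phenotype, levels = names(p)))
    suppressWarnings(stats::chisq.test(counts, p = p)$p.value)
  }, numeric(1))
  # at alpha = 0.001 the expected number of false alarms in 100 replicates
  # is 0.1; two or more would indicate a real mixture defect
  expect_lte(sum(pvals <= 0.001), 1)
  expect_gt(mean(pvals), 0.25) # bulk of replicates comfortably consistent
})

test_that("random effects have the specified variance and no autocorrelation", {
  spec <- population_spec(n = 10000)
  pop <- generate_population(spec, seed = 5)
  expect_lt(abs(var(pop$eta_cl23) / spec$omega2_CL23 - 1), 0.10)
  expect_lt(abs(var(pop$eta_cl20) / spec$omega2_CL20 - 1), 0.10)
  expect_lt(abs(mean(pop$eta_cl23)), 4 * sqrt(spec$omega2_CL23 / spec$n))
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(lag1(pop$eta_cl23)), 0.05)
  expect_lt(abs(lag1(pop$eta_cl20)), 0.05)
})

test_that("generation is deterministic under a fixed seed", {
  spec <- population_spec(n = 500)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_population(generate_population(spec, seed = 99), f1)
  write_population(generate_population(spec, seed = 99), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    generate_population(spec, seed = 99)$age,
    generate_population(spec, seed = 100)$age))
})

test_that("population tables round-trip through CSV", {
  pop <- data.frame(id = 1:3, activity_score = c(2, 1, 0),
                    phenotype = c("gNM", "gIM", "gPM"),
                    age = c(45, 60.5, 72), weight = c(58, 70, 81.25),
                    eta_cl23 = c(0.25, -0.5, 0),
                    eta_cl20 = c(0, 0.125, -0.25))
  f <- tempfile(fileext = ".csv")
  write_population(pop, f)
  expect_equal(read_population(f), pop)
  # empty population writes a header-only file
  f0 <- tempfile(fileext = ".csv")
  write_population(generate_population(population_spec(n = 0)), f0)
  expect_identical(length(readLines(f0)), 1L)
})

test_that("malformed population files are rejected with a line number", {
  pop <- data.frame(id = 1:2, activity_score = c(2, 1),
                    phenotype = c("gNM", "gIM"), age = c(45, 60),
                    weight = c(58, -70), eta_cl23 = c(0, 0),
                    eta_cl20 = c(0, 0))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(pop, f, row.names = FALSE)
  expect_error(read_population(f), "line 3.*weight")
  pop$weight[2] <- 70; pop$phenotype[2] <- "gPM"
  utils::write.csv(pop, f, row.names = FALSE)
  expect_error(read_population(f), "line 3.*phenotype")
  writeLines(c("id,age", "1,50"), f)
  expect_error(read_population(f), "header")
})
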