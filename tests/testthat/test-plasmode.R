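# True outcome-generating model and plasmode resampling.

test_that("design matrix expands polynomial, interaction and transform terms", {
  X <- data.frame(age = 2, pafi = 0.5, heart_rate = 3, mean_bp = -1,
                  gcs = 2, hematocrit = -1, sodium = 0.5, weight = 0,
                  apache = 0)
  co <- manual_cohort(rbind(X, X), A = c(0, 1))
  terms <- list(list(type = "poly", var = "age", degree = 3L),
                list(type = "interaction", vars = c("heart_rate", "mean_bp")),
                list(type = "interaction",
                     vars = c("gcs", "hematocrit", "sodium")),
                list(type = "transform", var = "weight", fn = "exp"),
                list(type = "transform", var = "apache", fn = "cos"))
  D <- build_design_matrix(co, terms)
  expect_equal(unname(D[1, c("age^1", "age^2", "age^3")]), c(2, 4, 8))
  expect_equal(unname(D[1, "heart_rate:mean_bp"]), -3)
  expect_equal(unname(D[1, "gcs:hematocrit:sodium"]), -1)
  expect_equal(unname(D[1, "exp(weight)"]), 1)
  expect_equal(unname(D[1, "cos(apache)"]), 1)
  expect_error(build_design_matrix(co, list(list(type = "main", var = "zzz"))),
               "zzz")
})

test_that("default term list covers all covariates plus the special terms", {
  co <- preprocess(small_cohort(200, n_binary = 2L, n_categorical = 1L))
  terms <- dgm_terms(co$schema)
  D <- build_design_matrix(co, terms)
  # main effect of every covariate appears (age/pafi via their first powers)
  labs <- colnames(D)
  expect_true(all(setdiff(names(co$X), c("age", "pafi")) %in% labs))
  expect_true(all(c("age^1", "age^2", "age^3", "pafi^1", "pafi^2",
                    "heart_rate:mean_bp", "gcs:hematocrit:sodium",
                    "exp(weight)", "cos(apache)") %in% labs))
  expect_equal(ncol(D), ncol(co$X) - 2 + 5 + 2 + 2)
})

test_that("fitting a null outcome gives near-zero coefficients and an exact overwrite", {
  co <- preprocess(small_cohort(4000, seed = 11, confounding_strength = 0))
  co$Y <- with(list(), {set.seed(2); rbinom(4000, 1, 0.4)})  # Y independent
  spec <- fit_true_outcome_model(co, true_or = 0.7)
  expect_equal(spec$beta_treatment, log(0.7))
  expect_equal(spec$beta_treatment, -0.356675, tolerance = 1e-6)
  expect_lt(max(abs(spec$beta)), 0.25)  # null fit, sampling noise only
  spec1 <- fit_true_outcome_model(co, true_or = 1.0)
  expect_identical(spec1$beta_treatment, 0)
})

test_that("intercept calibration matches a bisection oracle", {
  co <- preprocess(small_cohort(200, seed = 3))
  spec <- fit_true_outcome_model(co, true_or = 0.7)
  # degenerate oracle case: all coefficients zero -> intercept is logit(target)
  spec0 <- spec
  spec0$beta[] <- 0
  spec0$beta_treatment <- 0
  out0 <- calibrate_intercept(spec0, co, 0.5)
  expect_equal(out0$intercept, 0, tolerance = 1e-8)

  # scalar oracle: lp values {0, 0, 2}, target 0.7, solved by bisection
  f <- function(b) (2 * plogis(b) + plogis(b + 2)) / 3 - 0.7
  lo <- -10; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  oracle <- (lo + hi) / 2
  expect_equal(plasmatch:::solve_intercept(c(0, 0, 2), 0.7), oracle,
               tolerance = 1e-7)

  # full spec: calibrated mean equals the target to high precision
  out <- calibrate_intercept(spec, co, 0.3)
  pr <- plogis(out$intercept + plasmatch:::dgm_linear_predictor(out, co))
  expect_equal(mean(pr), 0.3, tolerance = 1e-8)
})

test_that("stratified resampling hits exact treated counts and keeps rows intact", {
  base <- preprocess(small_cohort(1500, seed = 5))
  r1 <- resample_base(base, 3500, 0.30, seed = 10)
  expect_equal(sum(r1$A), 1050L)
  expect_equal(nrow(r1$X), 3500L)
  r2 <- resample_base(base, 3500, 0.05, seed = 10)
  expect_equal(sum(r2$A), 175L)
  expect_error(resample_base(base, 3500, 1.0), "stratum")

  # row identity: every resampled row matches its base row exactly
  rows <- attr(r1, "base_rows")
  expect_equal(unname(as.matrix(r1$X)), unname(as.matrix(base$X)[rows, ]))
  expect_equal(r1$A, base$A[rows])

  # determinism
  expect_identical(r1$X, resample_base(base, 3500, 0.30, seed = 10)$X)
})

test_that("simulated outcomes are Bernoulli draws from the calibrated model", {
  base <- preprocess(small_cohort(2000, seed = 6))
  sc <- scenario_config("i", 0.30, 0.30, 0.7, 3500, n_sims = 1)
  dgm <- build_dgm(base, sc)
  dat <- resample_base(base, 3500, 0.30, seed = 1)
  a <- simulate_outcomes(dgm, dat, seed = 2)
  b <- simulate_outcomes(dgm, dat, seed = 2)
  expect_identical(a$data$Y, b$data$Y)
  expect_false(identical(a$data$Y, simulate_outcomes(dgm, dat, 3)$data$Y))

  uncal <- fit_true_outcome_model(base, true_or = 0.7)
  expect_error(simulate_outcomes(uncal, dat, 1), "calibrated")

  # null-coefficient spec calibrated to 0.30 gives mean(Y) near 0.30
  null_spec <- uncal
  null_spec$beta[] <- 0
  null_spec$beta_treatment <- 0
  null_spec <- calibrate_intercept(null_spec, dat, 0.30)
  y <- simulate_outcomes(null_spec, dat, seed = 9)$data$Y
  expect_lt(abs(mean(y) - 0.30), 3 * sqrt(0.3 * 0.7 / 3500))
})

test_that("refitting the true model on a very large replicate recovers the injected OR", {
  base <- preprocess(generate_cohort(4000, seed = 21))
  sc <- scenario_config("i", 0.30, 0.30, 0.7, 3500)
  dgm <- build_dgm(base, sc)
  big <- resample_base(base, 150000, 0.30, seed = 30)
  rep_big <- simulate_outcomes(dgm, big, seed = 31)
  D <- build_design_matrix(rep_big$data, dgm$terms)
  fit <- plasmatch:::fit_logistic(cbind(A = rep_big$data$A, D), rep_big$data$Y)
  or_hat <- exp(unname(fit$coef["A"]))
  se <- unname(fit$se["A"])
  expect_lt(abs(log(or_hat) - log(0.7)), 3 * se)
  expect_equal(or_hat, 0.7, tolerance = 0.05)
  # achieved outcome prevalence close to the calibration target
  expect_lt(abs(mean(rep_big$data$Y) - 0.30), 0.01)
})

test_that("scenario grid matches the registered settings", {
  sc <- default_scenarios()
  grid <- t(vapply(sc, function(s)
    c(s$exposure_prevalence, s$outcome_prevalence, s$true_or, s$sample_size),
    numeric(4)))
  expect_equal(unname(grid),
               matrix(c(0.30, 0.30, 0.7, 3500,
                        0.05, 0.30, 0.7, 3500,
                        0.30, 0.05, 0.7, 3500,
                        0.30, 0.30, 0.7, 5000,
                        0.30, 0.30, 1.0, 3500),
                      ncol = 4, byrow = TRUE))
  expect_equal(sc$i$n_sims, 1000L)
  dir <- withr::local_tempdir()
  write_scenarios_yaml(sc, file.path(dir, "sc.yaml"))
  back <- read_scenarios_yaml(file.path(dir, "sc.yaml"))
  expect_equal(back$ii$exposure_prevalence, 0.05)
  expect_equal(back$v$true_or, 1.0)
})
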