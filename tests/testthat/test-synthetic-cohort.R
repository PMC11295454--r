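test_that("generated cohort has the requested dimensions and calibrated exposure", {
  co <- generate_cohort(5735, exposure_prevalence = 0.38, seed = 1)
  expect_s3_class(co, "cohort")
  expect_equal(dim(co), c(5735L, 50L))
  expect_equal(nrow(co$schema), 50L)
  expect_true(all(dgm_special_names() %in% names(co$X)))
  # realized prevalence within ~3 binomial SDs of the calibrated target
  expect_lt(abs(mean(co$A) - 0.38), 3 * sqrt(0.38 * 0.62 / 5735))
  expect_false(anyNA(co$X))
})

test_that("zero confounding strength makes exposure independent of covariates", {
  co <- preprocess(generate_cohort(8000, confounding_strength = 0, seed = 4,
                                   outcome_prevalence = NULL))
  smds <- vapply(co$X, function(v) smd(v, co$A), 0)
  expect_lt(max(abs(smds)), 0.08)  # sampling error only at n = 8000
})

test_that("positive confounding strength induces covariate imbalance", {
  co <- preprocess(generate_cohort(8000, confounding_strength = 1, seed = 4,
                                   outcome_prevalence = NULL))
  smds <- vapply(co$X, function(v) smd(v, co$A), 0)
  expect_gt(max(abs(smds)), 0.1)
})

test_that("cohort generation is deterministic in the seed and varies across seeds", {
  a <- generate_cohort(300, seed = 7,
                       schema = default_schema(9L, 2L, 1L))
  b <- generate_cohort(300, seed = 7,
                       schema = default_schema(9L, 2L, 1L))
  c <- generate_cohort(300, seed = 8,
                       schema = default_schema(9L, 2L, 1L))
  expect_identical(a, b)
  expect_false(identical(a$X, c$X))
})

test_that("achieved exposure prevalence is unbiased over repeated cohorts", {
  target <- 0.30
  prev <- vapply(1:200, function(s)
    mean(generate_cohort(500, exposure_prevalence = target, seed = s,
                         schema = default_schema(9L, 2L, 0L),
                         outcome_prevalence = NULL)$A), 0)
  mcse <- sd(prev) / sqrt(length(prev))
  expect_lt(abs(mean(prev) - target), 2 * mcse + 1e-12)
})

test_that("generation rejects invalid prevalence and sample size", {
  expect_error(generate_cohort(100, exposure_prevalence = 0), "prevalence")
  expect_error(generate_cohort(100, exposure_prevalence = 1), "prevalence")
  expect_error(generate_cohort(1), "n must be")
})

test_that("preprocess centers and scales with the n-1 denominator", {
  co <- manual_cohort(data.frame(x = c(1, 2, 3)), A = c(0, 1, 0))
  co$scaled <- FALSE
  out <- preprocess(co)
  expect_equal(out$X$x, c(-1, 0, 1))
  expect_true(out$scaled)
  expect_error(preprocess(out), "already")
})

test_that("preprocess leaves binaries alone and reference-codes categoricals", {
  X <- data.frame(x = rnorm(20), b = rep(c(0, 1), 10),
                  g = rep(c("a", "b", "c", "a"), 5))
  schema <- cov_schema(c("x", "b", "g"),
                       c("continuous", "binary", "categorical"),
                       levels = list(NULL, NULL, c("a", "b", "c")),
                       role = rep("plain", 3))
  co <- new_cohort(X, A = rep(c(0, 1), 10), schema = schema)
  out <- preprocess(co)
  expect_identical(out$X$b, X$b)
  expect_setequal(names(out$X), c("x", "b", "g.b", "g.c"))
  expect_equal(out$X$g.b, as.numeric(X$g == "b"))
  expect_lt(abs(mean(out$X$x)), 1e-10)
  expect_equal(sd(out$X$x), 1, tolerance = 1e-10)
})

test_that("preprocess rejects zero-variance continuous columns", {
  co <- manual_cohort(data.frame(x = rep(2, 10)), A = rep(c(0, 1), 5))
  co$scaled <- FALSE
  expect_error(preprocess(co), "zero-variance")
})

test_that("cohorts round-trip through CSV and schema YAML", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "cohort.csv")
  df <- data.frame(age = c(61, 45, 70, 52), sofa = c(4, 9, 2, 7),
                   rhc = c(1, 0, 1, 0), death = c(0, 1, 1, 0))
  write.csv(df, csv, row.names = FALSE)
  co <- load_cohort(csv, exposure_col = "rhc", outcome_col = "death")
  expect_equal(dim(co), c(4L, 2L))
  expect_equal(co$A, c(1L, 0L, 1L, 0L))
  expect_equal(co$Y, c(0L, 1L, 1L, 0L))
  expect_equal(co$schema$kind, c("continuous", "continuous"))

  yml <- file.path(dir, "schema.yaml")
  sc <- default_schema(9L, 1L, 1L)
  write_schema_yaml(sc, yml)
  back <- read_schema_yaml(yml)
  expect_equal(back$name, sc$name)
  expect_equal(back$kind, sc$kind)
  expect_equal(back$levels[[11]], sc$levels[[11]])
})

test_that("load_cohort reports unusable exposure columns and missing rows", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "bad.csv")
  write.csv(data.frame(x = 1:4, rhc = c("yes", "no", "maybe", "yes")),
            csv, row.names = FALSE)
  expect_error(load_cohort(csv, exposure_col = "rhc"), "rhc")
  expect_error(load_cohort(csv, exposure_col = "swang1"), "swang1")

  csv2 <- file.path(dir, "na.csv")
  write.csv(data.frame(x = c(1, NA, 3, 4), rhc = c(1, 0, 1, 0)),
            csv2, row.names = FALSE)
  expect_message(co <- load_cohort(csv2, exposure_col = "rhc"), "1 rows")
  expect_equal(nrow(co$X), 3L)
})
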