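# The six propensity-score estimators.

rank_auc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

test_that("logistic PS matches a formula-interface glm oracle", {
  lc <- linear_ps_cohort(500, p = 3, seed = 2)
  res <- ps_logistic(lc$cohort)
  oracle <- glm(A ~ x1 + x2 + x3,
                data = cbind(lc$cohort$X, A = lc$cohort$A),
                family = binomial())
  expect_equal(res$ps, unname(fitted(oracle)), tolerance = 1e-6)
  expect_true(res$diagnostics$converged)
})

test_that("logistic PS on independent exposure concentrates at the base rate", {
  set.seed(3)
  X <- matrix(rnorm(2000), 500, 4)
  A <- rbinom(500, 1, 0.4)
  res <- ps_logistic(manual_cohort(X, A))
  expect_lt(abs(mean(res$ps) - mean(A)), 1e-6)  # logistic mean preservation
  expect_lt(sd(res$ps), 0.06)
})

test_that("logistic PS is monotone in a single separating covariate and rejects degenerate exposure", {
  co <- manual_cohort(data.frame(x = c(-1, -0.5, 0.5, 1)), c(0, 0, 1, 1))
  res <- ps_logistic(co)
  expect_true(all(diff(res$ps[order(co$X$x)]) >= 0))
  expect_error(ps_logistic(manual_cohort(data.frame(x = rnorm(10)),
                                         rep(1, 10))),
               "constant")
})

test_that("MARS recovers a hinge mean function at least as well as an exhaustive single-pair search", {
  set.seed(4)
  n <- 100
  x <- sort(runif(n, -1, 1))
  y <- 2 * pmax(x - 0.3, 0) - pmax(-0.2 - x, 0) + rnorm(n, sd = 0.1)
  fit <- mars_fit(matrix(x, ncol = 1), y, max_degree = 1)
  # oracle: all single reflected-pair models over a dense knot grid
  best_mse <- Inf
  for (t in seq(-0.95, 0.95, by = 0.01)) {
    B <- cbind(1, pmax(x - t, 0), pmax(t - x, 0))
    f <- lm.fit(B, y)
    best_mse <- min(best_mse, mean(f$residuals^2))
  }
  expect_lte(mean((fit$fitted - y)^2), best_mse + 1e-8)
  # pruning never leaves a worse GCV than the full forward model
  B_full <- plasmatch:::mars_basis(fit, matrix(x, ncol = 1))
  rss_full <- sum(lm.fit(B_full, y)$residuals^2)
  gcv_full <- plasmatch:::mars_gcv(rss_full, n, ncol(B_full), 2)
  expect_lte(fit$gcv, gcv_full + 1e-12)
})

test_that("MARS propensity scores approximate a step assignment and report truncation", {
  set.seed(5)
  n <- 800
  x <- rnorm(n)
  A <- as.integer(x > 0.2)
  A[sample(n, 40)] <- 1L - A[sample(n, 40)]  # mild label noise
  res <- ps_mars(manual_cohort(data.frame(x = x), A))
  expect_true(all(res$ps > 0 & res$ps < 1))
  expect_gt(cor(res$ps, as.numeric(x > 0.2)), 0.8)
  # least-squares fit of a step leaves some raw predictions outside (0,1)
  expect_true(res$diagnostics$truncation_count >= 0)
  expect_identical(res$ps[res$ps >= 1 - 1e-6],
                   rep(1 - 1e-6, sum(res$ps >= 1 - 1e-6)))
})

test_that("MARS with constant exposure signal returns an intercept-only fit", {
  set.seed(6)
  co <- manual_cohort(data.frame(x = rnorm(200), z = rnorm(200)),
                      rep(c(0, 1), 100))
  res <- ps_mars(co)
  expect_lt(diff(range(res$ps)), 0.35)
  expect_lt(abs(mean(res$ps) - 0.5), 0.1)
})

test_that("supervised deep PS separates a strong single-covariate signal", {
  set.seed(7)
  n <- 2000
  x <- rnorm(n)
  A <- rbinom(n, 1, plogis(4 * x))
  co <- manual_cohort(data.frame(x = x, z1 = rnorm(n), z2 = rnorm(n)), A)
  cfg <- net_config(epochs = 20L, batch_size = 128L, seed = 11L)
  res <- ps_deep_supervised(co, cfg)
  expect_gt(rank_auc(res$ps, A), 0.8)
  res_n <- ps_deep_supervised(co, cfg, naive = TRUE)
  expect_gt(rank_auc(res_n$ps, A), 0.8)
  expect_identical(res$method, "DL")
  expect_identical(res_n$method, "DL.n")
})

test_that("deep PS with no signal concentrates near the exposure rate and is seed-reproducible", {
  set.seed(8)
  X <- matrix(rnorm(800 * 5), 800, 5)
  A <- rbinom(800, 1, 0.35)
  co <- manual_cohort(X, A)
  cfg <- net_config(epochs = 15L, batch_size = 128L, seed = 9L)
  r1 <- ps_deep_supervised(co, cfg)
  r2 <- ps_deep_supervised(co, cfg)
  expect_identical(r1$ps, r2$ps)
  expect_lt(abs(mean(r1$ps) - mean(A)), 0.1)
  expect_lt(sd(r1$ps), 0.15)
})

test_that("a full-capacity linear autoencoder reconstructs its input", {
  set.seed(9)
  X <- matrix(rnorm(300 * 4), 300, 4)
  co <- manual_cohort(X, rbinom(300, 1, 0.5))
  cfg <- net_config(ae_hidden = integer(0), bottleneck_size = 4L,
                    ae_epochs = 200L, batch_size = 64L,
                    learning_rate = 1e-2, seed = 2L)
  res <- ps_autoencoder(co, cfg)
  expect_lt(res$diagnostics$reconstruction_mse, 0.1)
})

test_that("a 2-unit linear autoencoder approaches the PCA-2 reconstruction error", {
  set.seed(10)
  n <- 400
  scores <- matrix(rnorm(n * 2), n, 2)
  load <- matrix(rnorm(2 * 6), 2, 6)
  X <- scores %*% load + matrix(rnorm(n * 6, sd = 0.1), n, 6)
  X <- scale(X)
  co <- manual_cohort(X, rbinom(n, 1, 0.5))
  pc <- prcomp(X, center = FALSE)
  pca_resid <- mean((X - pc$x[, 1:2] %*% t(pc$rotation[, 1:2]))^2)
  cfg <- net_config(ae_hidden = integer(0), bottleneck_size = 2L,
                    ae_epochs = 300L, batch_size = 128L,
                    learning_rate = 1e-2, seed = 3L)
  res <- ps_autoencoder(co, cfg)
  expect_lt(res$diagnostics$reconstruction_mse, pca_resid * 2 + 0.02)
  expect_gte(res$diagnostics$reconstruction_mse, pca_resid - 0.02)
})

test_that("autoencoder PS with independent exposure concentrates at the base rate", {
  set.seed(11)
  X <- matrix(rnorm(600 * 5), 600, 5)
  A <- rbinom(600, 1, 0.4)
  co <- manual_cohort(X, A)
  cfg <- net_config(ae_epochs = 20L, batch_size = 128L, seed = 4L)
  res <- ps_autoencoder(co, cfg)
  expect_lt(abs(mean(res$ps) - mean(A)), 0.1)
})

test_that("all six estimators give valid, truth-correlated scores on a linear cohort", {
  lc <- linear_ps_cohort(3500, p = 5, seed = 12)
  cfg <- net_config(epochs = 20L, ae_epochs = 30L, batch_size = 256L,
                    seed = 21L)
  runs <- list(
    PS = ps_logistic(lc$cohort),
    MARS = ps_mars(lc$cohort),
    DL = ps_deep_supervised(lc$cohort, cfg),
    DL.n = ps_deep_supervised(lc$cohort, cfg, naive = TRUE),
    AE = ps_autoencoder(lc$cohort, cfg),
    AE.o = ps_autoencoder(lc$cohort, cfg, optimized = TRUE)
  )
  for (m in names(runs)) {
    ps <- runs[[m]]$ps
    expect_length(ps, 3500)
    expect_true(all(ps > 0 & ps < 1), info = m)
    expect_gt(cor(ps, lc$ps_true, method = "spearman"), 0.5)
  }
})
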