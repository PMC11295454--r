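# Targeted maximum likelihood estimation of the marginal odds ratio, with a
# two-learner super learner (main-effects logistic regression and MARS) for
# the initial outcome model and externally supplied propensity scores.

# Candidate learners. Each returns a fit object and a predict(newX, newA)
# closure giving outcome probabilities.
sl_learner_logistic <- function(X, A, Y) {
  fit <- fit_logistic(cbind(A = A, X), Y)
  list(predict = function(Xn, An) {
    eta <- fit$coef[1] + drop(cbind(A = An, Xn) %*% fit$coef[-1])
    expit(eta)
  }, converged = fit$converged)
}

sl_learner_mars <- function(X, A, Y) {
  fit <- mars_fit(cbind(A = A, X), Y, max_degree = 2L)
  list(predict = function(Xn, An) {
    p <- predict(fit, cbind(A = An, Xn))
    pmin(pmax(p, 1e-6), 1 - 1e-6)
  }, converged = all(is.finite(fit$coef)))
}

default_sl_learners <- function() {
  list(logistic = sl_learner_logistic, mars = sl_learner_mars)
}

#' Fit a two-learner super learner for the outcome model
#'
#' Cross-validated (5-fold) predictions are computed for each candidate
#' learner; the ensemble weights minimize the cross-validated squared-error
#' risk of the convex combination, via nonnegative least squares normalized
#' onto the simplex. Learners are then refit on the full data. A learner
#' that fails on any fold gets weight 0.
#'
#' @param cohort a preprocessed [new_cohort()] with outcome `Y` (n >= 50).
#' @param learners named list of learner factories; defaults to logistic
#'   regression and MARS.
#' @param cv_folds number of cross-validation folds.
#' @param seed seed controlling the fold split.
#' @return a `super_learner` with simplex `weights`, per-learner `cv_risk`
#'   and a `predict(X, A)` closure.
#' @export
fit_super_learner <- function(cohort, learners = default_sl_learners(),
                              cv_folds = 5L, seed = 1L) {
  if (is.null(cohort$Y)) stop("cohort has no outcome")
  n <- length(cohort$Y)
  if (n < 50L) stop("super learner needs n >= 50")
  X <- cohort_matrix(cohort); A <- cohort$A; Y <- cohort$Y
  K <- length(learners)
  folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
  cv_pred <- matrix(NA_real_, n, K, dimnames = list(NULL, names(learners)))
  failed <- stats::setNames(rep(FALSE, K), names(learners))
  for (k in seq_len(K)) {
    for (f in seq_len(cv_folds)) {
      test <- folds == f
      fit <- tryCatch(learners[[k]](X[!test, , drop = FALSE], A[!test],
                                    Y[!test]),
                      error = function(e) NULL)
      if (is.null(fit) || !isTRUE(fit$converged)) { failed[k] <- TRUE; break }
      cv_pred[test, k] <- fit$predict(X[test, , drop = FALSE], A[test])
    }
  }
  if (all(failed)) stop("all super-learner candidates failed")
  cv_risk <- colMeans((cv_pred - Y)^2)
  cv_risk[failed] <- NA_real_
  ok <- which(!failed)
  w <- rep(0, K); names(w) <- names(learners)
  nn <- pracma::lsqnonneg(cv_pred[, ok, drop = FALSE], as.numeric(Y))$x
  if (sum(nn) <= 0) nn <- rep(1, length(ok))  # degenerate: fall back to equal
  w[ok] <- nn / sum(nn)
  full <- vector("list", K)
  for (k in ok) full[[k]] <- learners[[k]](X, A, Y)
  pred_fun <- function(Xn, An) {
    out <- 0
    for (k in ok) if (w[k] > 0) out <- out + w[k] * full[[k]]$predict(Xn, An)
    out
  }
  structure(list(weights = w, cv_risk = cv_risk, cv_folds = cv_folds,
                 failed = failed, predict = pred_fun),
            class = "super_learner")
}

#' @export
print.super_learner <- function(x, ...) {
  cat("<super_learner> weights:",
      paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' TMLE of the marginal odds ratio using supplied propensity scores
#'
#' Initial outcome predictions come from the super learner; the clever
#' covariates are `H1 = A/ps` and `H0 = -(1-A)/(1-ps)`; a two-coefficient
#' logistic fluctuation of `Y` on `(H1, H0)` with offset
#' `logit(Q(A, W))` and no intercept targets the treated and control mean
#' outcomes jointly. `psi1`/`psi0` are the means of the targeted
#' predictions, the effect is `logit(psi1) - logit(psi0)`, and the standard
#' error comes from the efficient influence curve with a delta-method step
#' onto the log-OR scale.
#'
#' @param cohort a preprocessed [new_cohort()] with outcome.
#' @param ps propensity scores in (0, 1); values outside
#'   `[ps_bound, 1 - ps_bound]` are bounded and counted.
#' @param sl optional pre-fitted [fit_super_learner()]; fitted if `NULL`.
#' @param method label for the PS method feeding the TMLE.
#' @param ps_bound positivity bound applied inside TMLE only.
#' @param q_bound bound on initial outcome predictions.
#' @param seed passed to the super learner fit.
#' @return a `tmle_estimate` with `psi1`, `psi0`, `log_or`, `se`, 95% CI,
#'   fluctuation coefficients `epsilon` and a bounded-PS count. The object
#'   also carries `converged = TRUE` so it can feed
#'   [summarize_estimates()].
#' @export
tmle_estimate <- function(cohort, ps, sl = NULL, method = "PS",
                          ps_bound = 0.001, q_bound = 1e-6, seed = 1L) {
  if (is.null(cohort$Y)) stop("cohort has no outcome")
  stopifnot(length(ps) == length(cohort$A))
  if (any(ps <= 0 | ps >= 1)) stop("propensity scores must lie in (0, 1)")
  n <- length(ps)
  g <- pmin(pmax(ps, ps_bound), 1 - ps_bound)
  n_bounded <- sum(g != ps)
  if (is.null(sl)) sl <- fit_super_learner(cohort, seed = seed)
  X <- cohort_matrix(cohort); A <- cohort$A; Y <- cohort$Y

  bound_q <- function(q) pmin(pmax(q, q_bound), 1 - q_bound)
  QA <- bound_q(sl$predict(X, A))
  Q1 <- bound_q(sl$predict(X, rep(1, n)))
  Q0 <- bound_q(sl$predict(X, rep(0, n)))

  H1 <- A / g
  H0 <- -(1 - A) / (1 - g)
  fl <- suppressWarnings(
    stats::glm.fit(cbind(H1 = H1, H0 = H0), Y,
                   family = stats::binomial(), offset = logit(QA),
                   intercept = FALSE, control = list(maxit = 200)))
  eps <- fl$coefficients
  eps[is.na(eps)] <- 0

  Q1s <- expit(logit(Q1) + eps[1] / g)
  Q0s <- expit(logit(Q0) - eps[2] / (1 - g))
  QAs <- ifelse(A == 1, Q1s, Q0s)
  psi1 <- mean(Q1s); psi0 <- mean(Q0s)
  log_or <- logit(psi1) - logit(psi0)

  ic1 <- H1 * (Y - QAs) + Q1s - psi1
  ic0 <- -H0 * (Y - QAs) + Q0s - psi0
  d1 <- 1 / (psi1 * (1 - psi1)); d0 <- 1 / (psi0 * (1 - psi0))
  ic <- d1 * ic1 - d0 * ic0
  se <- stats::sd(ic) / sqrt(n)
  ci <- log_or + c(-1, 1) * stats::qnorm(0.975) * se

  structure(list(method = paste0("TMLE:", method),
                 psi1 = psi1, psi0 = psi0,
                 log_or = log_or, se = se, ci_low = ci[1], ci_high = ci[2],
                 or_scale = c(or = exp(log_or), ci_low = exp(ci[1]),
                              ci_high = exp(ci[2])),
                 epsilon = eps, n_ps_bounded = n_bounded,
                 score = c(h1 = mean(H1 * (Y - QAs)),
                           h0 = mean(H0 * (Y - QAs))),
                 sl_weights = sl$weights, converged = TRUE),
            class = "tmle_estimate")
}

#' @export
print.tmle_estimate <- function(x, ...) {
  cat(sprintf("<tmle_estimate> %s: OR %.3f (95%% CI %.3f-%.3f)\n",
              x$method, exp(x$log_or), exp(x$ci_low), exp(x$ci_high)))
  invisible(x)
}
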