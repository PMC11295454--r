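# Multivariate adaptive regression splines, fitted by least squares:
# greedy forward addition of reflected hinge pairs (compiled search), then
# backward deletion choosing the subset with the best generalized
# cross-validation (GCV) score. No cross-validation is used.

mars_gcv <- function(rss, n, m_active, penalty) {
  enp <- m_active + penalty * (m_active - 1) / 2
  if (enp >= n) return(Inf)
  (rss / n) / (1 - enp / n)^2
}

#' Fit a MARS model by least squares
#'
#' Forward pass: starting from the intercept, repeatedly add the reflected
#' hinge pair `max(0, x - t)`, `max(0, t - x)` (times an existing basis
#' function, up to `max_degree` factors) that most reduces the residual sum
#' of squares, with knot candidates at marginal quantiles. Backward pass:
#' greedy deletion, keeping the subset minimizing the GCV criterion
#' `(RSS/n) / (1 - enp/n)^2` with effective parameters
#' `enp = m + penalty (m - 1) / 2`.
#'
#' @param X numeric matrix of predictors.
#' @param y numeric response (a 0/1 vector gives a linear-probability fit).
#' @param max_degree maximum number of hinge factors per basis function
#'   (2 allows second-order interactions).
#' @param max_terms maximum number of basis functions (including intercept)
#'   built in the forward pass.
#' @param n_knots knot candidates per variable (marginal quantiles).
#' @param penalty GCV cost per knot (3 when interactions are allowed, 2 for
#'   additive models, following the usual MARS convention).
#' @return a `mars_fit` with basis descriptors, selected subset and
#'   least-squares coefficients.
#' @export
mars_fit <- function(X, y, max_degree = 2L, max_terms = 15L, n_knots = 10L,
                     penalty = if (max_degree > 1L) 3 else 2) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  knots <- lapply(seq_len(ncol(X)), function(j) {
    u <- unique(stats::quantile(X[, j],
                                probs = seq(0.05, 0.95, length.out = n_knots),
                                names = FALSE, type = 7))
    u[u < max(X[, j])]  # a knot at the maximum gives a zero hinge
  })
  fwd <- mars_forward_cpp(X, as.numeric(y), knots,
                          as.integer(max_terms), as.integer(max_degree))
  B <- fwd$B
  m <- ncol(B)

  # backward pass: greedy deletion path, best-GCV subset along the path
  active <- seq_len(m)
  fit_rss <- function(idx) {
    f <- stats::lm.fit(B[, idx, drop = FALSE], y)
    sum(f$residuals^2)
  }
  best_active <- active
  best_gcv <- mars_gcv(fit_rss(active), n, length(active), penalty)
  cur <- active
  while (length(cur) > 1L) {
    cand <- cur[cur != 1L]  # never drop the intercept
    rss_d <- vapply(cand, function(d) fit_rss(setdiff(cur, d)), 0)
    drop_term <- cand[which.min(rss_d)]
    cur <- setdiff(cur, drop_term)
    g <- mars_gcv(min(rss_d), n, length(cur), penalty)
    if (g < best_gcv) { best_gcv <- g; best_active <- cur }
  }

  ls <- stats::lm.fit(B[, best_active, drop = FALSE], y)
  ls$coefficients[is.na(ls$coefficients)] <- 0
  structure(list(parent = fwd$parent, var = fwd$var, sign = fwd$sign,
                 knot = fwd$knot, degree = fwd$degree,
                 active = best_active, coef = ls$coefficients,
                 gcv = best_gcv, n_terms_forward = m,
                 fitted = drop(B[, best_active, drop = FALSE] %*%
                                 ls$coefficients)),
            class = "mars_fit")
}

# Rebuild the basis matrix for new data from the hinge descriptors.
mars_basis <- function(fit, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  m <- length(fit$parent)
  B <- matrix(0, n, m)
  B[, 1L] <- 1
  for (j in seq_len(m)[-1L]) {
    v <- fit$var[j] + 1L  # C++ indices are 0-based
    h <- if (fit$sign[j] > 0) pmax(X[, v] - fit$knot[j], 0)
         else pmax(fit$knot[j] - X[, v], 0)
    B[, j] <- B[, fit$parent[j] + 1L] * h
  }
  B
}

#' Predict from a MARS fit
#'
#' @param object a [mars_fit()].
#' @param newdata numeric matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of (untruncated) predictions.
#' @export
predict.mars_fit <- function(object, newdata, ...) {
  B <- mars_basis(object, newdata)
  drop(B[, object$active, drop = FALSE] %*% object$coef)
}

#' @export
print.mars_fit <- function(x, ...) {
  cat(sprintf("<mars_fit> %d basis functions kept of %d (GCV %.4g)\n",
              length(x$active), x$n_terms_forward, x$gcv))
  invisible(x)
}
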