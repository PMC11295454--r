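#' @useDynLib plasmatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats glm.fit binomial sd quantile rnorm runif rbinom plogis
#'   qlogis uniroot qnorm complete.cases
#' @importFrom utils read.csv
NULL

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

#' Clip probabilities away from 0 and 1
#'
#' @param p numeric vector of probabilities.
#' @param bound lower clipping bound; the upper bound is `1 - bound`.
#' @return list with `p` (clipped vector) and `n_clipped` (count of values
#'   that were moved).
#' @export
clip_prob <- function(p, bound = 1e-6) {
  out <- pmin(pmax(p, bound), 1 - bound)
  list(p = out, n_clipped = sum(out != p | !is.finite(p)))
}

# Maximum-likelihood logistic regression on a plain design matrix, without
# formula overhead. Returns coefficients, model-based SEs and a convergence
# flag.  |coef| > coef_cap on standardized inputs is treated as effective
# separation.
fit_logistic <- function(x, y, maxit = 100L, coef_cap = 15) {
  x <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = list(maxit = maxit))
  )
  cf <- fit$coefficients
  ok <- fit$converged && all(is.finite(cf)) && max(abs(cf[-1]), 0) <= coef_cap
  se <- rep(NA_real_, length(cf))
  if (all(is.finite(cf))) {
    R <- qr.R(fit$qr)
    d <- abs(diag(R))
    if (all(d > 1e-10)) {
      cov <- chol2inv(R)
      se <- sqrt(pmax(diag(cov), 0))
    } else ok <- FALSE
  }
  names(se) <- names(cf)
  list(coef = cf, se = se, fitted = fit$fitted.values, converged = ok)
}

# Monotone root-finding for an intercept b such that the (optionally
# weighted) mean of plogis(b + lp) equals the target.
solve_intercept <- function(lp, target, tol = 1e-10, weights = NULL) {
  if (any(!is.finite(lp)))
    stop("linear predictor contains non-finite values; intercept target unreachable")
  if (is.null(weights)) weights <- rep(1 / length(lp), length(lp))
  else weights <- weights / sum(weights)
  f <- function(b) sum(weights * expit(b + lp)) - target
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}
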