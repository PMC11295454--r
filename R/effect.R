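#' Doubly adjusted treatment-effect estimate on the matched cohort
#'
#' Logistic regression of the simulated (or observed) outcome on the
#' exposure plus all covariate main effects — the same untransformed inputs
#' the propensity model saw — restricted to the matched rows. The estimate is
#' the conditional log odds ratio with its model-based (information-matrix)
#' standard error and 95% Wald interval.
#'
#' @param replicate a `plasmode_replicate` (or any list with a preprocessed
#'   cohort under `$data` that has `Y`).
#' @param matched a [ps_match()] result; must contain at least one pair.
#' @param method label to attach to the estimate.
#' @return an `effect_estimate`: `log_or`, `se`, `ci_low`, `ci_high`,
#'   `or_scale` (exp-transformed triple), `n_pairs`, `converged`.
#' @export
estimate_effect <- function(replicate, matched, method = "PS") {
  cohort <- replicate$data
  if (is.null(cohort$Y)) stop("replicate has no outcome")
  if (nrow(matched$pairs) < 1L) stop("matched cohort is empty")
  rows <- as.vector(matched$pairs)
  X <- cohort_matrix(cohort)[rows, , drop = FALSE]
  A <- cohort$A[rows]; Y <- cohort$Y[rows]
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  fit <- fit_logistic(cbind(A = A, X[, keep, drop = FALSE]), Y)
  log_or <- unname(fit$coef["A"])
  se <- unname(fit$se["A"])
  converged <- fit$converged && is.finite(log_or) && is.finite(se) && se > 0
  ci <- log_or + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(method = method, log_or = log_or, se = se,
                 ci_low = ci[1], ci_high = ci[2],
                 or_scale = c(or = exp(log_or), ci_low = exp(ci[1]),
                              ci_high = exp(ci[2])),
                 n_pairs = nrow(matched$pairs), converged = converged),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: OR %.3f (95%% CI %.3f-%.3f), %d pairs%s\n",
              x$method, exp(x$log_or), exp(x$ci_low), exp(x$ci_high),
              x$n_pairs, if (x$converged) "" else " [not converged]"))
  invisible(x)
}
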