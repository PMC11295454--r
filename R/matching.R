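#' Caliper width for propensity-score matching
#'
#' Returns 0.2 times the standard deviation (n-1 denominator) of the
#' logit-transformed propensity scores, computed on the full pre-matching
#' sample.
#'
#' @param ps propensity scores strictly inside (0, 1).
#' @param multiplier caliper multiplier (0.2 by convention).
#' @return nonnegative caliper on the logit scale; constant `ps` gives a
#'   zero caliper with a warning.
#' @export
compute_caliper <- function(ps, multiplier = 0.2) {
  if (any(ps <= 0 | ps >= 1)) stop("propensity scores must lie in (0, 1)")
  s <- stats::sd(logit(ps))
  if (s == 0) {
    warning("constant propensity scores: caliper is 0")
    return(0)
  }
  multiplier * s
}

#' Greedy 1:1 nearest-neighbour caliper matching without replacement
#'
#' Treated units are processed in data order; each takes the not-yet-used
#' control minimizing the absolute logit-scale propensity difference,
#' provided that difference is within the caliper, otherwise the treated
#' unit stays unmatched. Ties go to the lower control index.
#'
#' @param ps propensity scores in (0, 1).
#' @param A 0/1 exposure vector of the same length.
#' @param caliper_logit maximum |logit difference| allowed in a pair.
#' @return a `matched_cohort`: `pairs` (two-column matrix of treated and
#'   control row indices), the caliper, and the unmatched-treated count.
#' @export
ps_match <- function(ps, A, caliper_logit) {
  stopifnot(length(ps) == length(A))
  if (any(ps <= 0 | ps >= 1)) stop("propensity scores must lie in (0, 1)")
  treated <- which(A == 1)
  controls <- which(A == 0)
  if (!length(treated) || !length(controls))
    stop("need at least one treated and one control unit")
  lps <- logit(ps)
  ctrl_lps <- lps[controls]
  available <- rep(TRUE, length(controls))
  t_idx <- integer(0); c_idx <- integer(0)
  for (t in treated) {
    open <- which(available)
    if (!length(open)) break
    d <- abs(ctrl_lps[open] - lps[t])
    k <- open[which.min(d)]  # which.min takes the first (lowest-index) tie
    if (d[match(k, open)] <= caliper_logit) {
      available[k] <- FALSE
      t_idx <- c(t_idx, t)
      c_idx <- c(c_idx, controls[k])
    }
  }
  structure(list(pairs = cbind(treated = t_idx, control = c_idx),
                 caliper_logit = caliper_logit,
                 n_unmatched_treated = length(treated) - length(t_idx)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d pairs, %d treated unmatched, caliper %.4f (logit)\n",
              nrow(x$pairs), x$n_unmatched_treated, x$caliper_logit))
  invisible(x)
}

#' Standardized mean difference
#'
#' `(mean treated - mean control) / pooled SD`, with pooled SD
#' `sqrt((s_t^2 + s_c^2) / 2)` always computed on the pre-matching sample so
#' that before/after values share a denominator. Indicator columns are
#' treated as numeric.
#'
#' @param values numeric covariate vector (full sample).
#' @param A 0/1 exposure vector (full sample).
#' @param subset optional row indices (e.g. matched rows) over which the
#'   group means are taken; the pooled SD still comes from the full sample.
#' @return the SMD, or `NA` when either group in `subset` has fewer than 2
#'   observations.
#' @export
smd <- function(values, A, subset = NULL) {
  values <- as.numeric(values)
  s_t <- stats::sd(values[A == 1]); s_c <- stats::sd(values[A == 0])
  pooled <- sqrt((s_t^2 + s_c^2) / 2)
  if (!is.null(subset)) { values <- values[subset]; A <- A[subset] }
  if (sum(A == 1) < 2L || sum(A == 0) < 2L) return(NA_real_)
  if (pooled == 0) return(0)
  (mean(values[A == 1]) - mean(values[A == 0])) / pooled
}

#' Covariate balance table before and after matching
#'
#' @param cohort a preprocessed [new_cohort()].
#' @param matched a [ps_match()] result.
#' @param flag_threshold |SMD| above which a covariate is flagged as
#'   imbalanced (0.25 by convention).
#' @return data frame with covariate, `smd_before`, `smd_after` and an
#'   imbalance flag for the matched cohort — the numeric basis of a love
#'   plot.
#' @export
smd_table <- function(cohort, matched, flag_threshold = 0.25) {
  rows <- as.vector(matched$pairs)
  out <- data.frame(covariate = names(cohort$X),
                    smd_before = NA_real_, smd_after = NA_real_)
  for (i in seq_along(cohort$X)) {
    v <- cohort$X[[i]]
    out$smd_before[i] <- smd(v, cohort$A)
    out$smd_after[i] <- smd(v, cohort$A, subset = rows)
  }
  out$imbalanced <- !is.na(out$smd_after) & abs(out$smd_after) > flag_threshold
  out
}
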