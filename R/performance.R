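# Simulation performance measures with Monte Carlo standard errors,
# following the standard simulation-study reporting framework: bias,
# empirical SE, MSE, average model SE, coverage and bias-eliminated
# coverage, plus zip-plot data.

#' Summarize replicate estimates into performance measures
#'
#' Non-converged replicates are excluded (listwise, per method) and counted.
#' Measures on the converged set of size `n`:
#' bias `mean(est) - truth` (MCSE `empSE/sqrt(n)`);
#' empirical SE `sd(est)` (MCSE `empSE/sqrt(2(n-1))`);
#' MSE `mean((est - truth)^2)` (MCSE `sd((est-truth)^2)/sqrt(n)`);
#' model SE `mean(se_i)` — the arithmetic mean of reported SEs — or the
#' root-mean-square of the variances when `mod_se_rms = TRUE`
#' (MCSE `sd(se_i)/sqrt(n)`);
#' coverage / bias-eliminated coverage as the fraction of 95% intervals
#' containing the truth / the mean estimate (MCSE `sqrt(p(1-p)/n)`).
#'
#' @param estimates list of [estimate_effect()] (or TMLE) results.
#' @param truth true log odds ratio.
#' @param method optional method label (defaults to the first estimate's).
#' @param scenario optional scenario label.
#' @param mod_se_rms average model SE as root-mean-square of variances
#'   instead of the arithmetic mean of SEs.
#' @return one-row data frame of class `performance_table`.
#' @export
summarize_estimates <- function(estimates, truth, method = NULL,
                                scenario = NA_character_,
                                mod_se_rms = FALSE) {
  conv <- vapply(estimates, function(e) isTRUE(e$converged), TRUE)
  used <- estimates[conv]
  n <- length(used)
  if (n < 2L) stop("need at least 2 converged estimates to summarize")
  est <- vapply(used, `[[`, 0, "log_or")
  se <- vapply(used, `[[`, 0, "se")
  lo <- vapply(used, `[[`, 0, "ci_low")
  hi <- vapply(used, `[[`, 0, "ci_high")
  if (is.null(method)) method <- used[[1L]]$method

  bias <- mean(est) - truth
  emp_se <- stats::sd(est)
  mse <- mean((est - truth)^2)
  mod_se <- if (mod_se_rms) sqrt(mean(se^2)) else mean(se)
  cover <- mean(lo <= truth & truth <= hi)
  be_cover <- mean(lo <= mean(est) & mean(est) <= hi)

  out <- data.frame(
    scenario = scenario, method = method,
    bias = bias, bias_mcse = emp_se / sqrt(n),
    emp_se = emp_se, emp_se_mcse = emp_se / sqrt(2 * (n - 1)),
    mse = mse, mse_mcse = stats::sd((est - truth)^2) / sqrt(n),
    mod_se = mod_se, mod_se_mcse = stats::sd(se) / sqrt(n),
    coverage = cover, coverage_mcse = sqrt(cover * (1 - cover) / n),
    be_coverage = be_cover,
    be_coverage_mcse = sqrt(be_cover * (1 - be_cover) / n),
    n_used = n, n_excluded = length(estimates) - n,
    stringsAsFactors = FALSE)
  class(out) <- c("performance_table", "data.frame")
  out
}

#' Zip-plot data: replicate intervals ranked by |z|
#'
#' Replicates are sorted by `|(estimate - truth)/se|` ascending and given
#' fractional centiles `(i - 0.5)/n`; each row records the interval and
#' whether it covers the truth. Plotting centile against the intervals shows
#' which replicates fail to cover.
#'
#' @param estimates list of estimate objects (converged ones are used).
#' @param truth true log odds ratio.
#' @return data frame with `centile`, `z_abs`, `ci_low`, `ci_high`,
#'   `covers`.
#' @export
zip_data <- function(estimates, truth) {
  conv <- vapply(estimates, function(e) isTRUE(e$converged), TRUE)
  used <- estimates[conv]
  if (length(used) < 2L) stop("need at least 2 converged estimates")
  est <- vapply(used, `[[`, 0, "log_or")
  se <- vapply(used, `[[`, 0, "se")
  if (any(se == 0)) stop("zero standard error in a replicate")
  lo <- vapply(used, `[[`, 0, "ci_low")
  hi <- vapply(used, `[[`, 0, "ci_high")
  z <- abs((est - truth) / se)
  ord <- order(z)
  n <- length(z)
  data.frame(centile = (seq_len(n) - 0.5) / n,
             z_abs = z[ord], ci_low = lo[ord], ci_high = hi[ord],
             covers = (lo <= truth & truth <= hi)[ord])
}

#' Compare methods' performance against the logistic-regression baseline
#'
#' Reproduces the layout of the simulation's headline table: one row per
#' measure, one column per method, each non-baseline value annotated with an
#' up/down arrow for its direction relative to the `PS` (logistic) column.
#'
#' @param tables a `performance_table` (rows from [summarize_estimates()],
#'   one per method, same scenario/truth) or a list of such rows.
#' @param baseline method label of the reference column.
#' @param digits digits to print.
#' @return character matrix (measures x methods) of formatted
#'   `estimate (MCSE)` strings with direction arrows.
#' @export
compare_table <- function(tables, baseline = "PS", digits = 4) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  if (!baseline %in% tables$method)
    stop("baseline method '", baseline, "' not present")
  measures <- c(bias = "Bias", emp_se = "Empirical SE", mse = "MSE",
                mod_se = "Model-based SE", coverage = "Coverage",
                be_coverage = "Bias-eliminated Coverage")
  base_row <- tables[tables$method == baseline, ]
  out <- matrix("", length(measures), nrow(tables),
                dimnames = list(measures, tables$method))
  for (m in names(measures)) {
    for (j in seq_len(nrow(tables))) {
      v <- tables[[m]][j]
      mc <- tables[[paste0(m, "_mcse")]][j]
      cell <- sprintf("%.*f (%.*f)", digits, v, digits, mc)
      if (tables$method[j] != baseline) {
        ref <- base_row[[m]]
        if (v > ref) cell <- paste0(cell, " ↑")
        else if (v < ref) cell <- paste0(cell, " ↓")
      }
      out[measures[m], tables$method[j]] <- cell
    }
  }
  out
}
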