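# Scenario runner: resample -> simulate outcomes -> per method: estimate
# PS -> caliper -> match -> balance -> doubly adjusted effect (-> optional
# TMLE) -> summarize. Any replicate-level failure is caught and recorded as
# an exclusion; it never aborts the scenario.

#' Built-in propensity-score method registry
#'
#' Maps the method labels `PS`, `MARS`, `DL`, `DL.n`, `AE`, `AE.o` to
#' functions `(cohort, seed, config) -> ps_result`. User-supplied functions
#' with the same signature can be mixed in through the `methods` argument of
#' [run_scenario()].
#'
#' @return named list of estimator functions.
#' @export
ps_methods <- function() {
  list(
    PS = function(cohort, seed, config) ps_logistic(cohort),
    MARS = function(cohort, seed, config) ps_mars(cohort),
    DL = function(cohort, seed, config)
      ps_deep_supervised(cohort, config_with_seed(config, seed), naive = FALSE),
    DL.n = function(cohort, seed, config)
      ps_deep_supervised(cohort, config_with_seed(config, seed), naive = TRUE),
    AE = function(cohort, seed, config)
      ps_autoencoder(cohort, config_with_seed(config, seed), optimized = FALSE),
    AE.o = function(cohort, seed, config)
      ps_autoencoder(cohort, config_with_seed(config, seed), optimized = TRUE)
  )
}

config_with_seed <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

resolve_methods <- function(methods) {
  registry <- ps_methods()
  if (is.character(methods)) {
    unknown <- setdiff(methods, names(registry))
    if (length(unknown))
      stop("unknown methods: ", paste(unknown, collapse = ", "))
    registry[methods]
  } else {
    stopifnot(is.list(methods), !is.null(names(methods)))
    methods
  }
}

# One replicate of the matching pipeline for one method; returns an
# effect_estimate or signals an error (caught by the caller).
run_method_once <- function(replicate, method_label, method_fun, seed,
                            config) {
  psr <- method_fun(replicate$data, seed, config)
  if (!isTRUE(psr$diagnostics$converged))
    stop("propensity model did not converge")
  cal <- compute_caliper(psr$ps)
  matched <- ps_match(psr$ps, replicate$data$A, cal)
  if (nrow(matched$pairs) < 2L) stop("empty or singleton match set")
  est <- estimate_effect(replicate, matched, method = method_label)
  if (!est$converged) stop("outcome model did not converge")
  est
}

#' Run one plasmode simulation scenario
#'
#' @param base a preprocessed [new_cohort()] with a base outcome (e.g. from
#'   `preprocess(generate_cohort(...))`).
#' @param scenario a [scenario_config()].
#' @param methods character vector of registry labels (see [ps_methods()])
#'   or a named list of estimator functions.
#' @param dgm optional calibrated `dgm_spec`; built by [build_dgm()] when
#'   `NULL`.
#' @param nn_config [net_config()] shared by the deep-learning methods.
#' @param run_tmle also compute a TMLE estimate per method and replicate
#'   (slow; intended for cross-checks and real-data analyses).
#' @param global_seed integer seed from which all replicate seeds derive.
#' @param verbose print progress every 50 replicates.
#' @return list with `performance` (one [summarize_estimates()] row per
#'   method), `estimates` (per-replicate data frame), `exclusions` (named
#'   counts) and the `dgm` used.
#' @export
run_scenario <- function(base, scenario, methods = c("PS"), dgm = NULL,
                         nn_config = net_config(), run_tmle = FALSE,
                         global_seed = 1L, verbose = FALSE) {
  method_funs <- resolve_methods(methods)
  if (!length(method_funs)) stop("methods must be nonempty")
  seeds <- with_seed(global_seed,
                     matrix(sample.int(.Machine$integer.max - 1L,
                                       scenario$n_sims * 3L),
                            nrow = scenario$n_sims))
  if (is.null(dgm)) dgm <- build_dgm(base, scenario)
  truth <- log(scenario$true_or)

  estimates <- stats::setNames(
    replicate(length(method_funs), list(), simplify = FALSE),
    names(method_funs))
  rows <- list()
  for (i in seq_len(scenario$n_sims)) {
    dat <- resample_base(base, scenario$sample_size,
                         scenario$exposure_prevalence, seeds[i, 1L])
    rep_i <- simulate_outcomes(dgm, dat, seeds[i, 2L],
                               scenario_id = scenario$id,
                               replicate_index = i)
    for (m in names(method_funs)) {
      est <- tryCatch(
        run_method_once(rep_i, m, method_funs[[m]], seeds[i, 3L], nn_config),
        error = function(e) structure(
          list(method = m, log_or = NA_real_, se = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, n_pairs = 0L,
               converged = FALSE, reason = conditionMessage(e)),
          class = "effect_estimate"))
      estimates[[m]][[i]] <- est
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scenario$id, method = m, replicate = i,
        log_or = est$log_or, se = est$se, ci_low = est$ci_low,
        ci_high = est$ci_high, n_pairs = est$n_pairs,
        converged = est$converged, stringsAsFactors = FALSE)
      if (isTRUE(run_tmle) && est$converged) {
        tm <- tryCatch({
          psr <- method_funs[[m]](rep_i$data, seeds[i, 3L], nn_config)
          tmle_estimate(rep_i$data, psr$ps, method = m, seed = seeds[i, 2L])
        }, error = function(e) NULL)
        if (!is.null(tm))
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = scenario$id, method = tm$method, replicate = i,
            log_or = tm$log_or, se = tm$se, ci_low = tm$ci_low,
            ci_high = tm$ci_high, n_pairs = NA_integer_,
            converged = TRUE, stringsAsFactors = FALSE)
      }
    }
    if (verbose && i %% 50L == 0L)
      message("replicate ", i, "/", scenario$n_sims)
  }

  perf <- do.call(rbind, lapply(names(method_funs), function(m)
    summarize_estimates(estimates[[m]], truth, method = m,
                        scenario = scenario$id)))
  class(perf) <- c("performance_table", "data.frame")
  exclusions <- vapply(estimates, function(e)
    sum(!vapply(e, function(x) isTRUE(x$converged), TRUE)), 0L)
  list(performance = perf, estimates = do.call(rbind, rows),
       exclusions = exclusions, dgm = dgm)
}

#' Single-dataset analysis with all requested estimators
#'
#' Runs each propensity-score method through caliper matching and the
#' doubly adjusted outcome model on one observed (or synthetic stand-in)
#' cohort, optionally adding a TMLE estimate per method, and reports odds
#' ratios with 95% confidence intervals plus the SMD balance table.
#'
#' @param cohort a preprocessed [new_cohort()] with outcome.
#' @param methods registry labels or named list, as in [run_scenario()].
#' @param nn_config [net_config()] for the deep-learning methods.
#' @param run_tmle add `TMLE:<method>` rows.
#' @param seed integer seed.
#' @return list with `estimates` (data frame: estimator, OR, CI, pairs) and
#'   `balance` (named list of [smd_table()]s per method).
#' @export
run_real_data <- function(cohort, methods = c("PS", "MARS", "DL", "AE"),
                          nn_config = net_config(), run_tmle = FALSE,
                          seed = 1L) {
  if (is.null(cohort$Y)) stop("cohort has no outcome")
  method_funs <- resolve_methods(methods)
  replicate_like <- list(data = cohort)
  rows <- list(); balance <- list()
  sl <- NULL
  for (m in names(method_funs)) {
    psr <- method_funs[[m]](cohort, seed, nn_config)
    cal <- compute_caliper(psr$ps)
    matched <- ps_match(psr$ps, cohort$A, cal)
    balance[[m]] <- smd_table(cohort, matched)
    est <- estimate_effect(replicate_like, matched, method = m)
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = m, or = exp(est$log_or),
      ci_low = exp(est$ci_low), ci_high = exp(est$ci_high),
      n_pairs = est$n_pairs, converged = est$converged,
      stringsAsFactors = FALSE)
    if (isTRUE(run_tmle)) {
      if (is.null(sl)) sl <- fit_super_learner(cohort, seed = seed)
      tm <- tmle_estimate(cohort, psr$ps, sl = sl, method = m, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = tm$method, or = exp(tm$log_or),
        ci_low = exp(tm$ci_low), ci_high = exp(tm$ci_high),
        n_pairs = NA_integer_, converged = TRUE, stringsAsFactors = FALSE)
    }
  }
  list(estimates = do.call(rbind, rows), balance = balance)
}
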