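#' Define a plasmode simulation scenario
#'
#' @param id short scenario label.
#' @param exposure_prevalence treated fraction enforced by stratified
#'   resampling, in (0, 1).
#' @param outcome_prevalence target simulated outcome prevalence, in (0, 1).
#' @param true_or injected true conditional odds ratio.
#' @param sample_size rows per replicate.
#' @param n_sims number of replicates (the full study uses 1000).
#' @param base_seed integer seed offset for the scenario's replicate stream.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(id, exposure_prevalence, outcome_prevalence,
                            true_or, sample_size, n_sims = 1000L,
                            base_seed = 0L) {
  stopifnot(exposure_prevalence > 0, exposure_prevalence < 1,
            outcome_prevalence > 0, outcome_prevalence < 1,
            true_or > 0, sample_size >= 2, n_sims >= 1)
  structure(list(id = id, exposure_prevalence = exposure_prevalence,
                 outcome_prevalence = outcome_prevalence, true_or = true_or,
                 sample_size = as.integer(sample_size),
                 n_sims = as.integer(n_sims),
                 base_seed = as.integer(base_seed)),
            class = "scenario_config")
}

#' The five pre-registered simulation scenarios
#'
#' (i) frequent exposure and outcome (base): 30%/30%, OR 0.7, n 3500;
#' (ii) rare exposure: 5%/30%, OR 0.7, n 3500;
#' (iii) rare outcome: 30%/5%, OR 0.7, n 3500;
#' (iv) large sample: 30%/30%, OR 0.7, n 5000;
#' (v) null effect: 30%/30%, OR 1.0, n 3500.
#'
#' @param n_sims replicates per scenario (default 1000).
#' @return named list of [scenario_config()] objects.
#' @export
default_scenarios <- function(n_sims = 1000L) {
  list(
    i   = scenario_config("i",   0.30, 0.30, 0.7, 3500L, n_sims),
    ii  = scenario_config("ii",  0.05, 0.30, 0.7, 3500L, n_sims),
    iii = scenario_config("iii", 0.30, 0.05, 0.7, 3500L, n_sims),
    iv  = scenario_config("iv",  0.30, 0.30, 0.7, 5000L, n_sims),
    v   = scenario_config("v",   0.30, 0.30, 1.0, 3500L, n_sims)
  )
}

#' Read or write scenario configurations as YAML
#'
#' @param scenarios named list of [scenario_config()] objects.
#' @param path file path.
#' @return `read_scenarios_yaml` returns a named list of `scenario_config`s.
#' @export
write_scenarios_yaml <- function(scenarios, path) {
  yaml::write_yaml(lapply(scenarios, unclass), path)
  invisible(path)
}

#' @rdname write_scenarios_yaml
#' @export
read_scenarios_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s)
    scenario_config(s$id, s$exposure_prevalence, s$outcome_prevalence,
                    s$true_or, s$sample_size,
                    if (is.null(s$n_sims)) 1000L else s$n_sims,
                    if (is.null(s$base_seed)) 0L else s$base_seed))
}

#' Stratified with-replacement resampling of the base cohort
#'
#' Draws `round(sample_size * exposure_prevalence)` rows from the treated
#' stratum and the remainder from the untreated stratum, both with
#' replacement, so the treated fraction of every replicate is exact and
#' deterministic. Covariate rows are carried over unmodified; any base
#' outcome is dropped (it will be simulated).
#'
#' @param base a [new_cohort()] with exposure.
#' @param sample_size replicate size.
#' @param exposure_prevalence treated fraction in (0, 1).
#' @param seed integer seed.
#' @return a `cohort` with an extra `base_rows` attribute giving the sampled
#'   base row indices.
#' @export
resample_base <- function(base, sample_size, exposure_prevalence, seed) {
  if (exposure_prevalence <= 0 || exposure_prevalence >= 1)
    stop("exposure_prevalence must lie strictly in (0, 1): a stratum would be empty")
  t_rows <- which(base$A == 1L)
  c_rows <- which(base$A == 0L)
  if (!length(t_rows) || !length(c_rows))
    stop("base cohort needs both treated and untreated rows")
  n1 <- as.integer(round(sample_size * exposure_prevalence))
  n0 <- as.integer(sample_size) - n1
  if (n1 < 1L || n0 < 1L)
    stop("sample_size and exposure_prevalence give an empty stratum")
  rows <- with_seed(seed, c(t_rows[sample.int(length(t_rows), n1, replace = TRUE)],
                            c_rows[sample.int(length(c_rows), n0, replace = TRUE)]))
  out <- new_cohort(base$X[rows, , drop = FALSE],
                    base$A[rows], NULL, base$schema, scaled = base$scaled)
  rownames(out$X) <- NULL
  attr(out, "base_rows") <- rows
  out
}

#' Simulate outcomes from the calibrated outcome-generating model
#'
#' Draws `Y_i ~ Bernoulli(plogis(intercept + beta_treatment * A_i +
#' design_i . beta))`.
#'
#' @param spec a calibrated `dgm_spec`.
#' @param data a preprocessed [new_cohort()] (typically from
#'   [resample_base()]).
#' @param seed integer seed.
#' @param scenario_id,replicate_index bookkeeping labels carried through to
#'   the result.
#' @return a `plasmode_replicate`: the cohort with simulated `Y`, plus
#'   scenario id, replicate index and seed.
#' @export
simulate_outcomes <- function(spec, data, seed, scenario_id = "",
                              replicate_index = NA_integer_) {
  if (!isTRUE(spec$calibrated))
    stop("dgm_spec must be calibrated before simulating outcomes")
  pr <- expit(spec$intercept + dgm_linear_predictor(spec, data))
  data$Y <- with_seed(seed, rbinom(length(pr), 1L, pr))
  structure(list(data = data, scenario_id = scenario_id,
                 replicate_index = replicate_index, seed = as.integer(seed)),
            class = "plasmode_replicate")
}

#' Build the scenario's true outcome-generating model
#'
#' Fits the outcome-model term list on the base cohort, injects the
#' scenario's true odds ratio, and calibrates the intercept once against the
#' base cohort with its exposure strata reweighted to the scenario's
#' exposure prevalence. This matches the expectation under stratified
#' resampling exactly, so the achieved outcome prevalence is on target
#' without any calibration-stage Monte Carlo error.
#'
#' @param base preprocessed [new_cohort()] with a base outcome.
#' @param scenario a [scenario_config()].
#' @return a calibrated `dgm_spec`.
#' @export
build_dgm <- function(base, scenario) {
  spec <- fit_true_outcome_model(base, dgm_terms(base$schema),
                                 scenario$true_or)
  p <- scenario$exposure_prevalence
  n1 <- sum(base$A == 1L); n0 <- sum(base$A == 0L)
  w <- ifelse(base$A == 1L, p / n1, (1 - p) / n0)
  calibrate_intercept(spec, base, scenario$outcome_prevalence, weights = w)
}
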