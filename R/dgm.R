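#' Term list of the true outcome-generating model
#'
#' The true outcome model contains main effects of all covariates, a cubic
#' polynomial in age, a quadratic polynomial in the PaO2/FiO2 ratio, a
#' second-order interaction between heart rate and mean blood pressure, a
#' third-order interaction among Glasgow Coma Score, hematocrit and sodium,
#' the exponential of weight and the cosine of the APACHE score. Polynomial
#' terms carry the first power, so age and pafi do not appear again as plain
#' main effects.
#'
#' @param schema a (preprocessed) [cov_schema()].
#' @return list of term descriptors, each a list with a `type` of `"main"`,
#'   `"poly"`, `"interaction"` or `"transform"`.
#' @export
dgm_terms <- function(schema) {
  validate_schema(schema)
  plain <- setdiff(schema$name, c("age", "pafi"))
  c(lapply(plain, function(v) list(type = "main", var = v)),
    list(list(type = "poly", var = "age", degree = 3L),
         list(type = "poly", var = "pafi", degree = 2L),
         list(type = "interaction", vars = c("heart_rate", "mean_bp")),
         list(type = "interaction", vars = c("gcs", "hematocrit", "sodium")),
         list(type = "transform", var = "weight", fn = "exp"),
         list(type = "transform", var = "apache", fn = "cos")))
}

term_labels <- function(term) {
  switch(term$type,
         main = term$var,
         poly = paste0(term$var, "^", seq_len(term$degree)),
         interaction = paste(term$vars, collapse = ":"),
         transform = sprintf("%s(%s)", term$fn, term$var),
         stop("unknown term type: ", term$type))
}

#' Expand a cohort into the outcome-model design matrix
#'
#' Columns follow the term-list order. Polynomial terms are raw powers of the
#' (scaled) variable, interactions are elementwise products, and transform
#' terms apply `exp` or `cos` elementwise.
#'
#' @param cohort a preprocessed [new_cohort()].
#' @param terms term list from [dgm_terms()] (or a `dgm_spec`'s `terms`).
#' @return numeric matrix with one column per expanded term.
#' @export
build_design_matrix <- function(cohort, terms) {
  X <- cohort$X
  cols <- list()
  for (term in terms) {
    vars <- if (term$type == "interaction") term$vars else term$var
    missing_v <- setdiff(vars, names(X))
    if (length(missing_v))
      stop("design needs covariates absent from the cohort: ",
           paste(missing_v, collapse = ", "))
    new <- switch(term$type,
      main = list(as.numeric(X[[term$var]])),
      poly = lapply(seq_len(term$degree),
                    function(d) as.numeric(X[[term$var]])^d),
      interaction = list(Reduce(`*`, lapply(term$vars,
                                            function(v) as.numeric(X[[v]])))),
      transform = list(switch(term$fn,
                              exp = exp(as.numeric(X[[term$var]])),
                              cos = cos(as.numeric(X[[term$var]])),
                              stop("unknown transform: ", term$fn))))
    names(new) <- term_labels(term)
    cols <- c(cols, new)
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

#' Fit the true outcome-generating model on a base cohort
#'
#' Fits a maximum-likelihood logistic regression of the base outcome on the
#' exposure and the expanded term design, then overwrites the treatment
#' coefficient with `log(true_or)`, making `true_or` the injected conditional
#' odds ratio of the simulation. The intercept still needs
#' [calibrate_intercept()] before outcomes can be simulated.
#'
#' @param base a preprocessed [new_cohort()] with a binary outcome.
#' @param terms term list; defaults to [dgm_terms()] of the base schema.
#' @param true_or true conditional odds ratio to inject (positive).
#' @return a `dgm_spec`: terms, named coefficient vector `beta`,
#'   `beta_treatment = log(true_or)`, uncalibrated intercept, `source`.
#' @export
fit_true_outcome_model <- function(base, terms = dgm_terms(base$schema),
                                   true_or) {
  if (is.null(base$Y)) stop("base cohort has no outcome to fit")
  if (true_or <= 0) stop("true_or must be positive")
  D <- build_design_matrix(base, terms)
  fit <- fit_logistic(cbind(A = base$A, D), base$Y)
  if (!fit$converged)
    stop("true outcome model did not converge (possible separation); ",
         "terms: ", paste(colnames(D)[!is.finite(fit$coef[-(1:2)])],
                          collapse = ", "))
  beta <- fit$coef[-(1:2)]
  names(beta) <- colnames(D)
  structure(list(terms = terms, beta = beta,
                 beta_treatment = log(true_or),
                 intercept = unname(fit$coef[1L]),
                 calibrated = FALSE, source = "fitted"),
            class = "dgm_spec")
}

#' @export
print.dgm_spec <- function(x, ...) {
  cat(sprintf(paste0("<dgm_spec> %d terms (%d columns), treatment log-OR ",
                     "%.4f, intercept %.4f (%s)\n"),
              length(x$terms), length(x$beta), x$beta_treatment, x$intercept,
              if (x$calibrated) "calibrated" else "uncalibrated"))
  invisible(x)
}

dgm_linear_predictor <- function(spec, cohort) {
  D <- build_design_matrix(cohort, spec$terms)
  drop(D %*% spec$beta) + spec$beta_treatment * cohort$A
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Sets the intercept by monotone root-finding so that the mean of
#' `plogis(intercept + linear predictor)` over the supplied cohort equals
#' `target` (to within 1e-8). All other coefficients are untouched.
#'
#' @param spec a `dgm_spec`.
#' @param cohort a preprocessed [new_cohort()] with exposure.
#' @param target desired outcome prevalence in (0, 1).
#' @param weights optional nonnegative row weights (normalized internally);
#'   used to calibrate against a reweighted version of the cohort, e.g. with
#'   exposure strata reweighted to a scenario's exposure prevalence.
#' @return the calibrated `dgm_spec`.
#' @export
calibrate_intercept <- function(spec, cohort, target, weights = NULL) {
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)")
  lp <- dgm_linear_predictor(spec, cohort)
  spec$intercept <- solve_intercept(lp, target, tol = 1e-10,
                                    weights = weights)
  spec$calibrated <- TRUE
  spec
}
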