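# Shared fixtures: all built in code, no stored data.

# Small RHC-like cohort: 9 special + extra covariates, fast to generate.
small_cohort <- function(n = 600, seed = 1, confounding_strength = 1,
                         exposure_prevalence = 0.38, n_binary = 2L,
                         n_categorical = 0L, ...) {
  generate_cohort(n,
                  schema = default_schema(n_continuous = 9L,
                                          n_binary = n_binary,
                                          n_categorical = n_categorical),
                  exposure_prevalence = exposure_prevalence,
                  confounding_strength = confounding_strength,
                  seed = seed, ...)
}

# Hand-built scaled cohort with arbitrary numeric covariates and known A/Y.
manual_cohort <- function(X, A, Y = NULL) {
  X <- as.data.frame(X)
  schema <- cov_schema(names(X), "continuous",
                      role = rep("plain", ncol(X)))
  new_cohort(X, A, Y, schema, scaled = TRUE)
}

# A cohort whose true propensity model is linear-logistic in one block of
# standard-normal covariates; returns the cohort plus the true PS.
linear_ps_cohort <- function(n, p = 5, beta = NULL, intercept = -0.5,
                             seed = 1) {
  if (is.null(beta)) beta <- seq(0.8, 0.2, length.out = p)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  ps_true <- plogis(intercept + drop(X %*% beta))
  A <- rbinom(n, 1, ps_true)
  list(cohort = manual_cohort(X, A), ps_true = ps_true)
}

# Independent greedy-matching re-implementation used as an oracle:
# plain double loop, no shared code with ps_match().
oracle_greedy_match <- function(lps, A, caliper) {
  treated <- which(A == 1); controls <- which(A == 0)
  used <- logical(length(controls))
  pairs <- NULL
  for (t in treated) {
    best <- NA; best_d <- Inf
    for (j in seq_along(controls)) {
      if (used[j]) next
      d <- abs(lps[controls[j]] - lps[t])
      if (d < best_d) { best_d <- d; best <- j }
    }
    if (!is.na(best) && best_d <= caliper) {
      used[best] <- TRUE
      pairs <- rbind(pairs, c(t, controls[best]))
    }
  }
  pairs
}

# Maximum number of caliper-feasible pairs by exhaustive assignment search
# (bitmask DP over controls; fine for <= 6 x 6 instances).
oracle_max_pairs <- function(lps, A, caliper) {
  treated <- which(A == 1); controls <- which(A == 0)
  nt <- length(treated); nc <- length(controls)
  feas <- outer(treated, controls,
                function(t, c) abs(lps[t] - lps[c]) <= caliper)
  best <- 0
  recurse <- function(ti, used) {
    if (ti > nt) return(0)
    most <- recurse_memo(ti + 1L, used)  # skip this treated unit
    for (j in seq_len(nc)) {
      if (!used[j] && feas[ti, j]) {
        u2 <- used; u2[j] <- TRUE
        most <- max(most, 1L + recurse_memo(ti + 1L, u2))
      }
    }
    most
  }
  memo <- new.env()
  recurse_memo <- function(ti, used) {
    key <- paste0(ti, ":", paste0(as.integer(used), collapse = ""))
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- recurse(ti, used)
    memo[[key]] <- v
    v
  }
  recurse_memo(1L, logical(nc))
}

# Cohort whose outcome model is either logistic-linear or hinge-shaped in
# x1; used by the super-learner and TMLE tests.
sl_cohort <- function(n, truth = c("logistic", "hinge"), seed = 1) {
  truth <- match.arg(truth)
  set.seed(seed)
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  A <- rbinom(n, 1, plogis(0.4 * X[, 1]))
  eta <- if (truth == "logistic") -0.3 + 0.8 * X[, 1] - 0.5 * X[, 2] + 0.3 * A
         else -0.5 + 3 * pmax(X[, 1] - 0.2, 0) - 2.5 * pmax(-X[, 1], 0) + 0.3 * A
  Y <- rbinom(n, 1, plogis(eta))
  manual_cohort(X, A, Y)
}

# Lightweight stand-in estimate objects for the performance module.
fake_estimate <- function(log_or, se, converged = TRUE) {
  list(method = "X", log_or = log_or, se = se,
       ci_low = log_or - qnorm(0.975) * se,
       ci_high = log_or + qnorm(0.975) * se,
       converged = converged)
}
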