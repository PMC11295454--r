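#' Cohort container
#'
#' A `cohort` bundles the covariate table `X` (data frame; categoricals as
#' character level labels before preprocessing), the binary exposure `A`, an
#' optional binary outcome `Y`, the covariate schema, and a flag recording
#' whether continuous covariates have been centered and scaled.
#'
#' @param X data frame of covariates.
#' @param A integer/numeric 0-1 exposure vector.
#' @param Y optional 0-1 outcome vector.
#' @param schema a [cov_schema()].
#' @param scaled logical; `TRUE` once [preprocess()] has run.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(X, A, Y = NULL, schema, scaled = FALSE) {
  stopifnot(is.data.frame(X), nrow(X) == length(A))
  if (nrow(X) < 2L) stop("a cohort needs n >= 2 rows")
  if (anyNA(X) || anyNA(A) || (!is.null(Y) && anyNA(Y)))
    stop("cohort contains missing values")
  if (!all(A %in% c(0, 1))) stop("exposure must be coded 0/1")
  if (!is.null(Y) && !all(Y %in% c(0, 1))) stop("outcome must be coded 0/1")
  structure(list(X = X, A = as.integer(A),
                 Y = if (is.null(Y)) NULL else as.integer(Y),
                 schema = schema, scaled = isTRUE(scaled)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> n = %d, covariates = %d (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(sprintf("%d %s", table(x$schema$kind),
                            names(table(x$schema$kind))), collapse = ", ")))
  cat(sprintf("  exposure prevalence = %.3f; outcome %s; %s\n",
              mean(x$A),
              if (is.null(x$Y)) "absent"
              else sprintf("prevalence = %.3f", mean(x$Y)),
              if (x$scaled) "scaled" else "unscaled"))
  invisible(x)
}

#' @export
dim.cohort <- function(x) c(nrow(x$X), ncol(x$X))

# Deterministic pick of the exposure-model covariates: 5 special continuous,
# then plain continuous, then binaries, up to n_use names.
exposure_covariates <- function(schema, n_use = 12L) {
  sp <- c("age", "pafi", "heart_rate", "mean_bp", "apache")
  plain_cont <- setdiff(schema$name[schema$kind == "continuous"],
                        dgm_special_names())
  bins <- schema$name[schema$kind == "binary"]
  utils::head(c(sp, plain_cont, bins), n_use)
}

#' Generate a synthetic RHC-like cohort
#'
#' Continuous covariates are drawn from a multivariate normal with
#' exchangeable correlation `rho`; binary and categorical covariates are
#' generated through logistic/multinomial links on the continuous block, so
#' all covariate kinds are mutually correlated. The exposure follows a
#' logistic model on 12 covariates (5 of them special) with slopes
#' `±0.2 * confounding_strength` and an intercept calibrated so the expected
#' exposure prevalence equals `exposure_prevalence`. A base outcome is
#' simulated from a confounded logistic mechanism that includes mild versions
#' of the special nonlinear terms, so that refitting the true
#' outcome-generating model on this cohort yields non-trivial coefficients.
#'
#' @param n number of subjects (>= 2).
#' @param schema a [cov_schema()]; defaults to [default_schema()].
#' @param exposure_prevalence target exposure prevalence in (0, 1).
#' @param confounding_strength nonnegative multiplier on the exposure-model
#'   slopes; 0 makes exposure independent of the covariates.
#' @param seed integer seed; identical seeds give bitwise-identical cohorts.
#' @param rho exchangeable correlation of the continuous block.
#' @param outcome_prevalence target prevalence of the simulated base outcome,
#'   or `NULL` to omit the outcome.
#' @return an unscaled [new_cohort()] object.
#' @export
generate_cohort <- function(n, schema = default_schema(),
                            exposure_prevalence = 0.38,
                            confounding_strength = 1,
                            seed = 1L, rho = 0.2,
                            outcome_prevalence = 0.30) {
  if (n < 2L) stop("n must be >= 2")
  if (exposure_prevalence <= 0 || exposure_prevalence >= 1)
    stop("exposure_prevalence must lie strictly in (0, 1)")
  if (confounding_strength < 0) stop("confounding_strength must be >= 0")
  validate_schema(schema)

  cont_names <- schema$name[schema$kind == "continuous"]
  bin_names <- schema$name[schema$kind == "binary"]
  cat_names <- schema$name[schema$kind == "categorical"]
  p_c <- length(cont_names)

  with_seed(seed, {
    # continuous block: exchangeable correlation via the one-factor construction
    # x_j = sqrt(rho) f + sqrt(1 - rho) e_j, standard normal marginals
    f <- rnorm(n)
    Z <- sqrt(rho) * f + sqrt(1 - rho) *
      matrix(rnorm(n * p_c), n, p_c)
    colnames(Z) <- cont_names
    X <- as.data.frame(Z)

    # binaries: logistic on two rotating continuous parents; intercepts vary
    # prevalence across covariates
    for (j in seq_along(bin_names)) {
      k1 <- (j - 1L) %% p_c + 1L
      k2 <- j %% p_c + 1L
      a0 <- -0.8 + 0.6 * ((j - 1L) %% 4L) / 3  # prevalences roughly 0.3-0.5
      pr <- expit(a0 + 0.8 * Z[, k1] + 0.4 * Z[, k2])
      X[[bin_names[j]]] <- rbinom(n, 1L, pr)
    }

    # categoricals: multinomial logit on two continuous parents
    for (j in seq_along(cat_names)) {
      lv <- schema$levels[[match(cat_names[j], schema$name)]]
      k1 <- (2L * j - 1L) %% p_c + 1L
      k2 <- (2L * j) %% p_c + 1L
      eta <- cbind(0, 0.7 * Z[, k1] - 0.3, 0.5 * Z[, k2] - 0.3)
      eta <- eta[, seq_len(min(length(lv), 3L)), drop = FALSE]
      pr <- exp(eta) / rowSums(exp(eta))
      cum <- t(apply(pr, 1, cumsum))
      u <- runif(n)
      idx <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
      X[[cat_names[j]]] <- lv[idx]
    }

    # exposure: logistic on 12 covariates, slopes alternating +/- 0.2 * strength
    ev <- exposure_covariates(schema)
    M <- vapply(ev, function(v) as.numeric(X[[v]]), numeric(n))
    beta_a <- 0.2 * confounding_strength *
      rep_len(c(1, -1), length(ev))
    lp_a <- drop(M %*% beta_a)
    b0 <- solve_intercept(lp_a, exposure_prevalence)
    A <- rbinom(n, 1L, expit(b0 + lp_a))

    Y <- NULL
    if (!is.null(outcome_prevalence)) {
      lp_y <- base_outcome_lp(X, A)
      c0 <- solve_intercept(lp_y, outcome_prevalence)
      Y <- rbinom(n, 1L, expit(c0 + lp_y))
    }

    new_cohort(X, A, Y, schema, scaled = FALSE)
  })
}

# Confounded base-outcome linear predictor (without intercept): moderate main
# effects plus mild versions of the special nonlinear terms. Used only to
# seed the refit of the true outcome model on synthetic cohorts.
base_outcome_lp <- function(X, A) {
  sp <- dgm_special_names()
  main <- vapply(seq_along(sp), function(i) {
    0.3 * (-1)^(i - 1L) * X[[sp[i]]]
  }, numeric(nrow(X)))
  extra_cont <- grep("^cont", names(X), value = TRUE)
  extra <- 0
  for (i in seq_along(utils::head(extra_cont, 6L)))
    extra <- extra + 0.25 * (-1)^i * X[[extra_cont[i]]]
  bins <- grep("^bin", names(X), value = TRUE)
  for (i in seq_along(utils::head(bins, 4L)))
    extra <- extra + 0.3 * (-1)^(i - 1L) * X[[bins[i]]]
  rowSums(main) + extra - 0.3 * A +
    0.10 * X$age^2 + 0.04 * X$age^3 +
    0.10 * X$pafi^2 +
    0.10 * X$heart_rate * X$mean_bp +
    0.05 * X$gcs * X$hematocrit * X$sodium +
    0.10 * exp(X$weight) +
    0.15 * cos(X$apache)
}

#' Load a cohort from a CSV file
#'
#' Reads a header CSV with one row per subject, pulls out the exposure and
#' (optionally) outcome columns, recodes two-level exposure/outcome columns
#' to 0/1, drops incomplete rows (with a message stating the count), and
#' infers a schema when none is supplied: numeric columns taking only the
#' values 0/1 are binary, other numeric columns continuous, and character
#' columns categorical.
#'
#' @param path CSV file path.
#' @param exposure_col name of the binary exposure column.
#' @param outcome_col optional name of the binary outcome column.
#' @param schema optional [cov_schema()] describing the covariates.
#' @return an unscaled [new_cohort()].
#' @export
load_cohort <- function(path, exposure_col, outcome_col = NULL,
                        schema = NULL) {
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(exposure_col, outcome_col)
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  cc <- stats::complete.cases(dat)
  if (any(!cc)) {
    message(sum(!cc), " rows with missing values dropped (complete-case)")
    dat <- dat[cc, , drop = FALSE]
  }
  recode_binary <- function(v, col) {
    u <- sort(unique(v))
    if (length(u) != 2L)
      stop("column '", col, "' is not binary (", length(u), " levels)")
    if (is.numeric(v) && all(u == c(0, 1))) return(as.integer(v))
    as.integer(v == u[2L])
  }
  A <- recode_binary(dat[[exposure_col]], exposure_col)
  Y <- if (!is.null(outcome_col)) recode_binary(dat[[outcome_col]], outcome_col)
  X <- dat[, setdiff(names(dat), need), drop = FALSE]
  if (is.null(schema)) {
    kinds <- vapply(X, function(v) {
      if (is.numeric(v)) {
        if (all(v %in% c(0, 1))) "binary" else "continuous"
      } else "categorical"
    }, "")
    levels <- lapply(seq_along(X), function(j) {
      if (kinds[j] == "categorical") sort(unique(as.character(X[[j]]))) else NULL
    })
    schema <- cov_schema(names(X), kinds, levels,
                         role = ifelse(names(X) %in% dgm_special_names(),
                                       "dgm_special", "plain"))
  } else {
    keep <- intersect(schema$name, names(X))
    if (!length(keep)) stop("no schema covariates found in the CSV")
    X <- X[, keep, drop = FALSE]
    schema <- schema[match(keep, schema$name), , drop = FALSE]
    class(schema) <- c("cov_schema", "data.frame")
  }
  new_cohort(X, A, Y, schema, scaled = FALSE)
}

#' Center and scale a cohort for modelling
#'
#' Continuous covariates are centered and scaled to unit standard deviation
#' (n-1 denominator). Categorical covariates are expanded to reference-coded
#' 0/1 indicator columns (first level is the reference) so that every
#' downstream model sees one shared numeric design. Binary covariates are
#' left untouched.
#'
#' @param cohort an unscaled [new_cohort()].
#' @return a scaled `cohort` whose `X` is entirely numeric.
#' @export
preprocess <- function(cohort) {
  if (cohort$scaled) stop("cohort is already preprocessed")
  schema <- cohort$schema
  X <- cohort$X
  out <- list(); new_rows <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    v <- X[[nm]]
    if (schema$kind[i] == "continuous") {
      s <- stats::sd(v)
      if (s == 0) stop("zero-variance continuous column: ", nm)
      out[[nm]] <- (v - mean(v)) / s
      new_rows[[length(new_rows) + 1L]] <-
        data.frame(name = nm, kind = "continuous", role = schema$role[i])
    } else if (schema$kind[i] == "binary") {
      out[[nm]] <- as.numeric(v)
      new_rows[[length(new_rows) + 1L]] <-
        data.frame(name = nm, kind = "binary", role = schema$role[i])
    } else {
      lv <- schema$levels[[i]]
      for (l in lv[-1L]) {
        cn <- paste0(nm, ".", l)
        out[[cn]] <- as.numeric(v == l)
        new_rows[[length(new_rows) + 1L]] <-
          data.frame(name = cn, kind = "binary", role = "plain")
      }
    }
  }
  meta <- do.call(rbind, new_rows)
  new_schema <- cov_schema(meta$name, meta$kind, role = meta$role)
  new_cohort(as.data.frame(out), cohort$A, cohort$Y, new_schema,
             scaled = TRUE)
}

# Numeric covariate matrix of a preprocessed cohort.
cohort_matrix <- function(cohort) {
  if (!cohort$scaled) stop("cohort must be preprocessed first")
  as.matrix(cohort$X)
}
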