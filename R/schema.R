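#' Names of the covariates used in the special outcome-model terms
#'
#' The true outcome-generating model contains, beyond main effects,
#' polynomial terms in age and the PaO2/FiO2 ratio, an interaction between
#' heart rate and mean blood pressure, a three-way interaction among Glasgow
#' Coma Score, hematocrit and sodium, the exponential of weight and the
#' cosine of the APACHE score. These nine covariates must be present (and
#' continuous) in every schema used to build that model.
#'
#' @return character vector of the nine covariate names.
#' @export
dgm_special_names <- function() {
  c("age", "pafi", "heart_rate", "mean_bp", "gcs",
    "hematocrit", "sodium", "weight", "apache")
}

#' Construct a covariate schema
#'
#' A schema describes each covariate by name, kind (continuous, binary or
#' categorical), its levels (categoricals only) and its role: `"dgm_special"`
#' marks the nine named covariates entering the special outcome-model terms,
#' everything else is `"plain"`.
#'
#' @param name character vector of unique covariate names.
#' @param kind character vector, each one of `"continuous"`, `"binary"`,
#'   `"categorical"`.
#' @param levels list of character level vectors (only consulted for
#'   categorical covariates; `NULL` otherwise).
#' @param role character vector, each `"dgm_special"` or `"plain"`.
#' @return a `cov_schema` object (a data frame with a `levels` list column).
#' @export
cov_schema <- function(name, kind, levels = NULL, role = NULL) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("covariate names must be unique")
  kind <- match.arg(kind, c("continuous", "binary", "categorical"),
                    several.ok = TRUE)
  kind <- rep_len(kind, length(name))
  if (is.null(role)) {
    role <- ifelse(name %in% dgm_special_names(), "dgm_special", "plain")
  }
  role <- rep_len(role, length(name))
  if (is.null(levels)) levels <- vector("list", length(name))
  stopifnot(length(levels) == length(name), length(role) == length(name))
  bad <- kind == "categorical" & vapply(levels, length, 1L) < 2L
  if (any(bad))
    stop("categorical covariates need >= 2 levels: ",
         paste(name[bad], collapse = ", "))
  out <- data.frame(name = name, kind = kind, role = role,
                    stringsAsFactors = FALSE)
  out$levels <- levels
  class(out) <- c("cov_schema", "data.frame")
  out
}

#' Default RHC-like covariate schema
#'
#' 22 continuous covariates (including the nine special ones), 22 binary
#' covariates and 6 three-level categorical covariates: 50 raw covariates in
#' total, mirroring the size and mix of the critical-care adjustment set the
#' simulation emulates.
#'
#' @param n_continuous total number of continuous covariates (>= 9).
#' @param n_binary number of binary covariates.
#' @param n_categorical number of three-level categorical covariates.
#' @return a [cov_schema()] object.
#' @export
default_schema <- function(n_continuous = 22L, n_binary = 22L,
                           n_categorical = 6L) {
  if (n_continuous < 9L)
    stop("need at least the nine special continuous covariates")
  cont <- c(dgm_special_names(),
            sprintf("cont%02d", seq_len(n_continuous - 9L)))
  bin <- if (n_binary > 0L) sprintf("bin%02d", seq_len(n_binary)) else character()
  cat <- if (n_categorical > 0L) sprintf("cat%02d", seq_len(n_categorical)) else character()
  levels <- c(vector("list", length(cont) + length(bin)),
              rep(list(c("a", "b", "c")), length(cat)))
  cov_schema(name = c(cont, bin, cat),
             kind = c(rep("continuous", length(cont)),
                      rep("binary", length(bin)),
                      rep("categorical", length(cat))),
             levels = levels)
}

validate_schema <- function(schema) {
  if (!inherits(schema, "cov_schema")) stop("not a cov_schema")
  sp <- dgm_special_names()
  present <- sp %in% schema$name
  if (!all(present))
    stop("schema is missing special covariates: ",
         paste(sp[!present], collapse = ", "))
  kinds <- schema$kind[match(sp, schema$name)]
  if (!all(kinds == "continuous"))
    stop("special covariates must be continuous")
  invisible(schema)
}

#' Read or write a covariate schema as YAML
#'
#' @param schema a [cov_schema()] object.
#' @param path file path.
#' @return `read_schema_yaml` returns a `cov_schema`; `write_schema_yaml`
#'   returns `path` invisibly.
#' @export
write_schema_yaml <- function(schema, path) {
  entries <- lapply(seq_len(nrow(schema)), function(i) {
    e <- list(name = schema$name[i], kind = schema$kind[i],
              role = schema$role[i])
    if (schema$kind[i] == "categorical") e$levels <- schema$levels[[i]]
    e
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_schema_yaml
#' @export
read_schema_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  cov_schema(name = vapply(entries, `[[`, "", "name"),
             kind = vapply(entries, `[[`, "", "kind"),
             levels = lapply(entries, function(e) {
               if (is.null(e$levels)) NULL else as.character(e$levels)
             }),
             role = vapply(entries, `[[`, "", "role"))
}
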