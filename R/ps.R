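#' Network configuration for the deep-learning propensity estimators
#'
#' Defaults follow the package's declared architectures: a supervised
#' classifier with hidden layers (64, 32, 16), and an autoencoder with
#' encoder (32, 16), a linear 10-unit bottleneck and a symmetric decoder.
#' The regularization block (dropout 0.3, L2 penalty 0.01, batch
#' normalization, He normal initialization) is what the optimized variants
#' switch on.
#'
#' @param hidden_sizes hidden layer widths of the supervised classifier.
#' @param ae_hidden encoder hidden widths (decoder mirrors them).
#' @param bottleneck_size autoencoder bottleneck width.
#' @param dropout_rate dropout probability on hidden layers.
#' @param l2_penalty L2 weight-decay coefficient.
#' @param batch_norm use batch normalization on hidden layers.
#' @param he_init use He normal initialization (Glorot uniform otherwise).
#' @param epochs,ae_epochs training epochs for classifier / autoencoder.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed integer seed making training bit-reproducible.
#' @return a `net_config` list.
#' @export
net_config <- function(hidden_sizes = c(64L, 32L, 16L),
                       ae_hidden = c(32L, 16L),
                       bottleneck_size = 10L,
                       dropout_rate = 0.3, l2_penalty = 0.01,
                       batch_norm = TRUE, he_init = TRUE,
                       epochs = 50L, ae_epochs = 100L,
                       batch_size = 64L, learning_rate = 1e-3,
                       seed = 1L) {
  stopifnot(all(hidden_sizes >= 1), bottleneck_size >= 1,
            dropout_rate >= 0, dropout_rate < 1, l2_penalty >= 0,
            epochs >= 1, batch_size >= 2, learning_rate > 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 ae_hidden = as.integer(ae_hidden),
                 bottleneck_size = as.integer(bottleneck_size),
                 dropout_rate = dropout_rate, l2_penalty = l2_penalty,
                 batch_norm = isTRUE(batch_norm), he_init = isTRUE(he_init),
                 epochs = as.integer(epochs),
                 ae_epochs = as.integer(ae_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "net_config")
}

#' Read or write a network configuration as YAML
#' @param config a [net_config()].
#' @param path file path.
#' @export
write_net_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_net_config_yaml
#' @export
read_net_config_yaml <- function(path) {
  do.call(net_config, yaml::read_yaml(path))
}

ps_result <- function(method, ps, diagnostics, seed = NA_integer_) {
  structure(list(method = method, ps = as.numeric(ps),
                 diagnostics = diagnostics, seed = seed),
            class = "ps_result")
}

#' @export
print.ps_result <- function(x, ...) {
  cat(sprintf("<ps_result> %s: n = %d, range [%.4f, %.4f], converged = %s\n",
              x$method, length(x$ps), min(x$ps), max(x$ps),
              isTRUE(x$diagnostics$converged)))
  invisible(x)
}

check_ps_cohort <- function(cohort) {
  if (!cohort$scaled) stop("cohort must be preprocessed before PS estimation")
  if (length(unique(cohort$A)) < 2L)
    stop("exposure is constant; propensity model is degenerate")
  invisible(cohort)
}

#' Propensity scores from main-effects logistic regression
#'
#' @param cohort a preprocessed [new_cohort()].
#' @param clip_bound probability clipping bound (propensities are kept in
#'   `[clip_bound, 1 - clip_bound]` so the logit stays finite).
#' @return a `ps_result` with convergence flag and clipping count.
#' @export
ps_logistic <- function(cohort, clip_bound = 1e-6) {
  check_ps_cohort(cohort)
  fit <- fit_logistic(cohort_matrix(cohort), cohort$A)
  cl <- clip_prob(fit$fitted, clip_bound)
  ps_result("PS", cl$p,
            list(converged = fit$converged, truncation_count = cl$n_clipped))
}

#' Propensity scores from MARS
#'
#' Least-squares MARS of the exposure on covariate main effects, with hinge
#' bases, interactions up to `max_degree`, and GCV backward pruning (no
#' cross-validation). Raw predictions can fall outside (0, 1) and are
#' truncated; the truncation count is reported.
#'
#' @param cohort a preprocessed [new_cohort()].
#' @param max_degree maximum interaction order of the hinge bases.
#' @param clip_bound truncation bound.
#' @param ... further arguments passed to [mars_fit()].
#' @return a `ps_result`.
#' @export
ps_mars <- function(cohort, max_degree = 2L, clip_bound = 1e-6, ...) {
  check_ps_cohort(cohort)
  fit <- mars_fit(cohort_matrix(cohort), cohort$A, max_degree = max_degree,
                  ...)
  raw <- fit$fitted
  out_of_range <- sum(raw <= 0 | raw >= 1)
  cl <- clip_prob(raw, clip_bound)
  ps_result("MARS", cl$p,
            list(converged = all(is.finite(raw)),
                 truncation_count = out_of_range,
                 n_terms = length(fit$active), gcv = fit$gcv))
}

#' Propensity scores from a supervised deep-learning classifier
#'
#' A feed-forward sigmoid classifier trained with binary cross-entropy on
#' covariate main effects. With `naive = FALSE` the network uses dropout, L2
#' regularization, batch normalization and He initialization per `config`;
#' `naive = TRUE` disables all four.
#'
#' @param cohort a preprocessed [new_cohort()].
#' @param config a [net_config()].
#' @param naive drop the regularization/initialization block.
#' @param clip_bound probability clipping bound.
#' @return a `ps_result` (method `"DL"` or `"DL.n"`).
#' @export
ps_deep_supervised <- function(cohort, config = net_config(), naive = FALSE,
                               clip_bound = 1e-6) {
  check_ps_cohort(cohort)
  X <- cohort_matrix(cohort)
  net <- mlp_train(X, cohort$A, hidden = config$hidden_sizes,
                   out_act = "sigmoid", loss = "bce",
                   dropout = if (naive) 0 else config$dropout_rate,
                   l2 = if (naive) 0 else config$l2_penalty,
                   batch_norm = if (naive) FALSE else config$batch_norm,
                   he_init = if (naive) FALSE else config$he_init,
                   epochs = config$epochs, batch_size = config$batch_size,
                   lr = config$learning_rate, seed = config$seed)
  raw <- drop(mlp_predict(net, X))
  converged <- all(is.finite(net$trajectory)) && all(is.finite(raw))
  cl <- clip_prob(raw, clip_bound)
  ps_result(if (naive) "DL.n" else "DL", cl$p,
            list(converged = converged, truncation_count = cl$n_clipped,
                 loss_trajectory = net$trajectory),
            seed = config$seed)
}

#' Propensity scores from an autoencoder bottleneck
#'
#' An autoencoder (encoder, linear bottleneck, mirrored decoder, linear
#' output, mean-squared reconstruction loss) is trained unsupervised on the
#' covariates; the propensity score is then a logistic regression of the
#' exposure on the bottleneck activations. With `optimized = TRUE` the
#' network adds dropout 0.3, L2 0.01, batch normalization and He normal
#' initialization (per `config`).
#'
#' @param cohort a preprocessed [new_cohort()].
#' @param config a [net_config()].
#' @param optimized add the regularization/initialization block.
#' @param clip_bound probability clipping bound.
#' @return a `ps_result` (method `"AE"` or `"AE.o"`) whose diagnostics
#'   include the reconstruction-loss trajectory.
#' @export
ps_autoencoder <- function(cohort, config = net_config(), optimized = FALSE,
                           clip_bound = 1e-6) {
  check_ps_cohort(cohort)
  X <- cohort_matrix(cohort)
  hidden <- c(config$ae_hidden, config$bottleneck_size, rev(config$ae_hidden))
  hidden_acts <- c(rep("relu", length(config$ae_hidden)), "linear",
                   rep("relu", length(config$ae_hidden)))
  net <- mlp_train(X, X, hidden = hidden, hidden_acts = hidden_acts,
                   out_act = "linear", loss = "mse",
                   dropout = if (optimized) config$dropout_rate else 0,
                   l2 = if (optimized) config$l2_penalty else 0,
                   batch_norm = if (optimized) config$batch_norm else FALSE,
                   he_init = if (optimized) config$he_init else FALSE,
                   epochs = config$ae_epochs, batch_size = config$batch_size,
                   lr = config$learning_rate, seed = config$seed)
  bottleneck_layer <- length(config$ae_hidden) + 1L
  Z <- mlp_predict(net, X, layer = bottleneck_layer)
  keep <- apply(Z, 2, function(z) stats::sd(z) > 1e-10)
  fit <- fit_logistic(Z[, keep, drop = FALSE], cohort$A)
  converged <- all(is.finite(net$trajectory)) && fit$converged
  cl <- clip_prob(fit$fitted, clip_bound)
  ps_result(if (optimized) "AE.o" else "AE", cl$p,
            list(converged = converged, truncation_count = cl$n_clipped,
                 loss_trajectory = net$trajectory,
                 reconstruction_mse = utils::tail(net$trajectory, 1)),
            seed = config$seed)
}
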