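# Minimal deterministic feed-forward network engine: dense layers, ReLU
# hidden activations, sigmoid/linear outputs, binary cross-entropy or
# mean-squared-error loss, Adam, inverted dropout, L2 weight penalty and
# batch normalization. Gradients are verified against numeric differentiation
# in the test suite.

act_fun <- function(z, act) {
  switch(act, relu = pmax(z, 0), sigmoid = expit(z), linear = z,
         stop("unknown activation: ", act))
}

mlp_init <- function(sizes, acts, batch_norm, he_init, dropout) {
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    W <- if (he_init) {
      matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
    } else {  # Glorot uniform
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    }
    bn <- NULL
    if (batch_norm && l < length(layers)) {
      bn <- list(gamma = rep(1, fan_out), beta = rep(0, fan_out),
                 rmean = NULL, rvar = NULL)
    }
    layers[[l]] <- list(W = W, b = rep(0, fan_out), act = acts[l], bn = bn,
                        dropout = if (l < length(layers)) dropout else 0)
  }
  structure(list(layers = layers, sizes = sizes), class = "plasmatch_mlp")
}

bn_eps <- 1e-5

mlp_forward <- function(net, X, training = FALSE, rng_dropout = TRUE) {
  H <- X
  cache <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    S <- H %*% ly$W + rep(ly$b, each = nrow(H))
    bn_cache <- NULL
    if (!is.null(ly$bn)) {
      if (training) {
        mu <- colMeans(S)
        v <- pmax(colMeans(S^2) - mu^2, 0)
        Shat <- (S - rep(mu, each = nrow(S))) /
          rep(sqrt(v + bn_eps), each = nrow(S))
        bn_cache <- list(mu = mu, v = v, Shat = Shat)
      } else {
        mu <- if (is.null(ly$bn$rmean)) rep(0, ncol(S)) else ly$bn$rmean
        v <- if (is.null(ly$bn$rvar)) rep(1, ncol(S)) else ly$bn$rvar
        Shat <- (S - rep(mu, each = nrow(S))) /
          rep(sqrt(v + bn_eps), each = nrow(S))
      }
      Tm <- Shat * rep(ly$bn$gamma, each = nrow(S)) +
        rep(ly$bn$beta, each = nrow(S))
    } else Tm <- S
    A <- act_fun(Tm, ly$act)
    mask <- NULL
    if (training && ly$dropout > 0) {
      if (rng_dropout) {
        mask <- matrix(runif(length(A)) >= ly$dropout, nrow(A), ncol(A))
      } else mask <- matrix(TRUE, nrow(A), ncol(A))
      A <- A * mask / (1 - ly$dropout)
    }
    cache[[l]] <- list(H = H, S = S, Tm = Tm, A = A, bn = bn_cache,
                       mask = mask)
    H <- A
  }
  list(out = H, cache = cache)
}

# Backward pass; dOut is dLoss/dOutputActivation unless loss_fused, in which
# case it is already dLoss/dZ of the final layer (sigmoid+BCE shortcut).
mlp_backward <- function(net, fw, dOut, l2, loss_fused = FALSE) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cc <- fw$cache[[l]]
    n_b <- nrow(cc$H)
    if (!is.null(cc$mask)) dA <- dA * cc$mask / (1 - ly$dropout)
    if (l == length(net$layers) && loss_fused) {
      dT <- dA
    } else {
      dT <- switch(ly$act,
                   relu = dA * (cc$Tm > 0),
                   sigmoid = dA * act_fun(cc$Tm, "sigmoid") *
                     (1 - act_fun(cc$Tm, "sigmoid")),
                   linear = dA)
    }
    dgamma <- dbeta <- NULL
    if (!is.null(ly$bn)) {
      bc <- cc$bn
      dgamma <- colSums(dT * bc$Shat)
      dbeta <- colSums(dT)
      dShat <- dT * rep(ly$bn$gamma, each = n_b)
      inv_sd <- 1 / sqrt(bc$v + bn_eps)
      dS <- (dShat - rep(colMeans(dShat), each = n_b) -
               bc$Shat * rep(colMeans(dShat * bc$Shat), each = n_b)) *
        rep(inv_sd, each = n_b)
    } else dS <- dT
    grads[[l]] <- list(W = crossprod(cc$H, dS) + 2 * l2 * ly$W,
                       b = colSums(dS), gamma = dgamma, beta = dbeta)
    dA <- dS %*% t(ly$W)
  }
  grads
}

mlp_loss <- function(out, Y, loss) {
  if (loss == "bce") {
    p <- pmin(pmax(out, 1e-12), 1 - 1e-12)
    -mean(Y * log(p) + (1 - Y) * log(1 - p))
  } else mean((out - Y)^2)
}

# One Adam step over all layer parameters.
adam_step <- function(net, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(net$layers)) {
    for (par in c("W", "b", "gamma", "beta")) {
      g <- grads[[l]][[par]]
      if (is.null(g)) next
      key <- paste0(l, ".", par)
      st <- state[[key]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (par %in% c("W", "b")) {
        net$layers[[l]][[par]] <- net$layers[[l]][[par]] - upd
      } else {
        net$layers[[l]]$bn[[par]] <- net$layers[[l]]$bn[[par]] - upd
      }
      state[[key]] <- st
    }
  }
  list(net = net, state = state)
}

mlp_train <- function(X, Y, hidden, out_act, loss,
                      dropout = 0, l2 = 0, batch_norm = FALSE,
                      he_init = FALSE, epochs = 50L, batch_size = 64L,
                      lr = 1e-3, seed = 1L, bn_momentum = 0.9,
                      hidden_acts = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  sizes <- c(ncol(X), hidden, ncol(Y))
  if (is.null(hidden_acts)) hidden_acts <- rep("relu", length(hidden))
  acts <- c(hidden_acts, out_act)
  with_seed(seed, {
    net <- mlp_init(sizes, acts, batch_norm, he_init, dropout)
    state <- list()
    t <- 0L
    trajectory <- numeric(epochs)
    n <- nrow(X)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        if (length(idx) < 2L) next
        Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
        fw <- mlp_forward(net, Xb, training = TRUE)
        # update batch-norm running statistics
        for (l in seq_along(net$layers)) {
          bc <- fw$cache[[l]]$bn
          if (is.null(bc)) next
          bn <- net$layers[[l]]$bn
          if (is.null(bn$rmean)) {
            bn$rmean <- bc$mu; bn$rvar <- bc$v
          } else {
            bn$rmean <- bn_momentum * bn$rmean + (1 - bn_momentum) * bc$mu
            bn$rvar <- bn_momentum * bn$rvar + (1 - bn_momentum) * bc$v
          }
          net$layers[[l]]$bn <- bn
        }
        if (loss == "bce") {
          dZ <- (fw$out - Yb) / nrow(Xb)
          grads <- mlp_backward(net, fw, dZ, l2, loss_fused = TRUE)
        } else {
          dOut <- 2 * (fw$out - Yb) / length(Yb)
          grads <- mlp_backward(net, fw, dOut, l2, loss_fused = FALSE)
        }
        t <- t + 1L
        st <- adam_step(net, grads, state, lr, t)
        net <- st$net; state <- st$state
        ep_loss <- ep_loss + mlp_loss(fw$out, Yb, loss)
        n_batches <- n_batches + 1L
      }
      trajectory[ep] <- ep_loss / max(n_batches, 1L)
    }
    net$trajectory <- trajectory
    net
  })
}

# Inference-mode forward; layer = index to stop at (e.g. the bottleneck),
# NULL for the full network output.
mlp_predict <- function(net, X, layer = NULL) {
  H <- as.matrix(X)
  upto <- if (is.null(layer)) length(net$layers) else layer
  for (l in seq_len(upto)) {
    ly <- net$layers[[l]]
    S <- H %*% ly$W + rep(ly$b, each = nrow(H))
    if (!is.null(ly$bn)) {
      mu <- if (is.null(ly$bn$rmean)) rep(0, ncol(S)) else ly$bn$rmean
      v <- if (is.null(ly$bn$rvar)) rep(1, ncol(S)) else ly$bn$rvar
      S <- ((S - rep(mu, each = nrow(S))) /
              rep(sqrt(v + bn_eps), each = nrow(S))) *
        rep(ly$bn$gamma, each = nrow(S)) + rep(ly$bn$beta, each = nrow(S))
    }
    H <- act_fun(S, ly$act)
  }
  H
}
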