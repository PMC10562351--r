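# Multilayer perceptron with closed-form gradients.
#
# Architecture: input -> rectifier hidden layers -> sigmoid output, binary
# cross-entropy loss, Adam updates. Implemented in-package (plain matrix
# algebra) so that federated averaging, gradient checks and K=1 equivalence
# can be asserted bit-for-bit rather than through an opaque backend.
# A weight set is a flat named list of arrays (W1, b1, W2, b2, ...), the
# unit exchanged by FedAvg.

#' MLP architecture specification
#'
#' @param input_dim number of input features (registry length).
#' @param hidden integer vector of hidden-layer widths.
#' @return an `mlp_spec` with the full layer-width sequence.
#' @export
mlp_spec <- function(input_dim, hidden = c(64, 32)) {
  widths <- c(input_dim, hidden, 1L)
  structure(list(widths = as.integer(widths)), class = "mlp_spec")
}

#' Initialize an MLP weight set
#'
#' He-scaled normal initialization for rectifier layers, deterministic under
#' the seed.
#'
#' @param spec an [mlp_spec()].
#' @param seed integer seed.
#' @return named list `W1, b1, W2, b2, ...`; `Wl` has shape
#'   `(n_out, n_in)`.
#' @export
init_weights <- function(spec, seed = 1L) {
  w <- spec$widths
  with_seed(seed, {
    out <- list()
    for (l in seq_len(length(w) - 1L)) {
      fan_in <- w[l]
      sc <- sqrt(2 / fan_in)
      out[[paste0("W", l)]] <- matrix(rnorm(w[l + 1] * fan_in, 0, sc),
                                      w[l + 1], fan_in)
      out[[paste0("b", l)]] <- numeric(w[l + 1])
    }
    out
  })
}

n_layers <- function(weights) length(weights) / 2L

# Forward pass; returns activations for backprop.
nn_forward <- function(weights, X) {
  L <- n_layers(weights)
  A <- list(t(X))  # (d, n)
  for (l in seq_len(L)) {
    Z <- weights[[paste0("W", l)]] %*% A[[l]] + weights[[paste0("b", l)]]
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  A
}

#' Predict event probabilities with an MLP weight set
#' @param weights a weight set from [init_weights()] / [local_train()]; if it
#'   carries a `scaler` attribute (see [nn_fit()]) inputs are standardized
#'   with it first.
#' @param X numeric matrix (rows = observations).
#' @return numeric vector of probabilities.
#' @export
nn_predict <- function(weights, X) {
  X <- as.matrix(X)
  sc <- attr(weights, "scaler")
  if (!is.null(sc)) X <- scale_apply(sc, X)
  A <- nn_forward(weights, X)
  as.numeric(A[[length(A)]])
}

# Column z-scoring with training-set moments (constant columns untouched).
scale_fit <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

scale_apply <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

# Mean binary cross-entropy.
nn_loss <- function(weights, X, y, eps = 1e-12) {
  p <- nn_predict(weights, X)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Analytic gradient of mean BCE w.r.t. every parameter array.
nn_grad <- function(weights, X, y) {
  L <- n_layers(weights)
  n <- nrow(X)
  A <- nn_forward(weights, X)
  grads <- vector("list", length(weights))
  names(grads) <- names(weights)
  delta <- (A[[L + 1L]] - matrix(y, 1L, n)) / n  # (1, n)
  for (l in L:1) {
    grads[[paste0("W", l)]] <- delta %*% t(A[[l]])
    grads[[paste0("b", l)]] <- rowSums(delta)
    if (l > 1L) {
      delta <- (t(weights[[paste0("W", l)]]) %*% delta) * (A[[l]] > 0)
    }
  }
  grads
}

adam_init <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0),
       t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(weights = weights, state = state)
}

# One seeded epoch of mini-batch Adam. The shuffle is a pure function of
# `epoch_seed` so identical (data, seed) trajectories are bit-identical.
nn_epoch <- function(weights, state, X, y, batch_size, lr, epoch_seed) {
  n <- nrow(X)
  perm <- with_seed(epoch_seed, sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- perm[s:min(s + batch_size - 1L, n)]
    g <- nn_grad(weights, X[idx, , drop = FALSE], y[idx])
    upd <- adam_step(weights, g, state, lr)
    weights <- upd$weights
    state <- upd$state
  }
  list(weights = weights, state = state)
}

#' One site's local training pass (E epochs of mini-batch Adam)
#'
#' @param weights starting weight set (the broadcast global model).
#' @param X,y local training data (imputed matrix, 0/1 labels).
#' @param epochs number of local epochs E (0 returns `weights` unchanged).
#' @param batch_size mini-batch size B (last batch may be smaller).
#' @param learning_rate Adam learning rate.
#' @param seed base seed; the shuffle of global epoch `epoch_offset + e` is
#'   derived from it, so a federated schedule and an equivalent plain
#'   schedule visit identical batch sequences.
#' @param epoch_offset index of the last global epoch already consumed
#'   (round r of an E-epoch schedule passes `(r-1) * E`).
#' @param state optional Adam state carried across rounds; fresh if `NULL`.
#' @return list `(weights, state)`.
#' @export
local_train <- function(weights, X, y, epochs = 2L, batch_size = 32L,
                        learning_rate = 1e-2, seed = 1L, epoch_offset = 0L,
                        state = NULL) {
  if (!nrow(X)) stopf("local training data is empty")
  if (anyNA(X)) stopf("training data must be imputed (no NA)")
  if (is.null(state)) state <- adam_init(weights)
  if (epochs >= 1L) {
    for (e in seq_len(epochs)) {
      upd <- nn_epoch(weights, state, X, y, batch_size, learning_rate,
                      derive_seed(seed, 977L, epoch_offset + e))
      weights <- upd$weights
      state <- upd$state
    }
  }
  list(weights = weights, state = state)
}

#' Plain (non-federated) MLP training
#'
#' Identical machinery to the federated path: `epochs` seeded epochs of
#' mini-batch Adam from a He initialization. A K=1 federated run with
#' persistent optimizer state reproduces this trajectory exactly.
#'
#' @inheritParams local_train
#' @param hidden hidden-layer widths.
#' @param standardize z-score the inputs with training-set moments (stored
#'   with the weights and re-applied by [nn_predict()]). Disable when the
#'   caller already standardizes, e.g. the federated path, where scaling is
#'   site-local preprocessing.
#' @param validation_fraction fraction of the data held out (stratified) to
#'   pick the best epoch by validation AUROC; 0 disables epoch selection and
#'   returns the final-epoch weights (the federated-equivalence setting).
#' @return the trained weight set (attributes `spec` and optionally
#'   `scaler`).
#' @export
nn_fit <- function(X, y, hidden = c(64, 32), epochs = 40L, batch_size = 32L,
                   learning_rate = 1e-2, seed = 1L, standardize = TRUE,
                   validation_fraction = 0.15) {
  if (length(unique(y)) < 2L) stopf("training labels contain a single class")
  X <- as.matrix(X)
  y <- as.integer(y)
  scaler <- NULL
  if (standardize) {
    scaler <- scale_fit(X)
    X <- scale_apply(scaler, X)
  }
  # epoch selection: hold out a stratified slice and keep the epoch with the
  # best validation AUROC (the non-federated analogue of round selection)
  vi <- integer(0)
  if (validation_fraction > 0) {
    vi <- with_seed(derive_seed(seed, 613L), {
      unlist(lapply(unique(y), function(cls) {
        idx <- which(y == cls)
        sample(idx, max(1L, round(validation_fraction * length(idx))))
      }))
    })
  }
  tr <- setdiff(seq_along(y), vi)
  use_val <- length(vi) > 0 && length(unique(y[vi])) == 2L &&
    length(unique(y[tr])) == 2L
  if (!use_val) tr <- seq_along(y)
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]
  spec <- mlp_spec(ncol(X), hidden)
  weights <- init_weights(spec, derive_seed(seed, 311L))
  state <- adam_init(weights)
  best <- list(auroc = -Inf, weights = weights, epoch = 0L)
  for (e in seq_len(epochs)) {
    upd <- nn_epoch(weights, state, Xtr, ytr, batch_size, learning_rate,
                    derive_seed(seed, 977L, e))
    weights <- upd$weights
    state <- upd$state
    if (use_val) {
      va <- auroc(nn_predict(weights, X[vi, , drop = FALSE]), y[vi])
      if (va > best$auroc) best <- list(auroc = va, weights = weights,
                                        epoch = e)
    }
  }
  if (use_val) {
    out <- best$weights
    attr(out, "best_epoch") <- best$epoch
  } else {
    out <- weights
  }
  attr(out, "spec") <- spec
  attr(out, "scaler") <- scaler
  out
}
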