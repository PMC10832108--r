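# Low-level neural-network primitives.
#
# All layers operate on row-major batches: a matrix X of shape (rows x dim)
# where each row is one token position (or one example). Every *_fwd
# returns what the matching *_bwd needs; gradients are exact analytic
# derivatives and are verified against finite differences in the test
# suite. Everything is double precision.

LN_EPS <- 1e-12
INIT_SD <- 0.02

# truncated normal init at +/- 2 sd, the convention of BERT-family models
init_weights <- function(n, sd = INIT_SD) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

init_matrix <- function(nr, nc, sd = INIT_SD) {
  matrix(init_weights(nr * nc, sd), nr, nc)
}

linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y + rep(b, each = nrow(Y))
}

# returns list(dX, dW, db)
linear_bwd <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# exact GeLU: x * Phi(x). Phi(X) is cached by the forward pass so the
# backward pass pays for one density evaluation only.
gelu_fwd <- function(X, want_cache = FALSE) {
  P <- stats::pnorm(X)
  if (want_cache) list(Y = X * P, P = P) else X * P
}

gelu_bwd <- function(dY, X, P = stats::pnorm(X)) {
  dY * (P + X * stats::dnorm(X))
}

# Row-wise layer normalization with learnable gain/bias.
layernorm_fwd <- function(X, gamma, beta, eps = LN_EPS) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv_std <- 1 / sqrt(v + eps)
  xhat <- xc * inv_std
  n <- nrow(X)
  Y <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(Y = Y, xhat = xhat, inv_std = inv_std)
}

# dY -> list(dX, dgamma, dbeta); cache from layernorm_fwd
layernorm_bwd <- function(dY, cache, gamma) {
  xhat <- cache$xhat
  inv_std <- cache$inv_std
  H <- ncol(xhat)
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = nrow(dY))
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * xhat)
  dX <- (dxhat - s1 / H - xhat * (s2 / H)) * inv_std
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; mask is returned so the backward pass reuses it.
dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(Y = X, mask = NULL))
  }
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

# numerically stable sigmoid / softplus
sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

# mean binary cross-entropy on logits; returns loss and dlogit
bce_with_logits <- function(logits, labels) {
  n <- length(logits)
  loss <- mean(softplus(logits) - labels * logits)
  grad <- (sigmoid(logits) - labels) / n
  list(loss = loss, grad = grad)
}

# ---- parameter trees -------------------------------------------------------
#
# Parameters live in nested named lists whose leaves are numeric vectors or
# matrices. These helpers walk two trees in lockstep (for AdamW updates and
# gradient accumulation) while preserving shapes.

param_tree_map <- function(f, ...) {
  trees <- list(...)
  first <- trees[[1]]
  if (is.list(first)) {
    out <- purrr::map(seq_along(first), function(i) {
      do.call(param_tree_map, c(list(f), purrr::map(trees, i)))
    })
    names(out) <- names(first)
    out
  } else {
    do.call(f, trees)
  }
}

param_tree_zeros <- function(params) {
  param_tree_map(function(x) x * 0, params)
}

param_tree_count <- function(params) {
  total <- 0
  walk <- function(x) {
    if (is.list(x)) purrr::walk(x, walk) else total <<- total + length(x)
  }
  walk(params)
  total
}

param_tree_add <- function(a, b) param_tree_map(`+`, a, b)

# deterministic digest of a parameter tree (used to prove teacher freezing)
param_tree_digest <- function(params) {
  rlang::hash(param_tree_map(function(x) round(unclass(x), 12), params))
}

# ---- AdamW -----------------------------------------------------------------

adamw_state <- function(params) {
  list(m = param_tree_zeros(params), v = param_tree_zeros(params), t = 0L)
}

# Decoupled weight decay; `decay_mask` mirrors the parameter tree with 1
# where decay applies (weight matrices) and 0 where it does not (biases,
# layer-norm parameters, the gate scalar).
adamw_step <- function(params, grads, state, lr, weight_decay = 0.01,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       decay_mask = NULL) {
  state$t <- state$t + 1L
  state$m <- param_tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                            state$m, grads)
  state$v <- param_tree_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                            state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  if (is.null(decay_mask)) {
    params <- param_tree_map(function(p, m, v) {
      p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * p)
    }, params, state$m, state$v)
  } else {
    params <- param_tree_map(function(p, m, v, d) {
      p - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + weight_decay * d * p)
    }, params, state$m, state$v, decay_mask)
  }
  list(params = params, state = state)
}

# mask helper: 1 for matrices (weights), 0 for vectors/scalars
default_decay_mask <- function(params) {
  param_tree_map(function(x) if (is.matrix(x)) x * 0 + 1 else x * 0, params)
}

# Cosine-annealed learning rate over `total` epochs, floor 0, no restarts:
# full rate at epoch 1, decaying along a half cosine.
cosine_lr <- function(base_lr, epoch, total) {
  base_lr * 0.5 * (1 + cos(pi * (epoch - 1) / total))
}
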