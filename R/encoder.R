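#' Configuration of a BERT-style transformer encoder
#'
#' Captures every architectural quantity needed to instantiate an encoder
#' and to count its trainable parameters in closed form: token/position/
#' segment embedding sizes, the number of post-norm transformer blocks,
#' attention heads, feed-forward width, and whether a pooler head (dense +
#' tanh over the class token) is attached.
#'
#' @param n_layers Number of transformer blocks.
#' @param n_heads Attention heads; must divide `hidden_dim`.
#' @param hidden_dim Model width.
#' @param intermediate_dim Feed-forward inner width.
#' @param vocab_size Token vocabulary size.
#' @param max_positions Length of the learned absolute position table.
#' @param type_vocab Segment-embedding vocabulary (default 2, the BERT
#'   convention; only segment 0 is ever used here).
#' @param dropout Dropout proportion applied after attention and
#'   feed-forward sublayers and on embeddings.
#' @param has_pooler Whether a pooler (dense + tanh on CLS) is included.
#' @return An `encoder_config` object.
#' @examples
#' cfg <- encoder_config(2, 2, 32, 64, vocab_size = 30, max_positions = 64)
#' count_parameters(cfg)
#' @export
encoder_config <- function(n_layers, n_heads, hidden_dim, intermediate_dim,
                           vocab_size, max_positions, type_vocab = 2L,
                           dropout = 0.1, has_pooler = FALSE) {
  dims <- c(n_layers = n_layers, n_heads = n_heads, hidden_dim = hidden_dim,
            intermediate_dim = intermediate_dim, vocab_size = vocab_size,
            max_positions = max_positions, type_vocab = type_vocab)
  if (any(dims <= 0) || any(dims != as.integer(dims))) {
    rlang::abort("all encoder dimensions must be positive integers")
  }
  if (hidden_dim %% n_heads != 0) {
    rlang::abort("hidden_dim must be divisible by n_heads")
  }
  if (dropout < 0 || dropout >= 1) rlang::abort("dropout must be in [0, 1)")
  structure(
    list(
      n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
      hidden_dim = as.integer(hidden_dim),
      intermediate_dim = as.integer(intermediate_dim),
      vocab_size = as.integer(vocab_size),
      max_positions = as.integer(max_positions),
      type_vocab = as.integer(type_vocab),
      dropout = dropout, has_pooler = isTRUE(has_pooler)
    ),
    class = "encoder_config"
  )
}

#' @export
print.encoder_config <- function(x, ...) {
  cat("<encoder_config> ", x$n_layers, " layers, ", x$n_heads, " heads, ",
      "hidden ", x$hidden_dim, ", ff ", x$intermediate_dim,
      ", vocab ", x$vocab_size, ", positions ", x$max_positions,
      if (x$has_pooler) ", pooler" else "", "\n", sep = "")
  invisible(x)
}

#' Reference encoder configurations for the target branch
#'
#' `student_encoder_config()` is the compact trainable protein encoder:
#' two post-norm layers otherwise matching the teacher's width (16 heads,
#' hidden 1024, feed-forward 4096, vocabulary 30). Its position table spans
#' the 545-token maximum target length and it carries no pooler, giving
#' 25,785,344 trainable parameters (26 M rounded). `teacher_encoder_config()`
#' describes the 30-layer frozen teacher protein language model with its
#' 40,000-position table and pooler: 419,931,136 parameters (420 M rounded).
#'
#' @param max_positions Position-table length for the student (default 545).
#' @return An `encoder_config`.
#' @export
student_encoder_config <- function(max_positions = 545L) {
  encoder_config(
    n_layers = 2L, n_heads = 16L, hidden_dim = 1024L,
    intermediate_dim = 4096L, vocab_size = 30L,
    max_positions = max_positions, has_pooler = FALSE
  )
}

#' @rdname student_encoder_config
#' @export
teacher_encoder_config <- function() {
  encoder_config(
    n_layers = 30L, n_heads = 16L, hidden_dim = 1024L,
    intermediate_dim = 4096L, vocab_size = 30L,
    max_positions = 40000L, has_pooler = TRUE
  )
}

#' Count trainable parameters
#'
#' Closed-form summation over all weight shapes of the architecture
#' described by a config: embeddings (token + position + segment + their
#' layer norm), per-layer attention (Q/K/V/output projections with biases,
#' post-attention layer norm), feed-forward (two affine maps, post-FFN
#' layer norm) and the optional pooler. Agrees exactly with enumerating the
#' weights of an instantiated encoder.
#'
#' @param x An `encoder_config`, `head_spec`, or built model object.
#' @param ... Unused.
#' @return Integer (double for counts beyond 32-bit range).
#' @export
count_parameters <- function(x, ...) UseMethod("count_parameters")

#' @export
count_parameters.encoder_config <- function(x, ...) {
  h <- as.numeric(x$hidden_dim)
  i <- as.numeric(x$intermediate_dim)
  emb <- x$vocab_size * h + x$max_positions * h + x$type_vocab * h + 2 * h
  attn <- 3 * (h * h + h) + (h * h + h) + 2 * h
  ffn <- (h * i + i) + (i * h + h) + 2 * h
  per_layer <- attn + ffn
  total <- emb + x$n_layers * per_layer
  if (x$has_pooler) total <- total + h * h + h
  total
}

#' @export
count_parameters.encoder <- function(x, ...) {
  param_tree_count(x$params)
}

# ---- construction ----------------------------------------------------------

init_layer_params <- function(h, i) {
  list(
    Wq = init_matrix(h, h), bq = numeric(h),
    Wk = init_matrix(h, h), bk = numeric(h),
    Wv = init_matrix(h, h), bv = numeric(h),
    Wo = init_matrix(h, h), bo = numeric(h),
    ln1_gamma = rep(1, h), ln1_beta = numeric(h),
    W1 = init_matrix(h, i), b1 = numeric(i),
    W2 = init_matrix(i, h), b2 = numeric(h),
    ln2_gamma = rep(1, h), ln2_beta = numeric(h)
  )
}

#' Build a transformer encoder
#'
#' Instantiates the architecture of an [encoder_config()]: token, learned
#' absolute position and segment embeddings followed by an embedding layer
#' norm, then post-norm transformer blocks (multi-head self-attention with
#' per-head width `hidden_dim / n_heads`, GeLU feed-forward), and an
#' optional pooler. Weights are drawn from a truncated normal (sd 0.02,
#' clipped at two standard deviations) under the seed; layer-norm gains
#' start at one and all biases at zero.
#'
#' @param config An `encoder_config`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `encoder` holding `config` and `params`.
#' @export
build_encoder <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  h <- config$hidden_dim
  params <- withr::with_seed(seed, {
    p <- list(
      tok_emb = init_matrix(config$vocab_size, h),
      pos_emb = init_matrix(config$max_positions, h),
      type_emb = init_matrix(config$type_vocab, h),
      emb_ln_gamma = rep(1, h), emb_ln_beta = numeric(h),
      layers = purrr::map(seq_len(config$n_layers), function(l) {
        init_layer_params(h, config$intermediate_dim)
      })
    )
    if (config$has_pooler) {
      p$pooler_W <- init_matrix(h, h)
      p$pooler_b <- numeric(h)
    }
    p
  })
  structure(list(config = config, params = params), class = "encoder")
}

#' @export
print.encoder <- function(x, ...) {
  cat("<encoder> ", format(count_parameters(x$config), big.mark = ","),
      " parameters\n", sep = "")
  print(x$config)
  invisible(x)
}

# ---- forward / backward ----------------------------------------------------
#
# Batched forward over an ids matrix (B x L) with an attention mask of the
# same shape. Token rows are flattened sequence-major into a (B*L x h)
# matrix; position-wise sublayers run on the flat matrix, attention loops
# over sequences and heads. Padded key positions receive a -1e30 additive
# mask, which zeroes their softmax weight exactly, so the class-token
# output is invariant to padding length.

ATTN_MASK_NEG <- -1e30

encoder_forward <- function(enc, ids, mask, training = FALSE,
                            want_cache = FALSE) {
  cfg <- enc$config
  p <- enc$params
  if (is.null(dim(ids))) {
    ids <- matrix(ids, nrow = 1)
    mask <- matrix(mask, nrow = 1)
  }
  B <- nrow(ids); L <- ncol(ids)
  if (L > cfg$max_positions) {
    rlang::abort("input longer than the encoder position table; truncate first")
  }
  if (any(ids > cfg$vocab_size | ids < 1)) {
    rlang::abort("token id outside the encoder vocabulary")
  }
  h <- cfg$hidden_dim
  nh <- cfg$n_heads
  dh <- h / nh
  flat_ids <- as.vector(t(ids))
  pos_idx <- rep(seq_len(L), B)
  X0 <- p$tok_emb[flat_ids, , drop = FALSE] +
    p$pos_emb[pos_idx, , drop = FALSE] +
    rep(p$type_emb[1, ], each = B * L)
  emb_ln <- layernorm_fwd(X0, p$emb_ln_gamma, p$emb_ln_beta)
  emb_drop <- dropout_fwd(emb_ln$Y, cfg$dropout, training)
  X <- emb_drop$Y

  row_of <- function(b) ((b - 1L) * L + 1L):(b * L)
  head_cols <- purrr::map(seq_len(nh), function(k) ((k - 1L) * dh + 1L):(k * dh))
  scale <- 1 / sqrt(dh)

  layer_caches <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    lp <- p$layers[[l]]
    X_in <- X
    Q <- linear_fwd(X_in, lp$Wq, lp$bq)
    K <- linear_fwd(X_in, lp$Wk, lp$bk)
    V <- linear_fwd(X_in, lp$Wv, lp$bv)
    Ctx <- matrix(0, B * L, h)
    P_all <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- row_of(b)
      key_mask <- (1 - mask[b, ]) * ATTN_MASK_NEG
      Pb <- vector("list", nh)
      for (k in seq_len(nh)) {
        ch <- head_cols[[k]]
        S <- tcrossprod(Q[rb, ch, drop = FALSE], K[rb, ch, drop = FALSE]) * scale
        S <- S + rep(key_mask, each = L)
        S <- S - S[cbind(seq_len(L), max.col(S, ties.method = "first"))]
        E <- exp(S)
        P <- E / rowSums(E)
        Ctx[rb, ch] <- P %*% V[rb, ch, drop = FALSE]
        Pb[[k]] <- P
      }
      P_all[[b]] <- Pb
    }
    O <- linear_fwd(Ctx, lp$Wo, lp$bo)
    o_drop <- dropout_fwd(O, cfg$dropout, training)
    R1 <- X_in + o_drop$Y
    ln1 <- layernorm_fwd(R1, lp$ln1_gamma, lp$ln1_beta)
    X1 <- ln1$Y
    H1 <- linear_fwd(X1, lp$W1, lp$b1)
    gel <- gelu_fwd(H1, want_cache = TRUE)
    G <- gel$Y
    H2 <- linear_fwd(G, lp$W2, lp$b2)
    f_drop <- dropout_fwd(H2, cfg$dropout, training)
    R2 <- X1 + f_drop$Y
    ln2 <- layernorm_fwd(R2, lp$ln2_gamma, lp$ln2_beta)
    X <- ln2$Y
    if (want_cache) {
      layer_caches[[l]] <- list(
        X_in = X_in, Q = Q, K = K, V = V, P_all = P_all, Ctx = Ctx,
        o_mask = o_drop$mask, ln1 = ln1, X1 = X1, H1 = H1, G = G,
        gelu_P = gel$P, f_mask = f_drop$mask, ln2 = ln2
      )
    }
  }
  cls_rows <- seq(1L, B * L, by = L)
  out <- list(
    hidden = X,
    cls = X[cls_rows, , drop = FALSE],
    B = B, L = L
  )
  if (want_cache) {
    out$cache <- list(
      flat_ids = flat_ids, pos_idx = pos_idx, emb_ln = emb_ln,
      emb_mask = emb_drop$mask, layers = layer_caches, mask = mask,
      head_cols = head_cols, scale = scale, row_of = row_of
    )
  }
  out
}

# dHidden: gradient w.r.t. final hidden states, (B*L x h). Returns
# list(grads = parameter-tree gradient). Gradients to embeddings are
# scatter-added with rowsum().
encoder_backward <- function(enc, fwd, dHidden) {
  cfg <- enc$config
  p <- enc$params
  cache <- fwd$cache
  B <- fwd$B; L <- fwd$L
  h <- cfg$hidden_dim
  nh <- cfg$n_heads
  row_of <- cache$row_of
  head_cols <- cache$head_cols
  scale <- cache$scale

  g <- list(
    tok_emb = matrix(0, cfg$vocab_size, h),
    pos_emb = matrix(0, cfg$max_positions, h),
    type_emb = matrix(0, cfg$type_vocab, h),
    emb_ln_gamma = numeric(h), emb_ln_beta = numeric(h),
    layers = vector("list", cfg$n_layers)
  )
  if (cfg$has_pooler) {
    g$pooler_W <- matrix(0, h, h)
    g$pooler_b <- numeric(h)
  }

  dX <- dHidden
  for (l in rev(seq_len(cfg$n_layers))) {
    lp <- p$layers[[l]]
    lc <- cache$layers[[l]]
    ln2b <- layernorm_bwd(dX, lc$ln2, lp$ln2_gamma)
    dR2 <- ln2b$dX
    dH2 <- dropout_bwd(dR2, lc$f_mask)
    lb2 <- linear_bwd(dH2, lc$G, lp$W2)
    dG <- lb2$dX
    dH1 <- gelu_bwd(dG, lc$H1, lc$gelu_P)
    lb1 <- linear_bwd(dH1, lc$X1, lp$W1)
    dX1 <- dR2 + lb1$dX
    ln1b <- layernorm_bwd(dX1, lc$ln1, lp$ln1_gamma)
    dR1 <- ln1b$dX
    dO <- dropout_bwd(dR1, lc$o_mask)
    lbo <- linear_bwd(dO, lc$Ctx, lp$Wo)
    dCtx <- lbo$dX
    dQ <- matrix(0, B * L, h)
    dK <- matrix(0, B * L, h)
    dV <- matrix(0, B * L, h)
    for (b in seq_len(B)) {
      rb <- row_of(b)
      for (k in seq_len(nh)) {
        ch <- head_cols[[k]]
        P <- lc$P_all[[b]][[k]]
        dCb <- dCtx[rb, ch, drop = FALSE]
        dP <- tcrossprod(dCb, lc$V[rb, ch, drop = FALSE])
        dV[rb, ch] <- dV[rb, ch] + crossprod(P, dCb)
        dS <- P * (dP - rowSums(dP * P))
        dQ[rb, ch] <- dQ[rb, ch] + dS %*% lc$K[rb, ch, drop = FALSE] * scale
        dK[rb, ch] <- dK[rb, ch] + crossprod(dS, lc$Q[rb, ch, drop = FALSE]) * scale
      }
    }
    lbq <- linear_bwd(dQ, lc$X_in, lp$Wq)
    lbk <- linear_bwd(dK, lc$X_in, lp$Wk)
    lbv <- linear_bwd(dV, lc$X_in, lp$Wv)
    g$layers[[l]] <- list(
      Wq = lbq$dW, bq = lbq$db, Wk = lbk$dW, bk = lbk$db,
      Wv = lbv$dW, bv = lbv$db, Wo = lbo$dW, bo = lbo$db,
      ln1_gamma = ln1b$dgamma, ln1_beta = ln1b$dbeta,
      W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db,
      ln2_gamma = ln2b$dgamma, ln2_beta = ln2b$dbeta
    )
    dX <- dR1 + lbq$dX + lbk$dX + lbv$dX
  }
  demb <- dropout_bwd(dX, cache$emb_mask)
  embb <- layernorm_bwd(demb, cache$emb_ln, p$emb_ln_gamma)
  g$emb_ln_gamma <- embb$dgamma
  g$emb_ln_beta <- embb$dbeta
  dX0 <- embb$dX
  tok_sums <- rowsum(dX0, group = cache$flat_ids)
  g$tok_emb[as.integer(rownames(tok_sums)), ] <- tok_sums
  pos_sums <- rowsum(dX0, group = cache$pos_idx)
  g$pos_emb[as.integer(rownames(pos_sums)), ] <- pos_sums
  g$type_emb[1, ] <- colSums(dX0)
  list(grads = g)
}

# ---- class-token extraction ------------------------------------------------

#' Extract the class-token feature of the last hidden layer
#'
#' Runs the encoder forward in evaluation mode (no dropout) and returns the
#' final-layer hidden state at position 0 (the CLS slot). Padded positions
#' are masked out of attention, so the result does not depend on how much
#' padding follows the sequence.
#'
#' @param encoder An `encoder` (or a mock teacher from
#'   [make_mock_teacher()]).
#' @param tokens A `token_seq`, or a list of them for a batch.
#' @param ... Unused.
#' @return A numeric vector of length `hidden_dim` (single input) or a
#'   matrix with one row per input.
#' @export
encode_cls <- function(encoder, tokens, ...) UseMethod("encode_cls")

#' @export
encode_cls.encoder <- function(encoder, tokens, ...) {
  batch <- token_batch(tokens)
  out <- encoder_forward(encoder, batch$ids, batch$mask, training = FALSE)
  if (batch$single) drop(out$cls) else out$cls
}

# normalize token_seq / list-of-token_seq / ids+mask matrices to a batch
token_batch <- function(tokens) {
  if (inherits(tokens, "token_seq")) {
    list(ids = matrix(tokens$token_ids, nrow = 1),
         mask = matrix(tokens$attention_mask, nrow = 1), single = TRUE)
  } else if (is.list(tokens) && all(purrr::map_lgl(tokens, inherits, "token_seq"))) {
    list(ids = do.call(rbind, purrr::map(tokens, "token_ids")),
         mask = do.call(rbind, purrr::map(tokens, "attention_mask")),
         single = FALSE)
  } else {
    rlang::abort("tokens must be a token_seq or a list of token_seq")
  }
}

# ---- projections -----------------------------------------------------------

#' Layer-norm + affine projection
#'
#' The dimension-aligning projections applied to class tokens: a layer
#' normalization over the input dimension followed by an affine map to the
#' output dimension. `identity = TRUE` is a test hook that bypasses the
#' layer norm and uses a (rectangular) identity weight with zero bias, so
#' the projection returns its input (truncated or zero-padded when the
#' dimensions differ).
#'
#' @param input_dim,output_dim Dimensions of the affine map.
#' @param seed Seed for weight initialization.
#' @param identity Identity-mode test hook.
#' @param use_ln Whether the layer norm is applied (default TRUE).
#' @return A `projection_spec`.
#' @export
projection_spec <- function(input_dim, output_dim, seed = 1L,
                            identity = FALSE, use_ln = !identity) {
  W <- if (identity) {
    diag(1, input_dim, output_dim)
  } else {
    withr::with_seed(seed, init_matrix(input_dim, output_dim))
  }
  structure(
    list(
      input_dim = as.integer(input_dim), output_dim = as.integer(output_dim),
      use_ln = isTRUE(use_ln),
      params = c(
        if (use_ln) list(gamma = rep(1, input_dim), beta = numeric(input_dim)),
        list(W = W, b = numeric(output_dim))
      )
    ),
    class = "projection_spec"
  )
}

#' Apply a projection to a feature vector
#'
#' @param x Numeric vector of length `input_dim`, or a matrix with
#'   `input_dim` columns.
#' @param proj A [projection_spec()].
#' @return Projected vector (or matrix) of width `output_dim`.
#' @export
project_feature <- function(x, proj) {
  stopifnot(inherits(proj, "projection_spec"))
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1) else x
  if (ncol(X) != proj$input_dim) {
    rlang::abort("feature length does not match the projection input dimension")
  }
  if (proj$use_ln) {
    X <- layernorm_fwd(X, proj$params$gamma, proj$params$beta)$Y
  }
  Y <- linear_fwd(X, proj$params$W, proj$params$b)
  if (single) drop(Y) else Y
}
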