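#' Specification of the interaction prediction head
#'
#' The head consumes the concatenation of the drug feature and the target
#' feature (drug first) and maps it to a single binding logit through a
#' stack of blocks, each a fully connected layer followed by GeLU and
#' dropout, and a final fully connected layer with no activation or
#' dropout. The full-scale configuration is 1024 (= 512 + 512) -> 2048 ->
#' 1024 -> 512 -> 1 with dropout 0.1 per block.
#'
#' @param input_dim Concatenated feature width (default 1024).
#' @param dims Hidden widths of the blocks (default `c(2048, 1024, 512)`).
#' @param dropout Dropout proportion per block (default 0.1).
#' @return A `head_spec`.
#' @examples
#' count_parameters(head_spec())
#' @export
head_spec <- function(input_dim = 1024L, dims = c(2048L, 1024L, 512L),
                      dropout = 0.1) {
  if (input_dim <= 0 || any(dims <= 0)) {
    rlang::abort("head dimensions must be positive")
  }
  structure(
    list(input_dim = as.integer(input_dim), dims = as.integer(dims),
         dropout = dropout),
    class = "head_spec"
  )
}

#' @export
count_parameters.head_spec <- function(x, ...) {
  widths <- c(x$input_dim, x$dims, 1L)
  sum(widths[-length(widths)] * widths[-1] + widths[-1])
}

#' Build the interaction head
#'
#' @param spec A [head_spec()].
#' @param seed Seed for weight initialization (truncated normal, sd 0.02).
#' @return An `interaction_head` with `spec` and `params` (per-layer `W`,
#'   `b`).
#' @export
build_head <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "head_spec"))
  widths <- c(spec$input_dim, spec$dims, 1L)
  params <- withr::with_seed(seed, {
    purrr::map(seq_len(length(widths) - 1L), function(i) {
      list(W = init_matrix(widths[i], widths[i + 1]),
           b = numeric(widths[i + 1]))
    })
  })
  structure(list(spec = spec, params = params), class = "interaction_head")
}

#' @export
print.interaction_head <- function(x, ...) {
  cat("<interaction_head> ", paste(c(x$spec$input_dim, x$spec$dims, 1L),
                                   collapse = " -> "),
      " (", format(count_parameters(x$spec), big.mark = ","),
      " parameters)\n", sep = "")
  invisible(x)
}

#' @export
count_parameters.interaction_head <- function(x, ...) {
  param_tree_count(x$params)
}

# forward over a batch matrix (B x input_dim) of concatenated features;
# the last layer has no activation or dropout and yields one logit per row
head_forward <- function(head, X, training = FALSE, want_cache = FALSE) {
  params <- head$params
  p_drop <- head$spec$dropout
  n_blocks <- length(params) - 1L
  caches <- vector("list", n_blocks)
  A <- X
  for (i in seq_len(n_blocks)) {
    Z <- linear_fwd(A, params[[i]]$W, params[[i]]$b)
    gel <- gelu_fwd(Z, want_cache = want_cache)
    G <- if (want_cache) gel$Y else gel
    dr <- dropout_fwd(G, p_drop, training)
    if (want_cache) {
      caches[[i]] <- list(A = A, Z = Z, P = gel$P, mask = dr$mask)
    }
    A <- dr$Y
  }
  logits <- drop(linear_fwd(A, params[[n_blocks + 1L]]$W,
                            params[[n_blocks + 1L]]$b))
  out <- list(logits = logits)
  if (want_cache) {
    out$cache <- list(blocks = caches, A_final = A)
  }
  out
}

# dlogits (length B) -> list(dX, grads)
head_backward <- function(head, fwd, dlogits) {
  params <- head$params
  n_blocks <- length(params) - 1L
  grads <- vector("list", length(params))
  dA <- matrix(dlogits, ncol = 1)
  lb <- linear_bwd(dA, fwd$cache$A_final, params[[n_blocks + 1L]]$W)
  grads[[n_blocks + 1L]] <- list(W = lb$dW, b = lb$db)
  dA <- lb$dX
  for (i in rev(seq_len(n_blocks))) {
    bc <- fwd$cache$blocks[[i]]
    dG <- dropout_bwd(dA, bc$mask)
    dZ <- gelu_bwd(dG, bc$Z, bc$P)
    lb <- linear_bwd(dZ, bc$A, params[[i]]$W)
    grads[[i]] <- list(W = lb$dW, b = lb$db)
    dA <- lb$dX
  }
  list(dX = dA, grads = grads)
}

#' Predict a binding probability for one drug-target feature pair
#'
#' Concatenates the drug feature and the target feature (drug first — the
#' head is order-sensitive by construction), runs the head in evaluation
#' mode (dropout off) and applies the logistic function to the resulting
#' logit, giving a probability strictly inside (0, 1).
#'
#' @param z_drug,z_target Feature vectors (or matrices with one row per
#'   pair) whose widths sum to the head's input dimension.
#' @param head An [build_head()] object.
#' @return Probability vector in (0, 1).
#' @export
predict_interaction <- function(z_drug, z_target, head) {
  stopifnot(inherits(head, "interaction_head"))
  Zd <- if (is.null(dim(z_drug))) matrix(z_drug, nrow = 1) else z_drug
  Zt <- if (is.null(dim(z_target))) matrix(z_target, nrow = 1) else z_target
  X <- cbind(Zd, Zt)
  if (ncol(X) != head$spec$input_dim) {
    rlang::abort("concatenated feature width does not match the head input")
  }
  sigmoid(head_forward(head, X, training = FALSE)$logits)
}
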