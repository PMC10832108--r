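# Full model assembly: drug encoder -> f projection -> z_drug;
# student/teacher class tokens -> adaptation gate -> reduction -> z_target;
# concat -> interaction head -> binding logit.

# projection forward with cache for the backward pass
proj_fwd <- function(X, proj, want_cache = FALSE) {
  if (proj$use_ln) {
    ln <- layernorm_fwd(X, proj$params$gamma, proj$params$beta)
    Xl <- ln$Y
  } else {
    ln <- NULL
    Xl <- X
  }
  Y <- linear_fwd(Xl, proj$params$W, proj$params$b)
  if (want_cache) list(Y = Y, ln = ln, Xl = Xl) else list(Y = Y)
}

proj_bwd <- function(dY, fwd, proj) {
  lb <- linear_bwd(dY, fwd$Xl, proj$params$W)
  if (proj$use_ln) {
    lnb <- layernorm_bwd(lb$dX, fwd$ln, proj$params$gamma)
    list(dX = lnb$dX,
         grads = list(gamma = lnb$dgamma, beta = lnb$dbeta,
                      W = lb$dW, b = lb$db))
  } else {
    list(dX = lb$dX, grads = list(W = lb$dW, b = lb$db))
  }
}

#' Assemble a drug-target interaction model
#'
#' Builds the three-component architecture: a trainable drug encoder whose
#' class token passes through the `f` projection (layer norm + affine) to a
#' `z_dim` drug feature; a target branch producing a `z_dim` target feature
#' from student and/or frozen-teacher class tokens; and the concatenation
#' head mapping the pair to a binding logit.
#'
#' The three ablation modes are separate constructions, not runtime pinning
#' of lambda:
#' * `"adaptation"` — both branches, mixed by the learnable gate.
#' * `"teacher_only"` — no student encoder is built; the target feature is
#'   `reduce(h(LN(teacher_cls)))` and the drug encoder is frozen, so
#'   training this mode is linear probing: only projections and the head
#'   receive updates.
#' * `"student_only"` — no teacher branch exists; the target feature is
#'   `reduce(g(LN(student_cls)))`.
#'
#' @param drug_config `encoder_config` for the drug encoder.
#' @param student_config `encoder_config` for the student protein encoder
#'   (ignored in `teacher_only` mode).
#' @param teacher_dim Width of the frozen teacher's class-token features.
#' @param head A [head_spec()]; its input width must equal `2 * z_dim`.
#' @param mode One of `"adaptation"`, `"teacher_only"`, `"student_only"`.
#' @param z_dim Width of each of the drug and target features (512 at full
#'   scale).
#' @param mix_dim Width of the class-token mixing space (defaults to the
#'   student hidden width; 1024 at full scale). Ignored when
#'   `direct_mix = TRUE`.
#' @param direct_mix Alternative wiring in which `g` and `h` project
#'   straight to `z_dim` and no separate reduction map exists.
#' @param drug_trainable Whether the drug encoder is fine-tuned (default
#'   TRUE; forced FALSE in `teacher_only` mode).
#' @param drug_vocab,prot_vocab Vocabularies used when preparing records.
#' @param max_drug_len,max_target_len Tokenization lengths.
#' @param seed Seed for all weight initialization (sub-seeds are derived
#'   per component).
#' @return A `dti_model`.
#' @export
dti_model <- function(drug_config, student_config = NULL, teacher_dim,
                      head = head_spec(input_dim = 2L * z_dim),
                      mode = c("adaptation", "teacher_only", "student_only"),
                      z_dim = 512L, mix_dim = NULL, direct_mix = FALSE,
                      drug_trainable = TRUE,
                      drug_vocab = build_smiles_vocab(),
                      prot_vocab = build_protein_vocab(),
                      max_drug_len = 512L, max_target_len = 545L,
                      seed = 1L) {
  mode <- rlang::arg_match(mode)
  if (mode != "teacher_only" && is.null(student_config)) {
    rlang::abort("student_config is required outside teacher_only mode")
  }
  if (mode == "teacher_only") drug_trainable <- FALSE
  student_h <- if (!is.null(student_config)) student_config$hidden_dim else NULL
  if (is.null(mix_dim)) {
    mix_dim <- if (!is.null(student_h)) student_h else teacher_dim
  }
  if (direct_mix) mix_dim <- z_dim
  if (head$input_dim != 2L * z_dim) {
    rlang::abort("head input width must equal 2 * z_dim")
  }

  drug_encoder <- build_encoder(drug_config, seed = seed)
  f_proj <- projection_spec(drug_config$hidden_dim, z_dim, seed = seed + 1L)
  student <- NULL
  gate <- NULL
  g_proj <- NULL
  h_proj <- NULL
  if (mode != "teacher_only") {
    student <- build_encoder(student_config, seed = seed + 2L)
    g_proj <- projection_spec(student_h, mix_dim, seed = seed + 3L)
  }
  if (mode != "student_only") {
    h_proj <- projection_spec(teacher_dim, mix_dim, seed = seed + 4L)
  }
  if (mode == "adaptation") {
    lambda <- withr::with_seed(seed + 5L, stats::runif(1))
  } else {
    lambda <- NULL
  }
  reduce <- if (direct_mix) NULL else {
    reduce_spec(mix_dim, z_dim, seed = seed + 6L)
  }
  head <- build_head(head, seed = seed + 7L)

  structure(
    list(
      mode = mode, z_dim = as.integer(z_dim), mix_dim = as.integer(mix_dim),
      direct_mix = isTRUE(direct_mix),
      teacher_dim = as.integer(teacher_dim),
      drug_trainable = isTRUE(drug_trainable),
      drug_encoder = drug_encoder, f_proj = f_proj,
      student = student, g_proj = g_proj, h_proj = h_proj,
      lambda = lambda, reduce = reduce, head = head,
      drug_vocab = drug_vocab, prot_vocab = prot_vocab,
      max_drug_len = as.integer(max_drug_len),
      max_target_len = as.integer(max_target_len)
    ),
    class = "dti_model"
  )
}

#' @export
print.dti_model <- function(x, ...) {
  cat("<dti_model> mode ", x$mode, ", z_dim ", x$z_dim,
      ", mix_dim ", x$mix_dim, "\n", sep = "")
  if (!is.null(x$lambda)) {
    cat("  lambda = ", format(x$lambda, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

# ---- trainable parameter tree ---------------------------------------------
#
# The optimizer works on a nested list mirroring the trainable components;
# frozen components (teacher features always; the drug encoder in
# teacher_only mode) never appear in the tree, so they can receive no
# updates even in principle.

model_trainable_params <- function(model) {
  tree <- list()
  if (model$drug_trainable) tree$drug <- model$drug_encoder$params
  tree$f <- model$f_proj$params
  if (!is.null(model$student)) tree$student <- model$student$params
  if (!is.null(model$g_proj)) tree$g <- model$g_proj$params
  if (!is.null(model$h_proj)) tree$h <- model$h_proj$params
  if (!is.null(model$lambda)) tree$lambda <- model$lambda
  if (!is.null(model$reduce)) tree$reduce <- model$reduce$params
  tree$head <- model$head$params
  tree
}

model_set_params <- function(model, tree) {
  # exact [[ indexing throughout: $ would partial-match "h" onto "head"
  if (!is.null(tree[["drug"]])) model$drug_encoder$params <- tree[["drug"]]
  model$f_proj$params <- tree[["f"]]
  if (!is.null(tree[["student"]])) model$student$params <- tree[["student"]]
  if (!is.null(tree[["g"]])) model$g_proj$params <- tree[["g"]]
  if (!is.null(tree[["h"]])) model$h_proj$params <- tree[["h"]]
  if (!is.null(tree[["lambda"]])) model$lambda <- as.numeric(tree[["lambda"]])
  if (!is.null(tree[["reduce"]])) model$reduce$params <- tree[["reduce"]]
  model$head$params <- tree[["head"]]
  model
}

#' @export
count_parameters.dti_model <- function(x, ...) {
  param_tree_count(model_trainable_params(x))
}

# ---- batched forward / backward -------------------------------------------
#
# `batch` is a list with drug_ids/drug_mask (B x Ld), tgt_ids/tgt_mask
# (B x Lt, absent in teacher_only mode) and teacher_feat (B x teacher_dim,
# absent in student_only mode).

model_forward <- function(model, batch, training = FALSE, want_cache = FALSE) {
  cache <- list()
  drug_fwd <- encoder_forward(model$drug_encoder, batch$drug_ids,
                              batch$drug_mask, training = training,
                              want_cache = want_cache && model$drug_trainable)
  f_fwd <- proj_fwd(drug_fwd$cls, model$f_proj, want_cache = want_cache)
  z_drug <- f_fwd$Y

  gs <- NULL
  ht <- NULL
  student_fwd <- NULL
  g_fwd <- NULL
  h_fwd <- NULL
  if (!is.null(model$student)) {
    student_fwd <- encoder_forward(model$student, batch$tgt_ids,
                                   batch$tgt_mask, training = training,
                                   want_cache = want_cache)
    g_fwd <- proj_fwd(student_fwd$cls, model$g_proj, want_cache = want_cache)
    gs <- g_fwd$Y
  }
  if (!is.null(model$h_proj)) {
    h_fwd <- proj_fwd(batch$teacher_feat, model$h_proj,
                      want_cache = want_cache)
    ht <- h_fwd$Y
  }
  M <- switch(model$mode,
    adaptation = model$lambda * gs + (1 - model$lambda) * ht,
    student_only = gs,
    teacher_only = ht
  )
  if (is.null(model$reduce)) {
    z_target <- M
    r_fwd <- NULL
  } else {
    r_fwd <- proj_fwd(M, model$reduce, want_cache = want_cache)
    z_target <- r_fwd$Y
  }
  X <- cbind(z_drug, z_target)
  h_out <- head_forward(model$head, X, training = training,
                        want_cache = want_cache)
  out <- list(logits = h_out$logits, z_drug = z_drug, z_target = z_target)
  if (want_cache) {
    out$cache <- list(
      drug_fwd = drug_fwd, f_fwd = f_fwd, student_fwd = student_fwd,
      g_fwd = g_fwd, h_fwd = h_fwd, gs = gs, ht = ht, M = M, r_fwd = r_fwd,
      head_fwd = h_out
    )
  }
  out
}

# dlogits -> gradient tree matching model_trainable_params(model)
model_backward <- function(model, fwd, dlogits) {
  cc <- fwd$cache
  z <- model$z_dim
  hb <- head_backward(model$head, cc$head_fwd, dlogits)
  grads <- list()
  dZd <- hb$dX[, seq_len(z), drop = FALSE]
  dZt <- hb$dX[, z + seq_len(z), drop = FALSE]

  if (is.null(model$reduce)) {
    dM <- dZt
  } else {
    rb <- proj_bwd(dZt, cc$r_fwd, model$reduce)
    grads$reduce <- rb$grads
    dM <- rb$dX
  }
  if (model$mode == "adaptation") {
    grads$lambda <- sum(dM * (cc$gs - cc$ht))
    dgs <- model$lambda * dM
    dht <- (1 - model$lambda) * dM
  } else if (model$mode == "student_only") {
    dgs <- dM
    dht <- NULL
  } else {
    dgs <- NULL
    dht <- dM
  }
  if (!is.null(dgs)) {
    gb <- proj_bwd(dgs, cc$g_fwd, model$g_proj)
    grads$g <- gb$grads
    dHidden <- matrix(0, cc$student_fwd$B * cc$student_fwd$L,
                      ncol(gb$dX))
    cls_rows <- seq(1L, nrow(dHidden), by = cc$student_fwd$L)
    dHidden[cls_rows, ] <- gb$dX
    sb <- encoder_backward(model$student, cc$student_fwd, dHidden)
    grads$student <- sb$grads
  }
  if (!is.null(dht)) {
    hpb <- proj_bwd(dht, cc$h_fwd, model$h_proj)
    grads$h <- hpb$grads
    # hpb$dX is the gradient w.r.t. cached teacher features: discarded —
    # the teacher is frozen and receives no updates.
  }
  fb <- proj_bwd(dZd, cc$f_fwd, model$f_proj)
  grads$f <- fb$grads
  if (model$drug_trainable) {
    dHidden <- matrix(0, cc$drug_fwd$B * cc$drug_fwd$L, ncol(fb$dX))
    cls_rows <- seq(1L, nrow(dHidden), by = cc$drug_fwd$L)
    dHidden[cls_rows, ] <- fb$dX
    db <- encoder_backward(model$drug_encoder, cc$drug_fwd, dHidden)
    grads$drug <- db$grads
  }
  grads$head <- hb$grads
  # order the tree exactly like model_trainable_params()
  template <- model_trainable_params(model)
  grads[names(template)]
}

# ---- record preparation and prediction -------------------------------------

# Tokenize records once into padded id/mask matrices, trimmed to the
# longest true length in the set, and fetch teacher features from the
# cache (one lookup per record; unique sequences hit the same entry).
prepare_records <- function(model, records, cache = NULL, teacher = NULL) {
  drug_tok <- purrr::map(records$smiles, tokenize_smiles,
                         max_len = model$max_drug_len,
                         vocab = model$drug_vocab)
  tgt_tok <- purrr::map(records$sequence, tokenize_protein,
                        max_len = model$max_target_len,
                        vocab = model$prot_vocab)
  trim <- function(toks) {
    ids <- do.call(rbind, purrr::map(toks, "token_ids"))
    mask <- do.call(rbind, purrr::map(toks, "attention_mask"))
    keep <- seq_len(max(purrr::map_int(toks, "true_length")))
    list(ids = ids[, keep, drop = FALSE], mask = mask[, keep, drop = FALSE])
  }
  out <- list(labels = as.numeric(records$label), n = nrow(records))
  d <- trim(drug_tok)
  out$drug_ids <- d$ids
  out$drug_mask <- d$mask
  t <- trim(tgt_tok)
  out$tgt_ids <- t$ids
  out$tgt_mask <- t$mask
  if (!is.null(model$h_proj)) {
    if (is.null(cache) && is.null(teacher)) {
      rlang::abort(
        "modes with a teacher branch need a teacher cache or a live teacher"
      )
    }
    out$teacher_feat <- if (!is.null(cache)) {
      do.call(rbind, purrr::map(tgt_tok, function(tok) cache_lookup(cache, tok)))
    } else {
      # live path: one frozen forward pass per record
      do.call(rbind, purrr::map(tgt_tok, function(tok) {
        as.numeric(encode_cls(teacher, tok))
      }))
    }
  }
  out
}

subset_batch <- function(prep, idx) {
  out <- list(
    drug_ids = prep$drug_ids[idx, , drop = FALSE],
    drug_mask = prep$drug_mask[idx, , drop = FALSE],
    tgt_ids = prep$tgt_ids[idx, , drop = FALSE],
    tgt_mask = prep$tgt_mask[idx, , drop = FALSE],
    labels = prep$labels[idx]
  )
  if (!is.null(prep$teacher_feat)) {
    out$teacher_feat <- prep$teacher_feat[idx, , drop = FALSE]
  }
  out
}

#' Score interaction records with a fitted model
#'
#' Runs the model in evaluation mode (dropout off) over a tibble of
#' interaction records and returns the records with a `score` column of
#' binding probabilities.
#'
#' @param object A `dti_model`.
#' @param records Interaction tibble with `smiles`, `sequence` (and
#'   optionally `label`) columns.
#' @param cache A `teacher_cache` (required unless the model is
#'   student-only).
#' @param batch_size Scoring batch size.
#' @param ... Unused.
#' @return `records` with an added `score` column.
#' @export
predict.dti_model <- function(object, records, cache = NULL,
                              batch_size = 64L, ...) {
  if (!"label" %in% names(records)) records$label <- NA_real_
  prep <- prepare_records(object, records, cache)
  scores <- numeric(prep$n)
  starts <- seq(1L, prep$n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, prep$n)
    fwd <- model_forward(object, subset_batch(prep, idx), training = FALSE)
    scores[idx] <- sigmoid(fwd$logits)
  }
  dplyr::mutate(records, score = scores)
}
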