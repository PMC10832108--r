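#' Initialize the learnable adaptation gate
#'
#' The gate holds the scalar adaptation parameter lambda, drawn uniformly
#' from [0, 1) under the seed, together with the two branch projections:
#' `g` for the student class token and `h` for the teacher class token,
#' each a layer norm followed by an affine map into the mixing dimension.
#' Lambda is a raw unconstrained scalar: only its initialization is
#' bounded; training may move it outside [0, 1] and it is reported as-is.
#'
#' @param seed Seed for lambda and the projection weights.
#' @param student_dim,teacher_dim Hidden widths of the two encoders.
#' @param mix_dim Width of the mixed class-token space (default 1024).
#' @param identity Test hook: identity projections, layer norm bypassed.
#' @return An `adaptation_gate`.
#' @examples
#' g <- init_gate(seed = 1, student_dim = 8, teacher_dim = 8, mix_dim = 8)
#' g$lambda
#' @export
init_gate <- function(seed = 1L, student_dim = 1024L, teacher_dim = 1024L,
                      mix_dim = 1024L, identity = FALSE) {
  lambda <- withr::with_seed(seed, stats::runif(1))
  g <- projection_spec(student_dim, mix_dim, seed = seed + 1L,
                       identity = identity)
  h <- projection_spec(teacher_dim, mix_dim, seed = seed + 2L,
                       identity = identity)
  structure(
    list(lambda = lambda, g = g, h = h, mix_dim = as.integer(mix_dim)),
    class = "adaptation_gate"
  )
}

#' @export
print.adaptation_gate <- function(x, ...) {
  cat("<adaptation_gate> lambda = ", format(x$lambda, digits = 4),
      ", mix dim ", x$mix_dim, "\n", sep = "")
  invisible(x)
}

#' Mix student and teacher class tokens through the adaptation gate
#'
#' Computes `lambda * g(LN(student_cls)) + (1 - lambda) * h(LN(teacher_cls))`:
#' a gated combination of the task-specific student feature and the frozen
#' teacher "hint". The result lives in the mixing dimension (1024 in the
#' full-scale configuration). Gradients flow into lambda, both projections
#' and the student class token; the teacher class token is a cached
#' constant, so no gradient ever reaches teacher weights.
#'
#' @param student_cls,teacher_cls Class-token vectors (or matrices with one
#'   row per example) of the respective encoder widths.
#' @param gate An [init_gate()] object.
#' @return Mixed feature vector (or matrix) of width `mix_dim`.
#' @export
mix_class_tokens <- function(student_cls, teacher_cls, gate) {
  stopifnot(inherits(gate, "adaptation_gate"))
  gs <- project_feature(student_cls, gate$g)
  ht <- project_feature(teacher_cls, gate$h)
  gate$lambda * gs + (1 - gate$lambda) * ht
}

#' Affine reduction from the mixing space to the head input space
#'
#' The class-token mixing lives in the encoder width (1024) while the
#' interaction head consumes a 512-dimensional target feature; this affine
#' map bridges the two. Constructed with [reduce_spec()]; a truncating
#' identity test hook returns the first `output_dim` entries.
#'
#' @param mixed Mixed feature vector (or matrix) of width `input_dim`.
#' @param reduce A `projection_spec` built by [reduce_spec()].
#' @return Target feature of width `output_dim`.
#' @export
reduce_target_feature <- function(mixed, reduce) {
  project_feature(mixed, reduce)
}

#' @rdname reduce_target_feature
#' @param input_dim,output_dim Dimensions of the reduction (default
#'   1024 to 512).
#' @param seed Seed for initialization.
#' @param identity Truncating-identity test hook.
#' @export
reduce_spec <- function(input_dim = 1024L, output_dim = 512L, seed = 1L,
                        identity = FALSE) {
  projection_spec(input_dim, output_dim, seed = seed, identity = identity,
                  use_ln = FALSE)
}

# ---- teacher cache ---------------------------------------------------------

# digest of the exact token-id list: truncation policy is part of the key
token_digest <- function(token_ids) {
  paste(as.integer(token_ids), collapse = ".")
}

#' Fingerprint of a teacher configuration
#'
#' Serialized architectural description stored on a cache file; lookups
#' against a cache created under a different teacher are refused.
#'
#' @param teacher An `encoder` or mock teacher.
#' @return A JSON string.
#' @export
teacher_fingerprint <- function(teacher) UseMethod("teacher_fingerprint")

#' @export
teacher_fingerprint.encoder <- function(teacher) {
  cfg <- teacher$config
  as.character(jsonlite::toJSON(
    c(cfg[c("n_layers", "n_heads", "hidden_dim", "intermediate_dim",
            "vocab_size", "max_positions", "type_vocab", "has_pooler")],
      list(kind = "encoder", weights = param_tree_digest(teacher$params))),
    auto_unbox = TRUE
  ))
}

new_teacher_cache <- function(fingerprint, max_len) {
  structure(
    list(
      features = new.env(parent = emptyenv()),
      fingerprint = as.character(fingerprint),
      max_len = as.integer(max_len),
      created = format(Sys.time(), tz = "UTC")
    ),
    class = "teacher_cache"
  )
}

#' @export
print.teacher_cache <- function(x, ...) {
  cat("<teacher_cache> ", length(ls(x$features)), " cached targets, max_len ",
      x$max_len, "\n", sep = "")
  invisible(x)
}

#' Precompute the frozen-teacher feature cache
#'
#' Because the teacher is frozen its class-token output for a given target
#' is fixed, so it can be computed once, before training and inference, and
#' looked up thereafter. One entry is stored per unique tokenized sequence
#' (the digest keys the exact token-id list, so the truncation policy is
#' part of the key). Re-running against an existing store is idempotent:
#' digests already present are skipped. A store created under a different
#' teacher configuration is refused.
#'
#' @param targets Character vector of sequences, or a tibble with a
#'   `sequence` column.
#' @param teacher A frozen `encoder` or mock teacher.
#' @param store_path Optional RDS path; when it exists, entries are loaded
#'   and extended, and the updated store is written back.
#' @param max_len Target tokenization length (default 545).
#' @param vocab Protein vocabulary.
#' @return A `teacher_cache`.
#' @export
precompute_teacher_cache <- function(targets, teacher, store_path = NULL,
                                     max_len = 545L,
                                     vocab = build_protein_vocab()) {
  if (is.data.frame(targets)) targets <- targets$sequence
  targets <- unique(as.character(targets))
  fp <- teacher_fingerprint(teacher)
  if (!is.null(store_path) && file.exists(store_path)) {
    cache <- load_teacher_cache(store_path)
    if (!identical(cache$fingerprint, fp)) {
      rlang::abort(
        "existing cache store was built under a different teacher configuration"
      )
    }
  } else {
    cache <- new_teacher_cache(fp, max_len)
  }
  for (seq_str in targets) {
    tok <- tokenize_protein(seq_str, max_len = cache$max_len, vocab = vocab)
    key <- token_digest(tok$token_ids)
    if (!exists(key, envir = cache$features, inherits = FALSE)) {
      assign(key, as.numeric(encode_cls(teacher, tok)), envir = cache$features)
    }
  }
  if (!is.null(store_path)) save_teacher_cache(cache, store_path)
  cache
}

#' @rdname precompute_teacher_cache
#' @param cache A `teacher_cache`.
#' @param path RDS path.
#' @export
save_teacher_cache <- function(cache, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(
    features = as.list(cache$features),
    fingerprint = cache$fingerprint,
    max_len = cache$max_len,
    created = cache$created
  ), path)
  invisible(path)
}

#' @rdname precompute_teacher_cache
#' @export
load_teacher_cache <- function(path) {
  raw <- readRDS(path)
  cache <- new_teacher_cache(raw$fingerprint, raw$max_len)
  cache$created <- raw$created
  for (key in names(raw$features)) {
    assign(key, raw$features[[key]], envir = cache$features)
  }
  cache
}

#' Look up a cached teacher class-token feature
#'
#' Returns the stored full-precision vector for the digest of the token
#' sequence. A missing digest is an error naming the digest — there is no
#' silent recompute — unless a `fallback` teacher is supplied, in which
#' case the feature is computed, appended to the cache, and returned.
#'
#' @param cache A `teacher_cache`.
#' @param tokens A `token_seq`.
#' @param fallback Optional teacher used to compute and append missing
#'   entries.
#' @return Numeric feature vector.
#' @export
cache_lookup <- function(cache, tokens, fallback = NULL) {
  stopifnot(inherits(cache, "teacher_cache"), inherits(tokens, "token_seq"))
  key <- token_digest(tokens$token_ids)
  if (exists(key, envir = cache$features, inherits = FALSE)) {
    return(get(key, envir = cache$features, inherits = FALSE))
  }
  if (is.null(fallback)) {
    rlang::abort(paste0("teacher cache miss for target digest ", key))
  }
  if (!identical(cache$fingerprint, teacher_fingerprint(fallback))) {
    rlang::abort("fallback teacher does not match the cache fingerprint")
  }
  feat <- as.numeric(encode_cls(fallback, tokens))
  assign(key, feat, envir = cache$features)
  feat
}
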