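# Shared fixtures and independent oracles.

# ---- metric oracles (mechanically independent of the implementation) -------

# AUROC by exhaustive pairwise comparison, ties credited one half.
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by explicit rank enumeration under the same stable
# ordering convention (decreasing score, original order on ties).
oracle_average_precision <- function(labels, scores) {
  ord <- order(-scores)
  lab <- labels[ord]
  precisions <- c()
  for (r in seq_along(lab)) {
    if (lab[r] == 1) {
      precisions <- c(precisions, sum(lab[seq_len(r)] == 1) / r)
    }
  }
  mean(precisions)
}

# ---- tiny model fixtures ---------------------------------------------------

# miniature profile for unit tests: far smaller than tiny_profile() so
# gradient checks and determinism tests run in seconds
mini_profile <- function(dropout = 0, epochs = 3L, seed = 1L) {
  drug_vocab <- build_smiles_vocab()
  prot_vocab <- build_protein_vocab()
  list(
    drug_config = encoder_config(1L, 2L, 8L, 16L,
                                 vocab_size = length(drug_vocab),
                                 max_positions = 24L, dropout = dropout),
    student_config = encoder_config(2L, 2L, 8L, 16L,
                                    vocab_size = length(prot_vocab),
                                    max_positions = 32L, dropout = dropout),
    teacher_dims = 6L,
    head = head_spec(input_dim = 8L, dims = c(12L, 8L), dropout = dropout),
    train = train_config(learning_rate = 2e-3, epochs = epochs,
                         batch_size = 16L, seed = seed),
    z_dim = 4L, mix_dim = 8L,
    max_drug_len = 24L, max_target_len = 32L,
    drug_vocab = drug_vocab, prot_vocab = prot_vocab
  )
}

mini_model <- function(mode = "adaptation", seed = 7L, dropout = 0,
                       profile = mini_profile(dropout = dropout)) {
  dti_model(
    drug_config = profile$drug_config,
    student_config = profile$student_config,
    teacher_dim = profile$teacher_dims,
    head = profile$head,
    mode = mode,
    z_dim = profile$z_dim, mix_dim = profile$mix_dim,
    drug_vocab = profile$drug_vocab, prot_vocab = profile$prot_vocab,
    max_drug_len = profile$max_drug_len,
    max_target_len = profile$max_target_len,
    seed = seed
  )
}

# small synthetic corpus matched to the mini profile lengths
mini_corpus <- function(n_pairs = 240L, label_noise = 0, seed = 3L) {
  generate_synthetic_corpus(synthetic_spec(
    n_drugs = 60L, n_targets = 40L, n_pairs = n_pairs,
    drug_len = c(6L, 14L), target_len = c(10L, 24L),
    label_noise = label_noise, seed = seed
  ))
}

mini_teacher <- function(seed = 3L) {
  make_mock_teacher("motif_oracle", dims = 6L, seed = seed)
}

mini_cache <- function(corpus, teacher = mini_teacher(), max_len = 32L) {
  precompute_teacher_cache(unique(corpus$records$sequence), teacher,
                           max_len = max_len)
}

# ---- parameter-tree access for the finite-difference checks ----------------

leaf_paths <- function(tree, prefix = list()) {
  if (is.list(tree)) {
    unlist(lapply(seq_along(tree), function(i) {
      nm <- names(tree)[i]
      key <- if (is.null(nm) || nm == "") i else nm
      leaf_paths(tree[[i]], c(prefix, key))
    }), recursive = FALSE, use.names = FALSE)
  } else {
    list(prefix)
  }
}

get_leaf <- function(tree, path) {
  for (p in path) tree <- tree[[p]]
  tree
}

set_leaf <- function(tree, path, val) {
  if (length(path) == 1L) {
    tree[[path[[1]]]] <- val
    return(tree)
  }
  tree[[path[[1]]]] <- set_leaf(tree[[path[[1]]]], path[-1], val)
  tree
}

# digest helper mirroring the package's freezing checks
tree_digest <- function(params) {
  rlang::hash(rapply(params, function(x) round(unclass(x), 12), how = "list"))
}
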