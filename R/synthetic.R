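#' Specification of a synthetic DTI corpus
#'
#' The generator emulates the structure of public DTI benchmarks at desk
#' scale: pools of SMILES-like drugs and protein-like targets, a planted
#' interaction rule, dissociation constants consistent with the labels,
#' and class imbalance. The rule is a motif AND: a pair truly interacts
#' when the drug string contains the drug motif AND the target sequence
#' contains the target motif; labels are then flipped with probability
#' `label_noise`. Kd values are drawn log-uniformly from a class-consistent
#' range (positives strictly below the threshold 30, negatives at or
#' above), so thresholding Kd reconstructs the noisy label exactly.
#'
#' The motif split mirrors the teacher/student knowledge division: the
#' target motif is the kind of "general knowledge" a frozen protein
#' encoder can carry, while the drug motif must be learned by the
#' trainable path.
#'
#' @param n_drugs,n_targets Entity pool sizes.
#' @param n_pairs Number of interaction records (pairs sampled uniformly
#'   from the pools).
#' @param drug_len Range (min, max) of drug token counts.
#' @param target_len Range (min, max) of target residue counts.
#' @param drug_motif Token string planted in motif-bearing drugs.
#' @param target_motif Residue string planted in motif-bearing targets.
#' @param p_drug_motif,p_target_motif Motif prevalence among entities.
#' @param label_noise Label-flip probability in [0, 0.5).
#' @param kd_positive,kd_negative Kd ranges for positive / negative labels;
#'   the positive range must lie strictly below 30 and the negative range
#'   at or above 30.
#' @param seed Generator seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 200L, n_targets = 120L, n_pairs = 2000L,
                           drug_len = c(12L, 30L), target_len = c(20L, 50L),
                           drug_motif = "[Se][Se]", target_motif = "HWH",
                           p_drug_motif = 0.3, p_target_motif = 0.3,
                           label_noise = 0.05,
                           kd_positive = c(0.1, 30), kd_negative = c(30, 1e4),
                           seed = 1L) {
  if (n_drugs < 1 || n_targets < 1 || n_pairs < 1) {
    rlang::abort("entity and pair counts must be positive")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    rlang::abort("label_noise must be in [0, 0.5)")
  }
  if (kd_positive[2] > 30 || kd_negative[1] < 30) {
    rlang::abort("Kd ranges must straddle the threshold 30")
  }
  structure(
    list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
         n_pairs = as.integer(n_pairs), drug_len = as.integer(drug_len),
         target_len = as.integer(target_len), drug_motif = drug_motif,
         target_motif = target_motif, p_drug_motif = p_drug_motif,
         p_target_motif = p_target_motif, label_noise = label_noise,
         kd_positive = kd_positive, kd_negative = kd_negative,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# background alphabets deliberately exclude the default motifs, so motif
# presence is controlled by planting (plus rare chance assembly)
SYNTH_DRUG_ALPHABET <- c("C", "C", "C", "c", "c", "N", "O", "n", "o", "S",
                         "F", "Cl", "Br", "=", "#", "(", ")", "1", "2",
                         "[nH]", "[N+]", "[O-]")

random_smiles <- function(len, alphabet = SYNTH_DRUG_ALPHABET) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(PROTEIN_RESIDUES[1:20], len, replace = TRUE), collapse = "")
}

plant_motif <- function(s, motif, tokens) {
  # insert between token boundaries so the motif survives retokenization
  pos <- sample.int(length(tokens) + 1L, 1L) - 1L
  paste0(paste(tokens[seq_len(pos)], collapse = ""), motif,
         paste(tokens[setdiff(seq_along(tokens), seq_len(pos))], collapse = ""))
}

log_uniform <- function(n, range) {
  exp(stats::runif(n, log(range[1]), log(range[2])))
}

#' Generate a synthetic DTI corpus
#'
#' Samples entity pools with motifs planted at the specified prevalences,
#' pairs them uniformly, assigns true labels by the motif AND-rule (on the
#' actual strings, so chance motif assembly counts), flips labels with the
#' noise probability and draws class-consistent Kd values. Fully
#' reproducible under the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `records` (interaction tibble with `drug_id`, `smiles`,
#'   `target_id`, `sequence`, `label`, `kd`, `true_label`), `drugs` and
#'   `targets` (entity tibbles), and `rule` (the planted motifs and noise
#'   level).
#' @export
generate_synthetic_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    drug_lens <- sample(spec$drug_len[1]:spec$drug_len[2], spec$n_drugs,
                        replace = TRUE)
    drugs <- purrr::map_chr(drug_lens, random_smiles)
    has_dm <- stats::runif(spec$n_drugs) < spec$p_drug_motif
    drugs[has_dm] <- purrr::map_chr(which(has_dm), function(i) {
      plant_motif(drugs[i], spec$drug_motif, smiles_atom_tokens(drugs[i]))
    })
    target_lens <- sample(spec$target_len[1]:spec$target_len[2],
                          spec$n_targets, replace = TRUE)
    targets <- purrr::map_chr(target_lens, random_protein)
    has_tm <- stats::runif(spec$n_targets) < spec$p_target_motif
    targets[has_tm] <- purrr::map_chr(which(has_tm), function(i) {
      s <- targets[i]
      pos <- sample.int(nchar(s) + 1L, 1L) - 1L
      paste0(substr(s, 1, pos), spec$target_motif,
             substr(s, pos + 1L, nchar(s)))
    })

    di <- sample.int(spec$n_drugs, spec$n_pairs, replace = TRUE)
    ti <- sample.int(spec$n_targets, spec$n_pairs, replace = TRUE)
    smiles <- drugs[di]
    sequence <- targets[ti]
    true_label <- as.integer(
      grepl(spec$drug_motif, smiles, fixed = TRUE) &
        grepl(spec$target_motif, sequence, fixed = TRUE)
    )
    flip <- stats::runif(spec$n_pairs) < spec$label_noise
    label <- ifelse(flip, 1L - true_label, true_label)
    kd <- numeric(spec$n_pairs)
    kd[label == 1] <- log_uniform(sum(label == 1), spec$kd_positive)
    kd[label == 0] <- log_uniform(sum(label == 0), spec$kd_negative)

    records <- tibble::tibble(
      drug_id = sprintf("D%04d", di),
      smiles = smiles,
      target_id = sprintf("T%04d", ti),
      sequence = sequence,
      label = as.integer(label),
      kd = kd,
      true_label = true_label
    )
    list(
      records = records,
      drugs = tibble::tibble(drug_id = sprintf("D%04d", seq_along(drugs)),
                             smiles = drugs, has_motif = has_dm),
      targets = tibble::tibble(target_id = sprintf("T%04d", seq_along(targets)),
                               sequence = targets, has_motif = has_tm),
      rule = list(drug_motif = spec$drug_motif,
                  target_motif = spec$target_motif,
                  label_noise = spec$label_noise)
    )
  })
}

# ---- mock teachers ---------------------------------------------------------

#' Construct a mock frozen teacher
#'
#' Two desk-scale stand-ins for a large frozen protein encoder:
#' * `"random_frozen"` — a small seeded transformer encoder used frozen;
#'   deterministic features with no task signal.
#' * `"motif_oracle"` — a deterministic map embedding k-mer-presence
#'   indicators of the residue sequence into the class vector. One
#'   coordinate per tracked k-mer; the tracked set always includes
#'   `oracle_kmer` (by default the synthetic target motif), so a linear
#'   probe on these features can separate motif-bearing targets. This
#'   mirrors a teacher whose general sequence knowledge is already
#'   predictive of binding.
#'
#' Both kinds answer [encode_cls()] and carry a configuration fingerprint,
#' so the caching machinery treats them exactly like a real teacher.
#'
#' @param kind `"random_frozen"` or `"motif_oracle"`.
#' @param dims Feature width of the teacher class vector.
#' @param oracle_kmer K-mer guaranteed a coordinate in the oracle (default
#'   `"HWH"`, the default synthetic target motif).
#' @param seed Seed for the frozen weights / the sampled k-mer set.
#' @param vocab Protein vocabulary used to detokenize inputs.
#' @return An object usable wherever a frozen teacher is expected.
#' @export
make_mock_teacher <- function(kind = c("random_frozen", "motif_oracle"),
                              dims = 24L, oracle_kmer = "HWH", seed = 1L,
                              vocab = build_protein_vocab()) {
  kind <- rlang::arg_match(kind)
  if (kind == "random_frozen") {
    cfg <- encoder_config(
      n_layers = 1L, n_heads = 2L, hidden_dim = as.integer(dims),
      intermediate_dim = 2L * as.integer(dims), vocab_size = length(vocab),
      max_positions = 600L, dropout = 0
    )
    return(build_encoder(cfg, seed = seed))
  }
  kmers <- withr::with_seed(seed, {
    k <- nchar(oracle_kmer)
    pool <- replicate(dims * 3, paste(
      sample(PROTEIN_RESIDUES[1:20], k, replace = TRUE), collapse = ""
    ))
    unique(c(oracle_kmer, pool))[seq_len(dims)]
  })
  structure(
    list(kind = "motif_oracle", dims = as.integer(dims), kmers = kmers,
         vocab = vocab),
    class = "mock_teacher"
  )
}

#' @export
print.mock_teacher <- function(x, ...) {
  cat("<mock_teacher> ", x$kind, ", ", x$dims, " k-mer indicator dims\n",
      sep = "")
  invisible(x)
}

#' @export
encode_cls.mock_teacher <- function(encoder, tokens, ...) {
  encode_one <- function(tok) {
    seq_str <- detokenize(tok, encoder$vocab)
    as.numeric(purrr::map_lgl(encoder$kmers, grepl, x = seq_str,
                              fixed = TRUE))
  }
  if (inherits(tokens, "token_seq")) {
    encode_one(tokens)
  } else {
    do.call(rbind, purrr::map(tokens, encode_one))
  }
}

#' @export
teacher_fingerprint.mock_teacher <- function(teacher) {
  as.character(jsonlite::toJSON(
    list(kind = "motif_oracle", dims = teacher$dims,
         kmers = rlang::hash(teacher$kmers)),
    auto_unbox = TRUE
  ))
}

# ---- tiny profile ----------------------------------------------------------

#' Desk-scale model profile
#'
#' A scaled-down stand-in for the full-scale architecture so the complete
#' pipeline — tokenization, caching, training, selection, evaluation —
#' runs in minutes on one CPU core: hidden width 32 with 2 attention heads
#' and feed-forward width 64 (a 1-layer drug encoder and a 2-layer student,
#' preserving the shallow-student design), a 24-dimensional mock teacher,
#' 32-wide drug/target features into a 64 -> 128 -> 64 -> 32 -> 1 head,
#' and ten epochs of AdamW at learning rate 2e-3 (scaled up from the
#' full-scale 1e-4 in proportion to the much smaller model and shorter
#' schedule) with batch size 32.
#'
#' @param epochs Training epochs (default 10).
#' @param seed Seed recorded in the training config.
#' @return A list with `drug_config`, `student_config`, `teacher_dims`,
#'   `head`, `train`, `z_dim`, `mix_dim`, `max_drug_len`, `max_target_len`
#'   and the vocabularies.
#' @export
tiny_profile <- function(epochs = 10L, seed = 1L) {
  drug_vocab <- build_smiles_vocab()
  prot_vocab <- build_protein_vocab()
  list(
    drug_config = encoder_config(
      n_layers = 1L, n_heads = 2L, hidden_dim = 32L, intermediate_dim = 64L,
      vocab_size = length(drug_vocab), max_positions = 40L, dropout = 0.1
    ),
    student_config = encoder_config(
      n_layers = 2L, n_heads = 2L, hidden_dim = 32L, intermediate_dim = 64L,
      vocab_size = length(prot_vocab), max_positions = 60L, dropout = 0.1
    ),
    teacher_dims = 24L,
    head = head_spec(input_dim = 64L, dims = c(128L, 64L, 32L),
                     dropout = 0.1),
    train = train_config(learning_rate = 2e-3, epochs = epochs,
                         batch_size = 32L, seed = seed),
    z_dim = 32L, mix_dim = 32L,
    max_drug_len = 40L, max_target_len = 60L,
    drug_vocab = drug_vocab, prot_vocab = prot_vocab
  )
}

#' Assemble a model from a profile
#'
#' Builds a [dti_model()] from a profile list such as [tiny_profile()],
#' wiring in its encoder configurations, head, feature widths,
#' vocabularies and tokenization lengths.
#'
#' @param profile A profile list ([tiny_profile()] or a custom one with
#'   the same fields).
#' @param mode Ablation mode passed to [dti_model()].
#' @param seed Seed for weight initialization.
#' @return A `dti_model`.
#' @export
profile_model <- function(profile, mode = "adaptation", seed = 1L) {
  dti_model(
    drug_config = profile$drug_config,
    student_config = profile$student_config,
    teacher_dim = profile$teacher_dims,
    head = profile$head,
    mode = mode,
    z_dim = profile$z_dim,
    mix_dim = profile$mix_dim,
    drug_vocab = profile$drug_vocab,
    prot_vocab = profile$prot_vocab,
    max_drug_len = profile$max_drug_len,
    max_target_len = profile$max_target_len,
    seed = seed
  )
}
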