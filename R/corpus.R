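#' Binary label from a dissociation constant
#'
#' Interactions with Kd strictly below the threshold are positive binders;
#' a Kd exactly at the threshold is negative. Units are passed through
#' untransformed (the threshold is interpreted in whatever units the source
#' file uses; the conventional default is 30).
#'
#' @param kd Positive numeric vector of dissociation constants.
#' @param threshold Positivity threshold (default 30); `kd < threshold`
#'   gives label 1.
#' @return Integer vector of 0/1 labels.
#' @examples
#' label_from_kd(c(29.9, 30, 10000))
#' @export
label_from_kd <- function(kd, threshold = 30) {
  if (!is.numeric(kd) || any(is.na(kd)) || any(kd <= 0)) {
    rlang::abort("kd must be positive and non-missing")
  }
  as.integer(kd < threshold)
}

# Assign stable entity ids by first appearance of the exact string.
entity_ids <- function(x, prefix) {
  idx <- match(x, unique(x))
  sprintf("%s%04d", prefix, idx)
}

#' Read an interaction table
#'
#' Reads a CSV in the MolTrans dialect: columns `SMILES`, `Target Sequence`
#' and `Label` (plus an optional `Kd` column). When `Label` is absent but
#' `Kd` is present, labels are derived with [label_from_kd()]. Duplicated
#' (drug, target) rows are preserved as-is; their count is reported as a
#' message, never silently deduplicated.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param kd_threshold Threshold used when labels must be derived from Kd.
#' @return A tibble with columns `drug_id`, `smiles`, `target_id`,
#'   `sequence`, `label` and (when present in the source) `kd`.
#' @export
read_interaction_table <- function(path, kd_threshold = 30) {
  if (!file.exists(path)) {
    rlang::abort(paste0("interaction table not found: ", path))
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("SMILES", "Target Sequence")) {
    if (!col %in% names(raw)) {
      rlang::abort(paste0("required column missing: '", col, "'"))
    }
  }
  if (!"Label" %in% names(raw) && !"Kd" %in% names(raw)) {
    rlang::abort("required column missing: 'Label' (or 'Kd' to derive it)")
  }
  records <- tibble::tibble(
    smiles = as.character(raw$SMILES),
    sequence = as.character(raw$`Target Sequence`)
  )
  if (any(!nzchar(records$smiles)) || any(!nzchar(records$sequence))) {
    rlang::abort("SMILES and Target Sequence entries must be non-empty")
  }
  if ("Label" %in% names(raw)) {
    lab <- raw$Label
    if (!all(lab %in% c(0, 1))) {
      rlang::abort("column 'Label' must be binary 0/1")
    }
    records$label <- as.integer(lab)
  } else {
    records$label <- label_from_kd(raw$Kd, kd_threshold)
  }
  if ("Kd" %in% names(raw)) records$kd <- as.numeric(raw$Kd)
  records <- dplyr::mutate(
    records,
    drug_id = entity_ids(.data$smiles, "D"),
    target_id = entity_ids(.data$sequence, "T"),
    .before = 1
  )
  records <- dplyr::relocate(records, "drug_id", "smiles", "target_id",
                             "sequence", "label")
  n_dup <- sum(duplicated(records[, c("smiles", "sequence")]))
  if (n_dup > 0) {
    rlang::inform(paste0(n_dup, " duplicated (drug, target) rows preserved"))
  }
  records
}

#' Write an interaction table
#'
#' Writes records in the same CSV dialect [read_interaction_table()] reads,
#' so generated corpora round-trip exactly.
#'
#' @param records Interaction tibble with `smiles`, `sequence`, `label`
#'   and optionally `kd` columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(records, path) {
  out <- tibble::tibble(
    SMILES = records$smiles,
    `Target Sequence` = records$sequence,
    Label = as.integer(records$label)
  )
  if ("kd" %in% names(records)) out$Kd <- records$kd
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

new_split_bundle <- function(train, valid, test, provenance = "dataset") {
  structure(
    list(train = train, valid = valid, test = test, provenance = provenance),
    class = "split_bundle"
  )
}

#' @export
print.split_bundle <- function(x, ...) {
  cat("<split_bundle> ", x$provenance, ": train ", nrow(x$train),
      " / valid ", nrow(x$valid), " / test ", nrow(x$test), "\n", sep = "")
  invisible(x)
}

#' Split interaction records into train/validation/test
#'
#' Uniform random, unstratified split: records are permuted under the seed
#' and assigned contiguously, with split sizes rounded to the requested
#' ratios. Deterministic for a fixed seed.
#'
#' @param records Interaction tibble.
#' @param ratios Length-3 numeric vector summing to 1 (default 7:1:2).
#' @param seed Integer seed controlling the permutation.
#' @param provenance Dataset tag carried on the bundle.
#' @return A `split_bundle` with `train`, `valid`, `test` tibbles.
#' @examples
#' \dontrun{
#' b <- split_dataset(records, seed = 1)
#' }
#' @export
split_dataset <- function(records, ratios = c(0.7, 0.1, 0.2), seed = 1L,
                          provenance = "dataset") {
  if (nrow(records) == 0L) rlang::abort("records must be non-empty")
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8) {
    rlang::abort("ratios must be three proportions summing to 1")
  }
  n <- nrow(records)
  perm <- withr::with_seed(seed, sample.int(n))
  n_train <- round(ratios[1] * n)
  n_valid <- round(ratios[2] * n)
  n_valid <- min(n_valid, n - n_train)
  idx_train <- perm[seq_len(n_train)]
  idx_valid <- perm[seq_len(n_valid) + n_train]
  idx_test <- perm[setdiff(seq_len(n), seq_len(n_train + n_valid))]
  new_split_bundle(
    train = records[idx_train, , drop = FALSE],
    valid = records[idx_valid, , drop = FALSE],
    test = records[idx_test, , drop = FALSE],
    provenance = provenance
  )
}

#' Load a split bundle from published split files
#'
#' Loads one CSV per split verbatim (same dialect as
#' [read_interaction_table()]), overriding internal splitting when a
#' benchmark distributes official split files.
#'
#' @param train_path,valid_path,test_path CSV paths.
#' @param provenance Dataset tag.
#' @return A `split_bundle`.
#' @export
load_split_files <- function(train_path, valid_path, test_path,
                             provenance = "dataset") {
  new_split_bundle(
    train = read_interaction_table(train_path),
    valid = read_interaction_table(valid_path),
    test = read_interaction_table(test_path),
    provenance = provenance
  )
}

#' Merge several datasets into an integrated training configuration
#'
#' Concatenates the training splits of all bundles into one integrated
#' training set and likewise for validation (used for model selection),
#' while test sets remain separate per dataset so that reporting stays
#' per-benchmark. Unique drugs and targets are counted by exact string
#' identity of SMILES / sequence across all splits of all bundles.
#'
#' @param bundles List of `split_bundle` objects (at least two).
#' @return A list with `train`, `valid` (tibbles), `tests` (named list of
#'   per-dataset test tibbles) and `counts` (one-row tibble with
#'   `n_unique_drugs`, `n_unique_targets`).
#' @export
merge_integrated <- function(bundles) {
  if (length(bundles) < 2L) {
    rlang::abort("integrated merging needs at least two bundles")
  }
  stopifnot(all(purrr::map_lgl(bundles, inherits, "split_bundle")))
  all_rows <- purrr::map(bundles, ~ dplyr::bind_rows(.x$train, .x$valid, .x$test))
  all_rows <- dplyr::bind_rows(all_rows)
  tests <- purrr::map(bundles, "test")
  names(tests) <- purrr::map_chr(bundles, "provenance")
  list(
    train = dplyr::bind_rows(purrr::map(bundles, "train")),
    valid = dplyr::bind_rows(purrr::map(bundles, "valid")),
    tests = tests,
    counts = tibble::tibble(
      n_unique_drugs = dplyr::n_distinct(all_rows$smiles),
      n_unique_targets = dplyr::n_distinct(all_rows$sequence)
    )
  )
}

#' Extract cold-drug, cold-target and cold-binding test subsets
#'
#' Cold drugs are test interactions whose drug (exact SMILES string) occurs
#' in neither the training nor the validation split; cold targets are the
#' analogue for protein sequences; cold bindings are test interactions in
#' which both entities are unseen. By construction every cold binding is
#' both a cold-drug and a cold-target interaction.
#'
#' @param bundle A `split_bundle`.
#' @return A list of tibbles: `cold_drug`, `cold_target`, `cold_binding`.
#' @export
extract_cold_subsets <- function(bundle) {
  stopifnot(inherits(bundle, "split_bundle"))
  seen_drugs <- unique(c(bundle$train$smiles, bundle$valid$smiles))
  seen_targets <- unique(c(bundle$train$sequence, bundle$valid$sequence))
  test <- bundle$test
  is_cold_drug <- !(test$smiles %in% seen_drugs)
  is_cold_target <- !(test$sequence %in% seen_targets)
  list(
    cold_drug = test[is_cold_drug, , drop = FALSE],
    cold_target = test[is_cold_target, , drop = FALSE],
    cold_binding = test[is_cold_drug & is_cold_target, , drop = FALSE]
  )
}
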