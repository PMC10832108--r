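# Run manifests tie the pipeline together: one YAML file describes the
# data, the synthetic generator, the model profile, the training recipe
# and the artifact paths. Command functions validate the manifest before
# any compute and write a copy of the resolved manifest next to their
# artifacts for provenance.

#' Read and validate a run manifest
#'
#' A manifest is a YAML file with (a subset of) the sections `paths`
#' (`data`, `cache`, `output`), `synthetic` (fields of
#' [synthetic_spec()]), `profile` (`epochs`), `train` (fields of
#' [train_config()]), `split` (`ratios`, `seed`) and `mode`. Validation is
#' structural and runs before any computation; command functions check the
#' path entries they actually need.
#'
#' @param path YAML manifest path.
#' @return A `run_manifest` list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("manifest not found: ", path))
  m <- yaml::read_yaml(path)
  validate_manifest(m)
}

#' @rdname read_manifest
#' @param manifest A manifest list (already parsed).
#' @export
validate_manifest <- function(manifest) {
  if (!is.list(manifest)) rlang::abort("manifest must be a YAML mapping")
  known <- c("paths", "synthetic", "profile", "train", "split", "mode",
             "seeds")
  unknown <- setdiff(names(manifest), known)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown manifest sections: ",
                        paste(unknown, collapse = ", ")))
  }
  if (!is.null(manifest$mode)) {
    rlang::arg_match0(manifest$mode,
                      c("adaptation", "teacher_only", "student_only"))
  }
  if (!is.null(manifest$split$ratios)) {
    r <- manifest$split$ratios
    if (length(r) != 3 || abs(sum(r) - 1) > 1e-8) {
      rlang::abort("split ratios must be three proportions summing to 1")
    }
  }
  structure(manifest, class = c("run_manifest", "list"))
}

manifest_path <- function(manifest, key, required = TRUE) {
  p <- manifest$paths[[key]]
  if (is.null(p) && required) {
    rlang::abort(paste0("manifest paths section needs an entry '", key, "'"))
  }
  p
}

manifest_synthetic_spec <- function(manifest) {
  args <- manifest$synthetic %||% list()
  for (fld in c("drug_len", "target_len", "kd_positive", "kd_negative")) {
    if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
  }
  do.call(synthetic_spec, args)
}

manifest_train_config <- function(manifest, mode = NULL) {
  args <- manifest$train %||% list()
  if (!is.null(mode)) args$mode <- mode
  do.call(train_config, args)
}

manifest_profile <- function(manifest) {
  args <- manifest$profile %||% list()
  epochs <- args$epochs %||% (manifest$train$epochs %||% 10L)
  seed <- manifest$train$seed %||% 1L
  tiny_profile(epochs = as.integer(epochs), seed = as.integer(seed))
}

write_provenance <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(manifest), file.path(out_dir, "manifest.yaml"))
}

#' Pipeline commands
#'
#' Four commands tie the modules into a runnable pipeline; each takes a
#' validated manifest, validates the paths it needs, writes its artifacts
#' under the manifest's output directory together with a copy of the
#' resolved manifest, and returns its main result invisibly-friendly.
#'
#' * `cmd_simulate()` — generates a synthetic corpus, splits it 7:1:2 and
#'   writes `corpus.csv` plus per-split CSVs in the standard dialect.
#' * `cmd_cache()` — precomputes the frozen-teacher feature cache for
#'   every target in the data; idempotent on re-run; refuses a store built
#'   under a different teacher.
#' * `cmd_train()` — trains per the manifest (optionally over several
#'   seeds, aggregating metrics) and writes the history CSV, a checkpoint
#'   RDS with embedded config, and the evaluation report JSON.
#' * `cmd_evaluate()` — evaluates a saved checkpoint on the test split and
#'   optionally on the cold subsets.
#'
#' The mock teacher used by the desk-scale pipeline is reconstructed
#' deterministically from the manifest seed, so caches and runs are
#' reproducible end to end.
#'
#' @param manifest A `run_manifest` (or path to one).
#' @return `cmd_simulate`: the corpus list; `cmd_cache`: the cache;
#'   `cmd_train`: a `dti_run` (or list of runs plus aggregate);
#'   `cmd_evaluate`: a metric tibble.
#' @name pipeline_commands
NULL

as_manifest <- function(manifest) {
  if (is.character(manifest)) read_manifest(manifest) else
    validate_manifest(manifest)
}

manifest_teacher <- function(manifest) {
  kind <- manifest$synthetic$teacher %||% "motif_oracle"
  seed <- manifest$synthetic$seed %||% 1L
  motif <- manifest$synthetic$target_motif %||% "HWH"
  make_mock_teacher(kind, dims = 24L, oracle_kmer = motif,
                    seed = as.integer(seed))
}

#' @rdname pipeline_commands
#' @export
cmd_simulate <- function(manifest) {
  manifest <- as_manifest(manifest)
  data_dir <- manifest_path(manifest, "data")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- manifest_synthetic_spec(manifest)
  corpus <- generate_synthetic_corpus(spec)
  write_interaction_table(corpus$records, file.path(data_dir, "corpus.csv"))
  split_seed <- manifest$split$seed %||% spec$seed
  ratios <- unlist(manifest$split$ratios %||% c(0.7, 0.1, 0.2))
  bundle <- split_dataset(corpus$records, ratios = ratios, seed = split_seed,
                          provenance = "synthetic")
  for (nm in c("train", "valid", "test")) {
    write_interaction_table(bundle[[nm]], file.path(data_dir,
                                                    paste0(nm, ".csv")))
  }
  write_provenance(manifest, data_dir)
  corpus
}

load_manifest_bundle <- function(manifest) {
  data_dir <- manifest_path(manifest, "data")
  load_split_files(
    file.path(data_dir, "train.csv"),
    file.path(data_dir, "valid.csv"),
    file.path(data_dir, "test.csv"),
    provenance = "synthetic"
  )
}

#' @rdname pipeline_commands
#' @export
cmd_cache <- function(manifest) {
  manifest <- as_manifest(manifest)
  cache_path <- manifest_path(manifest, "cache")
  bundle <- load_manifest_bundle(manifest)
  teacher <- manifest_teacher(manifest)
  profile <- manifest_profile(manifest)
  targets <- unique(c(bundle$train$sequence, bundle$valid$sequence,
                      bundle$test$sequence))
  precompute_teacher_cache(targets, teacher, store_path = cache_path,
                           max_len = profile$max_target_len)
}

#' @rdname pipeline_commands
#' @param seeds Integer vector of run seeds; more than one triggers
#'   multi-seed aggregation.
#' @export
cmd_train <- function(manifest, seeds = NULL) {
  manifest <- as_manifest(manifest)
  out_dir <- manifest_path(manifest, "output")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- load_manifest_bundle(manifest)
  profile <- manifest_profile(manifest)
  mode <- manifest$mode %||% "adaptation"
  cache <- if (mode != "student_only") {
    load_teacher_cache(manifest_path(manifest, "cache"))
  }
  seeds <- as.integer(seeds %||% manifest$seeds %||%
                        (manifest$train$seed %||% 1L))
  runs <- purrr::map(seeds, function(s) {
    config <- manifest_train_config(manifest, mode = mode)
    config$seed <- s
    run <- ablation_fit(mode, bundle, config, profile, cache = cache)
    readr::write_csv(run$history,
                     file.path(out_dir, sprintf("history_seed%d.csv", s)),
                     progress = FALSE)
    saveRDS(list(run = run,
                 config_json = jsonlite::toJSON(unclass(run$config),
                                                auto_unbox = TRUE)),
            file.path(out_dir, sprintf("checkpoint_seed%d.rds", s)))
    run
  })
  reports <- purrr::map(runs, function(run) {
    evaluate_split(run, bundle$test, cache = cache)
  })
  report <- if (length(runs) > 1L) {
    agg <- aggregate_runs(reports)
    readr::write_csv(agg, file.path(out_dir, "aggregate.csv"),
                     progress = FALSE)
    agg
  } else {
    reports[[1]]
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(manifest, out_dir)
  if (length(runs) == 1L) runs[[1]] else list(runs = runs, report = report)
}

#' @rdname pipeline_commands
#' @param checkpoint Path to a checkpoint RDS written by `cmd_train()`.
#' @param cold Also evaluate the cold-drug/target/binding subsets.
#' @export
cmd_evaluate <- function(manifest, checkpoint, cold = FALSE) {
  manifest <- as_manifest(manifest)
  if (!file.exists(checkpoint)) {
    rlang::abort(paste0("checkpoint not found: ", checkpoint))
  }
  run <- readRDS(checkpoint)$run
  bundle <- load_manifest_bundle(manifest)
  cache <- if (run$config$mode != "student_only") {
    load_teacher_cache(manifest_path(manifest, "cache"))
  }
  report <- dplyr::mutate(
    evaluate_split(run, bundle$test, cache = cache),
    subset = "test", n = nrow(bundle$test), .before = 1
  )
  if (isTRUE(cold)) {
    report <- dplyr::bind_rows(
      report, evaluate_cold_splits(run, bundle, cache = cache)
    )
  }
  out_dir <- manifest_path(manifest, "output", required = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
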