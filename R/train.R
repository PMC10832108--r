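#' Training configuration
#'
#' The optimization recipe: AdamW (decoupled weight decay) with a cosine
#' annealing learning-rate schedule over the full epoch budget, binary
#' cross-entropy computed on logits, no class-imbalance sampler, and
#' checkpoint selection by validation AUPRC (ties resolved to the earliest
#' epoch). Defaults follow the full-scale recipe: learning rate 1e-4, 50
#' epochs, batch size 32.
#'
#' @param learning_rate Base AdamW learning rate.
#' @param epochs Training epochs; the cosine schedule spans all of them.
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled weight decay on weight matrices (biases,
#'   layer norms and the gate scalar are exempt).
#' @param mixed_precision Must be FALSE: computation is double precision
#'   throughout; there is no reduced-precision path.
#' @param seed Seed governing shuffling, dropout and initialization inside
#'   [fit_dti()].
#' @param mode Ablation mode, one of `"adaptation"`, `"teacher_only"`,
#'   `"student_only"`.
#' @param cache_path Optional path to a persisted teacher cache.
#' @param cache_fallback Whether a cache miss may be recomputed live
#'   (default FALSE: misses are errors naming the target).
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 50L, batch_size = 32L,
                         weight_decay = 0.01, mixed_precision = FALSE,
                         seed = 1L,
                         mode = c("adaptation", "teacher_only", "student_only"),
                         cache_path = NULL, cache_fallback = FALSE) {
  mode <- rlang::arg_match(mode)
  if (epochs < 1 || batch_size < 1) {
    rlang::abort("epochs and batch_size must be positive")
  }
  if (isTRUE(mixed_precision)) {
    rlang::abort("mixed precision is not available; computation is double precision")
  }
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), weight_decay = weight_decay,
         mixed_precision = FALSE, seed = as.integer(seed), mode = mode,
         cache_path = cache_path, cache_fallback = isTRUE(cache_fallback)),
    class = "train_config"
  )
}

#' Fit a drug-target interaction model
#'
#' Trains the drug encoder (when trainable), the student encoder, the gate
#' and projections, and the interaction head with AdamW under a cosine
#' annealing schedule, minimizing binary cross-entropy on logits. The
#' frozen teacher participates only through its cached class-token
#' features; its weights are never part of the optimizer state. After each
#' epoch the model is scored on the validation split (evaluation mode) and
#' the checkpoint maximizing validation AUPRC is retained, earliest epoch
#' winning ties. The run is deterministic for a fixed `config$seed`.
#'
#' @param model A [dti_model()].
#' @param bundle A `split_bundle` with train/valid/test tibbles.
#' @param config A [train_config()]; its `mode` must match the model's.
#' @param cache A `teacher_cache` (required when the model has a teacher
#'   branch, unless a live `teacher` is supplied instead).
#' @param teacher Optional frozen teacher used live: when no cache is
#'   given, teacher class tokens are computed by forward passes instead of
#'   lookups. Cached and live paths produce bit-identical features, hence
#'   identical loss trajectories under a fixed seed.
#' @return A `dti_run`: the best model, the per-epoch history tibble
#'   (`epoch`, `lr`, `train_loss`, `valid_auroc`, `valid_auprc`, `lambda`)
#'   and the selection epoch.
#' @export
fit_dti <- function(model, bundle, config, cache = NULL, teacher = NULL) {
  stopifnot(inherits(model, "dti_model"), inherits(config, "train_config"))
  if (!identical(model$mode, config$mode)) {
    rlang::abort("config mode does not match the model mode")
  }
  train_prep <- prepare_records(model, bundle$train, cache, teacher = teacher)
  valid_prep <- prepare_records(model, bundle$valid, cache, teacher = teacher)

  params <- model_trainable_params(model)
  opt <- adamw_state(params)
  decay_mask <- default_decay_mask(params)
  history <- vector("list", config$epochs)
  best <- list(auprc = -Inf, epoch = NA_integer_, params = NULL)

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- cosine_lr(config$learning_rate, epoch, config$epochs)
      order <- sample.int(train_prep$n)
      starts <- seq(1L, train_prep$n, by = config$batch_size)
      losses <- numeric(length(starts))
      for (si in seq_along(starts)) {
        idx <- order[starts[si]:min(starts[si] + config$batch_size - 1L,
                                    train_prep$n)]
        batch <- subset_batch(train_prep, idx)
        model <- model_set_params(model, params)
        fwd <- model_forward(model, batch, training = TRUE, want_cache = TRUE)
        loss_grad <- bce_with_logits(fwd$logits, batch$labels)
        losses[si] <- loss_grad$loss
        grads <- model_backward(model, fwd, loss_grad$grad)
        step <- adamw_step(params, grads, opt, lr = lr,
                           weight_decay = config$weight_decay,
                           decay_mask = decay_mask)
        params <- step$params
        opt <- step$state
      }
      model <- model_set_params(model, params)
      val_scores <- score_prepared(model, valid_prep, config$batch_size)
      val_auroc <- auroc(valid_prep$labels, val_scores)
      val_auprc <- auprc(valid_prep$labels, val_scores)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        valid_auroc = val_auroc, valid_auprc = val_auprc,
        lambda = if (is.null(model$lambda)) NA_real_ else model$lambda
      )
      if (val_auprc > best$auprc) {
        best <- list(auprc = val_auprc, epoch = epoch, params = params)
      }
    }
  })
  model <- model_set_params(model, best$params)
  structure(
    list(
      model = model,
      history = dplyr::bind_rows(history),
      best_epoch = best$epoch,
      best_valid_auprc = best$auprc,
      config = config
    ),
    class = "dti_run"
  )
}

# batched eval-mode scoring of a prepared record set
score_prepared <- function(model, prep, batch_size) {
  scores <- numeric(prep$n)
  starts <- seq(1L, prep$n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, prep$n)
    fwd <- model_forward(model, subset_batch(prep, idx), training = FALSE)
    scores[idx] <- sigmoid(fwd$logits)
  }
  scores
}

#' @export
print.dti_run <- function(x, ...) {
  cat("<dti_run> mode ", x$config$mode, ", ", nrow(x$history), " epochs, ",
      "best valid AUPRC ", format(x$best_valid_auprc, digits = 4),
      " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Fit an ablation variant
#'
#' Convenience wrapper that assembles the model for one ablation mode and
#' trains it. The modes are structurally distinct models, not runtime
#' pinnings of the gate: `teacher_only` performs linear probing of cached
#' teacher features (frozen drug encoder, no student; only projections and
#' the head update) and `student_only` contains no teacher branch at all,
#' so neither variant carries dead-weight parameters of the unused branch.
#'
#' @param mode Ablation mode.
#' @param bundle A `split_bundle`.
#' @param config A [train_config()] (its `mode` field is overridden).
#' @param profile A [tiny_profile()]-style list of component configs.
#' @param cache A `teacher_cache` (not needed for `student_only`).
#' @param model_seed Seed for model initialization (defaults to
#'   `config$seed`).
#' @return A `dti_run`.
#' @export
ablation_fit <- function(mode, bundle, config, profile, cache = NULL,
                         model_seed = NULL) {
  config$mode <- rlang::arg_match0(
    mode, c("adaptation", "teacher_only", "student_only")
  )
  model <- profile_model(profile, mode = config$mode,
                         seed = model_seed %||% config$seed)
  fit_dti(model, bundle, config, cache = cache)
}

#' Aggregate metrics over repeated seeded runs
#'
#' Summarizes per-run metric rows (as produced by [evaluate_split()] or
#' [glance.dti_run()]) across two or more runs that differ only in seed:
#' per-metric sample mean and sample standard deviation (n - 1 denominator),
#' with a `mean ± SD` formatted string per metric.
#'
#' @param reports A tibble (or list of one-row tibbles) of per-run metrics.
#' @return A tibble with one row per metric: `metric`, `mean`, `sd`,
#'   `formatted`, `n_runs`.
#' @examples
#' aggregate_runs(tibble::tibble(auprc = c(0.6, 0.8)))
#' @export
aggregate_runs <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) {
    reports <- dplyr::bind_rows(reports)
  }
  if (nrow(reports) < 2L) {
    rlang::abort("aggregation needs at least two runs")
  }
  numeric_cols <- names(reports)[purrr::map_lgl(reports, is.numeric)]
  numeric_cols <- setdiff(numeric_cols, c("n_pos", "n_neg", "threshold",
                                          "epoch", "best_epoch", "seed"))
  out <- tidyr::pivot_longer(reports[numeric_cols],
                             cols = dplyr::everything(),
                             names_to = "metric", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$metric),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n_runs = dplyr::n(), .groups = "drop"
  )
  dplyr::mutate(
    out,
    formatted = sprintf("%.3f ± %.3f", .data$mean, .data$sd)
  )
}

# ---- broom-style accessors -------------------------------------------------

#' Tidy the per-epoch history of a training run
#'
#' @param x A `dti_run`.
#' @param ... Unused.
#' @return The history tibble: one row per epoch with the learning rate,
#'   training loss, validation AUROC/AUPRC and the gate value lambda.
#' @export
tidy.dti_run <- function(x, ...) {
  x$history
}

#' One-row summary of a training run
#'
#' @param x A `dti_run`.
#' @param ... Unused.
#' @return Tibble with `mode`, `epochs`, `best_epoch`, `best_valid_auprc`,
#'   final training loss and final lambda.
#' @export
glance.dti_run <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    mode = x$config$mode,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_valid_auprc = x$best_valid_auprc,
    final_train_loss = last$train_loss,
    final_lambda = last$lambda
  )
}

#' Plot a training run
#'
#' Line panels of the per-epoch training loss, validation AUROC/AUPRC and
#' (when present) the adaptation parameter lambda.
#'
#' @param object A `dti_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dti_run <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(
    object$history,
    cols = c("train_loss", "valid_auroc", "valid_auprc", "lambda"),
    names_to = "series", values_to = "value"
  )
  hist_long <- dplyr::filter(hist_long, !is.na(.data$value))
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training history (dashed: selected epoch)") +
    ggplot2::theme_minimal()
}
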