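# Short training runs on the miniature profile; each takes a few seconds.

fit_mini <- function(mode = "adaptation", epochs = 2L, seed = 13L,
                     corpus = mini_corpus(), teacher = mini_teacher(),
                     live = FALSE) {
  profile <- mini_profile(dropout = 0.1, epochs = epochs, seed = seed)
  bundle <- split_dataset(corpus$records, seed = 21)
  model <- mini_model(mode = mode, seed = seed, dropout = 0.1,
                      profile = profile)
  config <- profile$train
  config$mode <- mode
  config$seed <- seed
  if (live) {
    run <- fit_dti(model, bundle, config, teacher = teacher)
  } else {
    cache <- if (mode == "student_only") NULL else mini_cache(corpus, teacher)
    run <- fit_dti(model, bundle, config, cache = cache)
  }
  list(run = run, bundle = bundle,
       cache = if (mode == "student_only") NULL else mini_cache(corpus, teacher))
}

test_that("training configuration validates its recipe", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$epochs, 50L)
  expect_equal(cfg$batch_size, 32L)
  expect_false(cfg$mixed_precision)
  expect_error(train_config(mixed_precision = TRUE), "double precision")
  expect_error(train_config(epochs = 0), "positive")
  # cosine annealing starts at the base rate and decays monotonically
  lrs <- purrr::map_dbl(1:50, ~ cosine_lr(1e-4, .x, 50))
  expect_equal(lrs[1], 1e-4)
  expect_true(all(diff(lrs) < 0))
  expect_gt(lrs[50], 0)
})

test_that("identical seeds reproduce the full loss trajectory bit-for-bit", {
  a <- fit_mini(epochs = 2L, seed = 13L)$run
  b <- fit_mini(epochs = 2L, seed = 13L)$run
  expect_identical(a$history, b$history)
  expect_identical(tree_digest(model_trainable_params(a$model)),
                   tree_digest(model_trainable_params(b$model)))
  c <- fit_mini(epochs = 2L, seed = 14L)$run
  expect_false(identical(a$history$train_loss, c$history$train_loss))
})

test_that("training with the cache equals training with the live teacher", {
  corpus <- mini_corpus()
  teacher <- mini_teacher()
  cached <- fit_mini(epochs = 2L, seed = 5L, corpus = corpus,
                     teacher = teacher)$run
  live <- fit_mini(epochs = 2L, seed = 5L, corpus = corpus,
                   teacher = teacher, live = TRUE)$run
  expect_identical(cached$history, live$history)
})

test_that("the teacher is frozen through every training mode", {
  corpus <- mini_corpus()
  teacher <- build_encoder(encoder_config(1, 2, 6, 12, vocab_size = 30,
                                          max_positions = 32, dropout = 0),
                           seed = 8)
  digest_before <- tree_digest(teacher$params)
  for (mode in c("adaptation", "teacher_only")) {
    fit_mini(mode = mode, epochs = 1L, corpus = corpus, teacher = teacher)
    expect_identical(tree_digest(teacher$params), digest_before)
  }
})

test_that("teacher-only training is linear probing: encoders never move", {
  corpus <- mini_corpus()
  profile <- mini_profile(dropout = 0.1, epochs = 2L)
  bundle <- split_dataset(corpus$records, seed = 21)
  model <- mini_model(mode = "teacher_only", seed = 3, profile = profile)
  drug_before <- tree_digest(model$drug_encoder$params)
  head_before <- tree_digest(model$head$params)
  config <- profile$train
  config$mode <- "teacher_only"
  run <- fit_dti(model, bundle, config, cache = mini_cache(corpus))
  expect_identical(tree_digest(run$model$drug_encoder$params), drug_before)
  expect_false(identical(tree_digest(run$model$head$params), head_before))
  expect_null(run$model$student)
  expect_setequal(names(model_trainable_params(run$model)),
                  c("f", "h", "reduce", "head"))
})

test_that("student-only models contain no teacher branch parameters", {
  model <- mini_model(mode = "student_only", seed = 3)
  tree <- model_trainable_params(model)
  expect_false(any(c("h", "lambda") %in% names(tree)))
  expect_null(model$h_proj)
  expect_null(model$lambda)
})

test_that("checkpoint selection maximizes validation AUPRC, earliest on ties", {
  out <- fit_mini(epochs = 3L, seed = 2L)
  run <- out$run
  expect_equal(run$best_epoch,
               min(which(run$history$valid_auprc ==
                           max(run$history$valid_auprc))))
  expect_equal(run$best_valid_auprc, max(run$history$valid_auprc))
  # re-evaluating the selected checkpoint reproduces its validation AUPRC
  report <- evaluate_split(run, out$bundle$valid, cache = out$cache)
  expect_equal(report$auprc, run$best_valid_auprc, tolerance = 1e-12)
  # lambda trajectory: finite, one value per epoch
  expect_equal(nrow(run$history), 3)
  expect_true(all(is.finite(run$history$lambda)))
})

test_that("missing cache entries abort with the target named", {
  corpus <- mini_corpus()
  bundle <- split_dataset(corpus$records, seed = 21)
  model <- mini_model(seed = 3)
  # cache built over the training targets only
  partial <- precompute_teacher_cache(bundle$train$sequence[1],
                                      mini_teacher(), max_len = 32L)
  config <- mini_profile(epochs = 1L)$train
  expect_error(fit_dti(model, bundle, config, cache = partial), "cache miss")
})

test_that("run aggregation reports mean and sample standard deviation", {
  agg <- aggregate_runs(tibble::tibble(auprc = c(0.6, 0.8)))
  expect_equal(agg$mean, 0.7)
  expect_equal(agg$sd, stats::sd(c(0.6, 0.8)))
  expect_equal(agg$formatted, "0.700 ± 0.141")
  # identical runs collapse to zero spread
  agg0 <- aggregate_runs(tibble::tibble(auroc = c(0.9, 0.9, 0.9)))
  expect_equal(agg0$sd, 0)
  expect_error(aggregate_runs(tibble::tibble(auprc = 0.5)), "at least two")
  # several metrics at once, count columns excluded
  multi <- aggregate_runs(tibble::tibble(
    auroc = c(0.8, 0.9), auprc = c(0.5, 0.7), n_pos = c(10L, 10L)
  ))
  expect_setequal(multi$metric, c("auroc", "auprc"))
})

test_that("tidy, glance and autoplot expose the run history", {
  run <- fit_mini(epochs = 2L, seed = 6L)$run
  td <- tidy(run)
  expect_named(td, c("epoch", "lr", "train_loss", "valid_auroc",
                     "valid_auprc", "lambda"))
  gl <- glance(run)
  expect_equal(gl$mode, "adaptation")
  expect_equal(gl$best_epoch, run$best_epoch)
  p <- autoplot(run)
  expect_s3_class(p, "ggplot")
})
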