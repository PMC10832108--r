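test_that("corpus generation is reproducible and validates its spec", {
  spec <- synthetic_spec(n_drugs = 30, n_targets = 20, n_pairs = 50, seed = 2)
  a <- generate_synthetic_corpus(spec)
  b <- generate_synthetic_corpus(spec)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 50)
  expect_equal(nrow(a$drugs), 30)
  expect_error(synthetic_spec(n_pairs = 0), "positive")
  expect_error(synthetic_spec(label_noise = 0.6), "0.5")
  expect_error(synthetic_spec(kd_positive = c(1, 50)), "threshold")
})

test_that("noise-free labels equal the motif AND-rule and match Kd exactly", {
  corpus <- generate_synthetic_corpus(synthetic_spec(
    n_drugs = 60, n_targets = 40, n_pairs = 400, label_noise = 0, seed = 7
  ))
  recs <- corpus$records
  rule <- as.integer(
    grepl(corpus$rule$drug_motif, recs$smiles, fixed = TRUE) &
      grepl(corpus$rule$target_motif, recs$sequence, fixed = TRUE)
  )
  expect_equal(recs$label, rule)
  expect_equal(recs$label, recs$true_label)
  # Kd ranges straddle the threshold: thresholding reconstructs every label
  expect_equal(label_from_kd(recs$kd), recs$label)
  # and the same holds for the noisy labels of a noisy corpus
  noisy <- generate_synthetic_corpus(synthetic_spec(
    n_drugs = 60, n_targets = 40, n_pairs = 400, label_noise = 0.1, seed = 7
  ))$records
  expect_equal(label_from_kd(noisy$kd), noisy$label)
  expect_gt(sum(noisy$label != noisy$true_label), 0)
})

test_that("positive prevalence matches the independence expectation", {
  # pools as large as the pair count, so pair-level independence holds
  eps <- 0.05
  corpus <- generate_synthetic_corpus(synthetic_spec(
    n_drugs = 10000, n_targets = 10000, n_pairs = 10000,
    label_noise = eps, seed = 19
  ))
  expected <- 0.09 * (1 - eps) + 0.91 * eps
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(mean(corpus$records$label) - expected), 3 * se)
})

test_that("the motif oracle teacher exposes motif presence linearly", {
  teacher <- make_mock_teacher("motif_oracle", dims = 12, oracle_kmer = "HWH",
                               seed = 4)
  with_m <- tokenize_protein("AAHWHAA", max_len = 16)
  without <- tokenize_protein("AAAAAAA", max_len = 16)
  f1 <- encode_cls(teacher, with_m)
  f0 <- encode_cls(teacher, without)
  expect_length(f1, 12)
  # sequences differing only in motif presence differ in the motif coordinate
  expect_equal(f1[1] - f0[1], 1)

  # a linear probe on oracle features recovers motif presence perfectly
  corpus <- generate_synthetic_corpus(synthetic_spec(
    n_drugs = 10, n_targets = 60, n_pairs = 20, label_noise = 0, seed = 5
  ))
  toks <- purrr::map(corpus$targets$sequence, tokenize_protein, max_len = 60)
  feats <- encode_cls(teacher, toks)
  y <- as.integer(grepl("HWH", corpus$targets$sequence, fixed = TRUE))
  expect_gt(length(unique(y)), 1)
  probe <- stats::lm.fit(cbind(1, feats), y)
  coefs <- probe$coefficients
  coefs[is.na(coefs)] <- 0  # constant (never-seen) k-mer columns
  pred <- as.integer(cbind(1, feats) %*% coefs >= 0.5)
  expect_equal(mean(pred == y), 1.0)
})

test_that("the frozen random teacher is deterministic", {
  teacher <- make_mock_teacher("random_frozen", dims = 8, seed = 6)
  tok <- tokenize_protein("MKVHWHA", max_len = 20)
  expect_identical(encode_cls(teacher, tok), encode_cls(teacher, tok))
  teacher2 <- make_mock_teacher("random_frozen", dims = 8, seed = 6)
  expect_identical(encode_cls(teacher2, tok), encode_cls(teacher, tok))
})

test_that("the tiny profile assembles a runnable end-to-end model", {
  prof <- tiny_profile(epochs = 3L, seed = 1L)
  expect_equal(prof$head$input_dim, 2 * prof$z_dim)
  expect_equal(prof$train$epochs, 3L)
  model <- profile_model(prof, mode = "adaptation", seed = 1)
  expect_s3_class(model, "dti_model")
  # a forward pass over a few synthetic records produces probabilities
  corpus <- generate_synthetic_corpus(synthetic_spec(
    n_drugs = 10, n_targets = 8, n_pairs = 12, seed = 3
  ))
  cache <- precompute_teacher_cache(
    corpus$records$sequence,
    make_mock_teacher("motif_oracle", dims = prof$teacher_dims, seed = 1),
    max_len = prof$max_target_len
  )
  scored <- predict(model, corpus$records, cache = cache)
  expect_true(all(scored$score > 0 & scored$score < 1))
})
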