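test_that("gate initialization is uniform on [0,1) and seed-deterministic", {
  g <- init_gate(seed = 5, student_dim = 4, teacher_dim = 4, mix_dim = 4)
  expect_gte(g$lambda, 0)
  expect_lt(g$lambda, 1)
  expect_identical(
    g$lambda,
    init_gate(seed = 5, student_dim = 4, teacher_dim = 4, mix_dim = 4)$lambda
  )
  # 10,000 draws: empirical mean within 3 standard errors of 1/2
  draws <- purrr::map_dbl(1:10000, function(s) {
    withr::with_seed(s, stats::runif(1))
  })
  se <- sqrt(1 / 12 / length(draws))
  expect_lt(abs(mean(draws) - 0.5), 3 * se)
})

test_that("class-token mixing is the gated combination of both branches", {
  gate <- init_gate(seed = 1, student_dim = 2, teacher_dim = 2, mix_dim = 2,
                    identity = TRUE)
  gate$lambda <- 0.5
  expect_equal(mix_class_tokens(c(2, 0), c(0, 2), gate), c(1, 1))
  gate$lambda <- 1
  expect_equal(mix_class_tokens(c(2, 0), c(0, 2), gate), c(2, 0))
  gate$lambda <- 0
  expect_equal(mix_class_tokens(c(2, 0), c(0, 2), gate), c(0, 2))
  # dimension mismatch is an error
  expect_error(mix_class_tokens(c(1, 2, 3), c(0, 2), gate), "dimension")
})

test_that("the reduction maps the mixing space to the head width", {
  red <- reduce_spec(8, 4, seed = 2)
  x <- withr::with_seed(4, stats::rnorm(8))
  expect_length(reduce_target_feature(x, red), 4)
  # truncating identity hook returns the first entries
  red_id <- reduce_spec(8, 4, identity = TRUE)
  expect_equal(reduce_target_feature(x, red_id), x[1:4])
  expect_error(reduce_target_feature(numeric(5), red), "input dimension")
})

test_that("the teacher cache stores one entry per unique target, bit-exactly", {
  teacher <- make_mock_teacher("random_frozen", dims = 8, seed = 2)
  seqs <- c("MKVA", "HWHAL", "MKVA", "ACDEF", "HWHAL", "WYV", "MKVA", "PQR")
  cache <- precompute_teacher_cache(seqs, teacher, max_len = 16)
  expect_equal(length(ls(cache$features)), 5)  # 5 unique targets
  for (s in unique(seqs)) {
    tok <- tokenize_protein(s, max_len = 16)
    expect_identical(cache_lookup(cache, tok),
                     as.numeric(encode_cls(teacher, tok)))
  }
})

test_that("cache misses are named errors unless a fallback teacher is given", {
  teacher <- make_mock_teacher("random_frozen", dims = 8, seed = 2)
  cache <- precompute_teacher_cache("MKVA", teacher, max_len = 16)
  unseen <- tokenize_protein("GGGG", max_len = 16)
  expect_error(cache_lookup(cache, unseen), "cache miss")
  feat <- cache_lookup(cache, unseen, fallback = teacher)
  expect_identical(feat, as.numeric(encode_cls(teacher, unseen)))
  # appended: second lookup now succeeds without the fallback
  expect_identical(cache_lookup(cache, unseen), feat)
  # a fallback that does not match the fingerprint is refused
  other <- make_mock_teacher("random_frozen", dims = 8, seed = 3)
  unseen2 <- tokenize_protein("HHHH", max_len = 16)
  expect_error(cache_lookup(cache, unseen2, fallback = other), "fingerprint")
})

test_that("persisted caches are idempotent and fingerprint-guarded", {
  teacher <- make_mock_teacher("random_frozen", dims = 8, seed = 2)
  store <- withr::local_tempfile(fileext = ".rds")
  c1 <- precompute_teacher_cache(c("MKVA", "HWHAL"), teacher,
                                 store_path = store, max_len = 16)
  expect_true(file.exists(store))
  # re-running skips existing digests and adds only the new target
  c2 <- precompute_teacher_cache(c("MKVA", "HWHAL", "ACDEF"), teacher,
                                 store_path = store, max_len = 16)
  expect_equal(length(ls(c2$features)), 3)
  reloaded <- load_teacher_cache(store)
  tok <- tokenize_protein("MKVA", max_len = 16)
  expect_identical(cache_lookup(reloaded, tok), cache_lookup(c1, tok))
  # a different teacher configuration refuses the existing store
  other <- make_mock_teacher("random_frozen", dims = 8, seed = 9)
  expect_error(
    precompute_teacher_cache("MKVA", other, store_path = store, max_len = 16),
    "different teacher"
  )
})

test_that("the digest keys the exact token-id list, truncation included", {
  teacher <- make_mock_teacher("random_frozen", dims = 8, seed = 2)
  long_seq <- paste(rep("A", 50), collapse = "")
  cache <- precompute_teacher_cache(long_seq, teacher, max_len = 16)
  tok16 <- tokenize_protein(long_seq, max_len = 16)
  tok12 <- tokenize_protein(long_seq, max_len = 12)
  expect_silent(cache_lookup(cache, tok16))
  expect_error(cache_lookup(cache, tok12), "cache miss")
})
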