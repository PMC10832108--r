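test_that("closed-form parameter counts match hand sums and printed scales", {
  tiny <- encoder_config(1, 2, 8, 16, vocab_size = 5, max_positions = 4)
  expect_equal(count_parameters(tiny), 704)

  student <- student_encoder_config()
  expect_equal(count_parameters(student), 25785344)
  expect_equal(round(count_parameters(student) / 1e6), 26)

  teacher <- teacher_encoder_config()
  expect_equal(count_parameters(teacher), 419931136)
  expect_equal(round(count_parameters(teacher) / 1e6), 420)
})

test_that("closed-form counts equal enumeration over instantiated weights", {
  withr::with_seed(23, {
    for (i in 1:50) {
      heads <- sample(c(1, 2, 4), 1)
      h <- heads * sample(2:6, 1)
      cfg <- encoder_config(
        n_layers = sample(1:3, 1), n_heads = heads, hidden_dim = h,
        intermediate_dim = sample(c(4, 8, 12, 24), 1),
        vocab_size = sample(5:40, 1), max_positions = sample(4:64, 1),
        type_vocab = sample(1:3, 1),
        has_pooler = sample(c(TRUE, FALSE), 1)
      )
      enc <- build_encoder(cfg, seed = i)
      expect_equal(count_parameters(enc), count_parameters(cfg))
    }
  })
})

test_that("encoder forward has the contracted shapes and is seed-deterministic", {
  cfg <- encoder_config(1, 2, 8, 16, vocab_size = 5, max_positions = 4,
                        dropout = 0)
  enc <- build_encoder(cfg, seed = 1)
  fwd <- encoder_forward(enc, matrix(c(3L, 1L, 2L, 4L), 1), matrix(1L, 1, 4))
  expect_equal(dim(fwd$hidden), c(4, 8))
  expect_equal(length(drop(fwd$cls)), 8)
  expect_true(all(is.finite(fwd$hidden)))

  enc2 <- build_encoder(cfg, seed = 1)
  expect_identical(enc$params, enc2$params)
  enc3 <- build_encoder(cfg, seed = 2)
  expect_false(identical(enc$params, enc3$params))

  tok <- structure(list(token_ids = c(3L, 1L, 2L, 4L),
                        attention_mask = rep(1L, 4), true_length = 4L),
                   class = "token_seq")
  expect_identical(encode_cls(enc, tok), encode_cls(enc, tok))
  expect_error(
    encoder_forward(enc, matrix(1L, 1, 10), matrix(1L, 1, 10)),
    "position"
  )
  expect_error(
    encoder_forward(enc, matrix(99L, 1, 2), matrix(1L, 1, 2)),
    "vocabulary"
  )
})

test_that("full-scale student forward yields 1024-wide hidden states", {
  # one forward pass of the 26 M-parameter student over a 545-slot input
  enc <- build_encoder(student_encoder_config(), seed = 1)
  seq_str <- paste(sample(c("M", "K", "V", "A", "L"), 800, replace = TRUE),
                   collapse = "")
  tok <- tokenize_protein(seq_str, max_len = 545)
  fwd <- encoder_forward(enc, matrix(tok$token_ids, 1),
                         matrix(tok$attention_mask, 1))
  expect_equal(dim(fwd$hidden), c(545, 1024))
  expect_length(drop(fwd$cls), 1024)
})

test_that("class token is invariant to padding length", {
  enc <- build_encoder(encoder_config(2, 2, 12, 24, vocab_size = 30,
                                      max_positions = 64, dropout = 0),
                       seed = 9)
  seq_str <- "MKVAHWHALG"
  cls_by_pad <- purrr::map(c(13, 20, 40, 64), function(L) {
    encode_cls(enc, tokenize_protein(seq_str, max_len = L))
  })
  for (i in 2:4) {
    expect_lt(max(abs(cls_by_pad[[1]] - cls_by_pad[[i]])), 1e-5)
  }
})

test_that("without position signal the class token ignores token order", {
  cfg <- encoder_config(1, 2, 8, 16, vocab_size = 30, max_positions = 16,
                        dropout = 0)
  enc <- build_encoder(cfg, seed = 3)
  enc$params$pos_emb[] <- 0
  ids <- c(3L, 7L, 12L, 9L, 21L)          # CLS then four body tokens
  ids_perm <- c(3L, 21L, 7L, 9L, 12L)     # body permuted, CLS fixed
  fwd1 <- encoder_forward(enc, matrix(ids, 1), matrix(1L, 1, 5))
  fwd2 <- encoder_forward(enc, matrix(ids_perm, 1), matrix(1L, 1, 5))
  expect_lt(max(abs(drop(fwd1$cls) - drop(fwd2$cls))), 1e-10)
})

test_that("projections layer-normalize then map affinely", {
  proj <- projection_spec(8, 4, seed = 2)
  x <- withr::with_seed(1, stats::rnorm(8))
  expect_length(project_feature(x, proj), 4)
  # identity-mode hook returns the input unchanged
  idp <- projection_spec(6, 6, identity = TRUE)
  y <- withr::with_seed(2, stats::rnorm(6))
  expect_equal(project_feature(y, idp), y)
  # zero vector through LN + affine gives exactly the affine bias
  proj$params$b <- withr::with_seed(3, stats::rnorm(4))
  expect_equal(project_feature(numeric(8), proj), proj$params$b)
  expect_error(project_feature(numeric(5), proj), "input dimension")
  # drug-style projection at full scale lands in 512 dimensions
  f <- projection_spec(1024, 512, seed = 1)
  expect_length(project_feature(numeric(1024) + 1, f), 512)
})
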