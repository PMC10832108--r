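test_that("Kd labeling is strict at the threshold and monotone", {
  expect_equal(label_from_kd(29.9), 1L)
  expect_equal(label_from_kd(30), 0L)
  expect_equal(label_from_kd(10000), 0L)
  expect_error(label_from_kd(-1), "positive")
  expect_error(label_from_kd(0), "positive")
  # monotone non-increasing in kd
  kd <- sort(withr::with_seed(1, stats::runif(100, 0.01, 1000)))
  expect_true(all(diff(label_from_kd(kd)) <= 0))
})

write_dialect_csv <- function(df, path = withr::local_tempfile(
                                fileext = ".csv",
                                .local_envir = parent.frame())) {
  readr::write_csv(df, path, progress = FALSE)
  path
}

test_that("interaction tables read the standard CSV dialect", {
  path <- write_dialect_csv(tibble::tibble(
    SMILES = c("CCO", "c1ccccc1", "CCN"),
    `Target Sequence` = c("MKV", "HWHAL", "MKV"),
    Label = c(1, 0, 1)
  ))
  recs <- read_interaction_table(path)
  expect_equal(nrow(recs), 3)
  expect_named(recs, c("drug_id", "smiles", "target_id", "sequence", "label"))
  expect_equal(recs$label, c(1L, 0L, 1L))
  # shared sequence gets a shared target id
  expect_equal(recs$target_id[1], recs$target_id[3])
})

test_that("labels derive from Kd when absent, and format errors are named", {
  path <- write_dialect_csv(tibble::tibble(
    SMILES = c("CCO", "CCN"),
    `Target Sequence` = c("MKV", "HWH"),
    Kd = c(5, 300)
  ))
  recs <- read_interaction_table(path)
  expect_equal(recs$label, c(1L, 0L))
  expect_equal(recs$kd, c(5, 300))

  bad <- write_dialect_csv(tibble::tibble(SMILES = "CCO", Label = 1))
  expect_error(read_interaction_table(bad), "Target Sequence")
  bad2 <- write_dialect_csv(tibble::tibble(
    SMILES = "CCO", `Target Sequence` = "MKV", Label = 2
  ))
  expect_error(read_interaction_table(bad2), "binary")
  expect_error(read_interaction_table("no/such/file.csv"), "not found")
})

test_that("duplicated pairs are preserved and reported, not dropped", {
  path <- write_dialect_csv(tibble::tibble(
    SMILES = c("CCO", "CCO", "CCO"),
    `Target Sequence` = c("MKV", "MKV", "HWH"),
    Label = c(1, 1, 0)
  ))
  expect_message(recs <- read_interaction_table(path), "1 duplicated")
  expect_equal(nrow(recs), 3)
})

test_that("interaction tables round-trip through write and read", {
  corpus <- mini_corpus(n_pairs = 40L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_interaction_table(corpus$records, path)
  back <- read_interaction_table(path)
  expect_equal(back$smiles, corpus$records$smiles)
  expect_equal(back$sequence, corpus$records$sequence)
  expect_equal(back$label, corpus$records$label)
  expect_equal(back$kd, corpus$records$kd)
})

test_that("splits are 7:1:2 within rounding, disjoint, exhaustive, seeded", {
  recs <- mini_corpus(n_pairs = 100L)$records
  recs$row_id <- seq_len(nrow(recs))
  b <- split_dataset(recs, seed = 4)
  expect_equal(nrow(b$train), 70)
  expect_equal(nrow(b$valid), 10)
  expect_equal(nrow(b$test), 20)
  # exact tiny case
  b10 <- split_dataset(recs[1:10, ], seed = 4)
  expect_equal(purrr::map_int(b10[c("train", "valid", "test")], nrow),
               c(train = 7L, valid = 1L, test = 2L))
  # same seed twice: identical bundles
  b2 <- split_dataset(recs, seed = 4)
  expect_identical(b$train$row_id, b2$train$row_id)
  # property: disjoint and exhaustive for random sizes
  withr::with_seed(8, {
    for (n in sample(10:100, 10)) {
      bb <- split_dataset(recs[1:n, ], seed = sample.int(1e6, 1))
      ids <- c(bb$train$row_id, bb$valid$row_id, bb$test$row_id)
      expect_equal(sort(ids), 1:n)
      expect_lte(abs(nrow(bb$train) - 0.7 * n), 1)
      expect_lte(abs(nrow(bb$valid) - 0.1 * n), 1)
    }
  })
  expect_error(split_dataset(recs, ratios = c(0.5, 0.2, 0.2)), "summing to 1")
})

test_that("integrated merging concatenates train/valid but keeps tests apart", {
  recs <- mini_corpus(n_pairs = 60L)$records
  mk <- function(rows, tag) split_dataset(rows, seed = 1, provenance = tag)
  b1 <- mk(recs[1:10, ], "a")   # train 7 / valid 1 / test 2
  b2 <- mk(recs[11:30, ], "b")  # train 14 / valid 2 / test 4
  b3 <- mk(recs[31:60, ], "c")  # train 21 / valid 3 / test 6
  m <- merge_integrated(list(b1, b2, b3))
  expect_equal(nrow(m$train), 7 + 14 + 21)
  expect_equal(nrow(m$valid), 1 + 2 + 3)
  expect_named(m$tests, c("a", "b", "c"))
  expect_equal(purrr::map_int(m$tests, nrow), c(a = 2L, b = 4L, c = 6L))
  expect_error(merge_integrated(list(b1)), "at least two")

  # unique-entity counting is exact string identity across datasets
  r1 <- tibble::tibble(drug_id = "D1", smiles = c("CCO", "CCN"),
                       target_id = "T1", sequence = c("MKV", "MKV"),
                       label = c(1L, 0L))
  r2 <- tibble::tibble(drug_id = "D1", smiles = c("CCO", "CCC"),
                       target_id = "T1", sequence = c("HWH", "AAA"),
                       label = c(1L, 0L))
  m2 <- merge_integrated(list(
    split_dataset(r1, ratios = c(0.5, 0.25, 0.25), seed = 1, provenance = "x"),
    split_dataset(r2, ratios = c(0.5, 0.25, 0.25), seed = 1, provenance = "y")
  ))
  expect_equal(m2$counts$n_unique_drugs, 3)   # CCO shared
  expect_equal(m2$counts$n_unique_targets, 3) # MKV, HWH, AAA
})

test_that("cold subsets follow their definitions and containment", {
  mk_rec <- function(smi, seqs, lab = 1L) {
    tibble::tibble(drug_id = smi, smiles = smi, target_id = seqs,
                   sequence = seqs, label = lab)
  }
  bundle <- structure(list(
    train = mk_rec("A", "X"),
    valid = mk_rec("A", "X")[0, ],
    test = dplyr::bind_rows(mk_rec("B", "X"), mk_rec("A", "Y"),
                            mk_rec("B", "Y")),
    provenance = "toy"
  ), class = "split_bundle")
  cold <- extract_cold_subsets(bundle)
  expect_equal(cold$cold_drug$smiles, c("B", "B"))
  expect_equal(cold$cold_target$sequence, c("Y", "Y"))
  expect_equal(nrow(cold$cold_binding), 1)
  expect_equal(cold$cold_binding$smiles, "B")
  expect_equal(cold$cold_binding$sequence, "Y")

  # all test entities seen: all three subsets empty
  bundle$test <- mk_rec("A", "X")
  cold2 <- extract_cold_subsets(bundle)
  expect_true(all(purrr::map_int(cold2, nrow) == 0))

  # property: cold binding is contained in both cold sets, always
  withr::with_seed(17, {
    for (i in 1:20) {
      recs <- generate_synthetic_corpus(synthetic_spec(
        n_drugs = sample(5:20, 1), n_targets = sample(5:20, 1),
        n_pairs = 80, drug_len = c(4, 8), target_len = c(6, 12),
        seed = sample.int(1e6, 1)
      ))$records
      bb <- split_dataset(recs, seed = sample.int(1e6, 1))
      cc <- extract_cold_subsets(bb)
      key <- function(df) paste(df$smiles, df$sequence)
      expect_true(all(key(cc$cold_binding) %in% key(cc$cold_drug)))
      expect_true(all(key(cc$cold_binding) %in% key(cc$cold_target)))
      # and every cold-drug interaction's drug is truly unseen
      seen <- unique(c(bb$train$smiles, bb$valid$smiles))
      expect_false(any(cc$cold_drug$smiles %in% seen))
    }
  })
})
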