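test_that("read_fasta parses records, normalizes T to U, and validates", {
  fa <- write_fasta_tmp(c("m1 description here", "m2"), c("ACGU", "UUUU"))
  recs <- read_fasta(fa, kind = "miRNA")
  expect_equal(recs$id, c("m1", "m2"))
  expect_equal(recs$seq, c("ACGU", "UUUU"))
  expect_equal(recs$kind, c("miRNA", "miRNA"))

  fa2 <- write_fasta_tmp("m1", "ACGT")
  expect_equal(read_fasta(fa2, "miRNA")$seq, "ACGU")

  # multi-line sequences concatenate
  fa3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGU", "ACGU"), fa3)
  expect_equal(read_fasta(fa3, "circRNA")$seq, "ACGUACGU")

  fa_dup <- write_fasta_tmp(c("m1", "m1"), c("ACGU", "GGGG"))
  expect_error(read_fasta(fa_dup, "miRNA"), "duplicate")

  fa_bad <- write_fasta_tmp("m1", "ACGX")
  expect_error(read_fasta(fa_bad, "miRNA"), "outside")

  fa_mal <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGU", ">m1"), fa_mal)
  expect_error(read_fasta(fa_mal, "miRNA"))
})

test_that("read_interactions sniffs delimiters, dedups, checks references", {
  circ <- c("c1", "c2")
  mir <- c("m1", "m2")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "c1\tm1", "c2\tm1", "c2\tm2"), tsv)
  s <- read_interactions(tsv, circ, mir)
  expect_s3_class(s, "interaction_set")
  expect_equal(nrow(s$pairs), 3)

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("c1,m1", "c1,m1", "c2,m2"), csv)
  expect_warning(s2 <- read_interactions(csv, circ, mir), "duplicate")
  expect_equal(nrow(s2$pairs), 2)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c1\tm1\textra"), bad)
  expect_error(read_interactions(bad, circ, mir), "2 columns")

  unk <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("c9\tm1"), unk)
  expect_error(read_interactions(unk, circ, mir), "c9")
})

test_that("candidate_pool_size is exact and guards its precondition", {
  expect_identical(candidate_pool_size(2346, 962, 9905), 2246947)
  expect_identical(candidate_pool_size(1, 1, 0), 1)
  expect_identical(candidate_pool_size(10, 10, 100), 0)
  expect_error(candidate_pool_size(2, 2, 5), "exceeds")
})

test_that("sample_negatives draws disjoint unknown pairs, deterministically", {
  pairs <- tibble::tibble(
    circ_id = c("c1", "c2", "c3", "c1", "c2"),
    mirna_id = c("m1", "m2", "m3", "m4", "m1")
  )
  s <- interaction_set(pairs, circ_ids = paste0("c", 1:3),
    mirna_ids = paste0("m", 1:4))
  lab <- sample_negatives(s, ratio = 1, seed = 42)
  expect_equal(nrow(lab), 10)
  expect_equal(sum(lab$label), 5)
  neg <- lab[lab$label == 0, c("circ_id", "mirna_id")]
  expect_equal(nrow(dplyr::inner_join(neg, pairs,
    by = c("circ_id", "mirna_id"))), 0)
  expect_false(anyDuplicated(lab[, c("circ_id", "mirna_id")]) > 0)
  expect_identical(lab, sample_negatives(s, ratio = 1, seed = 42))
  expect_false(identical(lab, sample_negatives(s, ratio = 1, seed = 43)))

  # near-saturated pool still terminates (enumeration branch): pool = 7
  lab2 <- sample_negatives(s, ratio = 1.4, seed = 1)
  expect_equal(sum(lab2$label == 0), 7)
})

test_that("sample_negatives errors when the pool is exhausted", {
  grid <- interaction_set(
    tibble::tibble(circ_id = c("c1", "c1", "c2"), mirna_id = c("m1", "m2", "m1")),
    circ_ids = c("c1", "c2"), mirna_ids = c("m1", "m2")
  )
  # 2x2 grid with 3 positives leaves a pool of 1 < 6 requested
  expect_error(sample_negatives(grid, ratio = 2, seed = 1), "pool")
})

test_that("split_folds stratifies, partitions, and is reproducible", {
  lab <- tibble::tibble(
    circ_id = paste0("c", 1:10), mirna_id = paste0("m", 1:10),
    label = rep(c(0L, 1L), each = 5)
  )
  f <- split_folds(lab, k = 5, seed = 9)
  tab <- table(f$fold, f$label)
  expect_true(all(tab == 1)) # 1 positive + 1 negative per fold
  expect_setequal(f$fold, 1:5)

  f2 <- split_folds(lab[1:4, ] |>
    dplyr::mutate(label = c(0L, 0L, 1L, 1L)), k = 2, seed = 3)
  expect_true(all(table(f2$fold, f2$label) == 1))

  expect_identical(split_folds(lab, 5, 11), split_folds(lab, 5, 11))
  expect_error(split_folds(lab, k = 6, seed = 1), "smaller class")
  expect_error(split_folds(dplyr::mutate(lab, label = 1L), 2, 1), "both classes")

  # stratification invariant on an unbalanced set
  lab3 <- tibble::tibble(label = rep(c(0L, 1L), c(40, 20)))
  f3 <- split_folds(lab3, k = 5, seed = 2)
  frac <- tapply(f3$label, f3$fold, mean)
  expect_true(all(abs(frac - 1 / 3) <= 0.02 + 1e-9))
})

test_that("write_folds exports a pair_index/fold TSV", {
  lab <- split_folds(
    tibble::tibble(label = rep(c(0L, 1L), each = 4)),
    k = 2, seed = 1
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_folds(lab, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("pair_index", "fold"))
  expect_equal(back$fold, lab$fold)
})
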