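test_that("synthetic_spec validates its invariants", {
  expect_error(synthetic_spec(p_in = 0.1, p_out = 0.2), "p_out")
  expect_error(synthetic_spec(n_blocks = 90, n_mirna = 80), "n_blocks")
  expect_error(synthetic_spec(mirna_len_range = c(3L, 4L)), "window")
})

test_that("deterministic limits: p_in = 1, p_out = 0 yields exactly the block grid", {
  spec <- synthetic_spec(
    n_circ = 12L, n_mirna = 8L, n_blocks = 2L,
    p_in = 1, p_out = 0, circ_len_range = c(30L, 40L), seed = 3
  )
  b <- generate_benchmark(spec)
  lab <- b$block_labels
  blocks <- stats::setNames(lab$block, lab$id)
  expect_equal(nrow(b$interactions$pairs), 12 / 2 * 8 / 2 * 2)
  same <- blocks[b$interactions$pairs$circ_id] ==
    blocks[b$interactions$pairs$mirna_id]
  expect_true(all(same))
})

test_that("matched null removes block-edge association (chi-square) and motifs", {
  spec <- synthetic_spec(
    n_circ = 60L, n_mirna = 60L, n_blocks = 3L,
    p_in = 0.2, p_out = 0.2, motif_copies_circ = 0L,
    motif_copies_mirna = 0L, circ_len_range = c(50L, 80L), seed = 9
  )
  b <- generate_benchmark(spec)
  lab <- b$block_labels
  blocks <- stats::setNames(lab$block, lab$id)
  grid <- expand.grid(
    circ_id = b$interactions$circ_ids,
    mirna_id = b$interactions$mirna_ids,
    stringsAsFactors = FALSE
  )
  key <- paste(grid$circ_id, grid$mirna_id)
  edge_key <- paste(
    b$interactions$pairs$circ_id,
    b$interactions$pairs$mirna_id
  )
  is_edge <- key %in% edge_key
  same_block <- blocks[grid$circ_id] == blocks[grid$mirna_id]
  p <- suppressWarnings(stats::chisq.test(table(is_edge, same_block))$p.value)
  expect_gt(p, 0.01)
})

test_that("null_spec matches the planted marginal density", {
  spec <- synthetic_spec()
  ns <- null_spec(spec)
  expect_equal(ns$p_in, ns$p_out)
  cb <- rep_len(1:4, spec$n_circ)
  mb <- rep_len(1:4, spec$n_mirna)
  f_in <- mean(outer(cb, mb, `==`))
  expect_equal(ns$p_in, spec$p_in * f_in + spec$p_out * (1 - f_in))
  expect_equal(ns$motif_copies_circ, 0L)
})

test_that("benchmarks are reproducible and edge counts match expectation", {
  spec <- synthetic_spec(
    n_circ = 40L, n_mirna = 30L,
    circ_len_range = c(50L, 90L), seed = 21
  )
  b1 <- generate_benchmark(spec)
  b2 <- generate_benchmark(spec)
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$interactions$pairs, b2$interactions$pairs)

  # realized edge count within 4 SD of its binomial expectation
  cb <- rep_len(1:4, 40)
  mb <- rep_len(1:4, 30)
  same <- outer(cb, mb, `==`)
  mu <- sum(ifelse(same, spec$p_in, spec$p_out))
  sd_n <- sqrt(sum(ifelse(
    same, spec$p_in * (1 - spec$p_in),
    spec$p_out * (1 - spec$p_out)
  )))
  expect_lt(abs(nrow(b1$interactions$pairs) - mu), 4 * sd_n)

  # sequence lengths honor the stated ranges
  circ_len <- nchar(b1$sequences$seq[b1$sequences$kind == "circRNA"])
  mirna_len <- nchar(b1$sequences$seq[b1$sequences$kind == "miRNA"])
  expect_true(all(circ_len >= 50 & circ_len <= 90))
  expect_true(all(mirna_len >= 20 & mirna_len <= 22))
})

test_that("block motifs are planted into member sequences", {
  b <- small_benchmark(seed = 5)
  lab <- b$block_labels
  # recover each block's motif as the most common shared 8-mer is overkill;
  # instead check that miRNAs of one block share an 8-mer that miRNAs of the
  # other block mostly lack
  mirnas <- b$sequences[b$sequences$kind == "miRNA", ]
  blocks <- stats::setNames(lab$block, lab$id)
  b1_seqs <- mirnas$seq[blocks[mirnas$id] == 1]
  kmers <- function(s) kmer_set(s, k = 8)$members
  shared <- Reduce(intersect, lapply(b1_seqs, kmers))
  expect_gte(length(shared), 1)
})

test_that("toy graphs have their documented shapes", {
  se <- generate_toy_graph("single_edge")
  expect_equal(nrow(se$pairs), 1)
  expect_equal(length(se$circ_ids) + length(se$mirna_ids), 2)

  bb <- generate_toy_graph("two_bicliques_bridge")
  expect_equal(nrow(bb$pairs), 9)
  expect_equal(length(bb$circ_ids) + length(bb$mirna_ids), 8)

  st <- generate_toy_graph("star")
  g <- build_graph(st)
  expect_equal(unname(g$degree["c1"]), 5)
  expect_error(generate_toy_graph("ring"))
})

test_that("holdout_edges splits, preserves the union, and reproduces", {
  b <- small_benchmark(seed = 11)
  m <- nrow(b$interactions$pairs)
  ho <- holdout_edges(b, fraction = 0.2, seed = 2)
  expect_equal(nrow(ho$heldout), round(0.2 * m))
  expect_equal(nrow(ho$train$pairs) + nrow(ho$heldout), m)
  recon <- dplyr::bind_rows(ho$train$pairs, ho$heldout)
  expect_setequal(
    paste(recon$circ_id, recon$mirna_id),
    paste(b$interactions$pairs$circ_id, b$interactions$pairs$mirna_id)
  )
  ho2 <- holdout_edges(b, fraction = 0.2, seed = 2)
  expect_identical(ho$heldout, ho2$heldout)
  expect_error(holdout_edges(b, fraction = 1e-6), "empty side")
})

test_that("write_benchmark round-trips through the loaders", {
  b <- small_benchmark(seed = 13)
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  circ <- read_fasta(file.path(dir, "circrna.fasta"), "circRNA")
  mirna <- read_fasta(file.path(dir, "mirna.fasta"), "miRNA")
  expect_equal(circ$seq, b$sequences$seq[b$sequences$kind == "circRNA"])
  inter <- read_interactions(file.path(dir, "pairs.tsv"), circ$id, mirna$id)
  expect_equal(inter$pairs, b$interactions$pairs)
})
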