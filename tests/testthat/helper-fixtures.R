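# shared fixtures and oracles, built in code at test time

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_corpus <- function(n, len = 21, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("mir%03d", seq_len(n)),
    kind = "miRNA",
    seq = replicate(n, random_rna(len))
  ))
}

write_fasta_tmp <- function(ids, seqs) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# central-difference numerical gradient of a scalar function
num_grad <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta
    tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

# an untrained ae2_model wrapper around explicit parameters, for forward-pass
# arithmetic checks
manual_ae2_model <- function(params, dims, config, n = 2L) {
  structure(
    list(
      params = params,
      H = matrix(0, config$k, n),
      scaling = lapply(dims, function(d) {
        list(lo = rep(0, d), rng = rep(1, d), constant = rep(FALSE, d))
      }),
      config = config, dims = dims,
      loss_history = numeric(0), initial_loss = NA_real_
    ),
    class = "ae2_model"
  )
}

# memoized mid-size trained embedder shared by several test blocks
.fixture_cache <- new.env(parent = emptyenv())
trained_embedder <- function() {
  if (is.null(.fixture_cache$embedder)) {
    .fixture_cache$embedder <- train_mlm_embedder(
      random_corpus(50, len = 22, seed = 3),
      embedder_config(2L, 32L, 4L, epochs = 20L, seed = 4)
    )
  }
  .fixture_cache$embedder
}

# memoized small cross-validation shared by the structural pipeline tests
cached_small_cv <- function() {
  if (is.null(.fixture_cache$small_cv)) {
    b <- small_benchmark(seed = 7)
    .fixture_cache$small_cv <- list(
      bench = b,
      eval = cross_validate(b$sequences, b$interactions, fast_config(seed = 3))
    )
  }
  .fixture_cache$small_cv
}

# a small planted benchmark + fast pipeline settings for end-to-end tests
small_benchmark <- function(seed = 7) {
  generate_benchmark(synthetic_spec(
    n_circ = 36L, n_mirna = 24L, n_blocks = 2L,
    p_in = 0.4, p_out = 0.03,
    circ_len_range = c(60L, 120L), mirna_len_range = c(20L, 22L),
    seed = seed
  ))
}

fast_config <- function(...) {
  pipeline_config(
    embedder = embedder_config(
      n_layers = 1L, hidden = 16L, n_heads = 2L,
      epochs = 3L
    ),
    line_dim = 16L, line_samples_per_edge = 50,
    fusion = fusion_config(k = 8L, epochs = 40L),
    classifier = list(n_trees = 60L, max_depth = 4L),
    folds = 3L,
    ...
  )
}
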