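#' Specification of a synthetic circRNA-miRNA benchmark
#'
#' Describes a block-structured world in which the method's two assumptions
#' both hold by construction: interaction probability is driven by shared
#' block membership (`p_in` within a block versus `p_out` across blocks),
#' and block membership leaves a sequence trace (each block plants a
#' distinct motif into its members' otherwise-random sequences). Desk-scale
#' defaults are sized so the full pipeline runs in minutes on one CPU.
#'
#' @param n_circ,n_mirna Node counts (defaults 120 and 80).
#' @param n_blocks Planted communities (default 4), assigned round-robin.
#' @param p_in,p_out Within/between-block edge probabilities (defaults
#'   0.15 and 0.01); must satisfy `0 <= p_out <= p_in <= 1`.
#' @param circ_len_range circRNA length bounds in nt (default 200-600;
#'   real circRNAs span hundreds to thousands of nt).
#' @param mirna_len_range miRNA length bounds in nt (default 20-22).
#' @param motif_len Planted motif length (default 8).
#' @param motif_copies_circ,motif_copies_mirna Motif insertions per sequence
#'   (defaults 3 and 1; miRNAs are short). Zero disables the sequence
#'   signal.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_circ = 120L, n_mirna = 80L, n_blocks = 4L,
                           p_in = 0.15, p_out = 0.01,
                           circ_len_range = c(200L, 600L),
                           mirna_len_range = c(20L, 22L),
                           motif_len = 8L, motif_copies_circ = 3L,
                           motif_copies_mirna = 1L, seed = 1L) {
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  if (n_blocks > min(n_circ, n_mirna)) {
    stop("n_blocks exceeds the smaller node count", call. = FALSE)
  }
  if (min(circ_len_range, mirna_len_range) < max(motif_len, 5L)) {
    stop("sequence lengths must cover the motif and the k-mer window",
      call. = FALSE
    )
  }
  structure(
    list(
      n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
      n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
      circ_len_range = as.integer(circ_len_range),
      mirna_len_range = as.integer(mirna_len_range),
      motif_len = as.integer(motif_len),
      motif_copies_circ = as.integer(motif_copies_circ),
      motif_copies_mirna = as.integer(motif_copies_mirna),
      seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Matched null version of a synthetic spec
#'
#' Removes all planted structure while keeping the expected edge count:
#' both edge probabilities are set to the spec's marginal edge density and
#' motif insertion is disabled. Cross-validated AUC on this world should
#' sit at chance.
#'
#' @param spec A [synthetic_spec()].
#' @return A `synthetic_spec` with `p_in == p_out` and no motifs.
#' @export
null_spec <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cb <- rep_len(seq_len(spec$n_blocks), spec$n_circ)
  mb <- rep_len(seq_len(spec$n_blocks), spec$n_mirna)
  same <- outer(cb, mb, `==`)
  f_in <- mean(same)
  density <- spec$p_in * f_in + spec$p_out * (1 - f_in)
  synthetic_spec(
    n_circ = spec$n_circ, n_mirna = spec$n_mirna, n_blocks = spec$n_blocks,
    p_in = density, p_out = density,
    circ_len_range = spec$circ_len_range,
    mirna_len_range = spec$mirna_len_range,
    motif_len = spec$motif_len, motif_copies_circ = 0L,
    motif_copies_mirna = 0L, seed = spec$seed
  )
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

plant_motif <- function(seq, motif, copies) {
  if (copies == 0L) {
    return(seq)
  }
  len <- nchar(seq)
  mlen <- nchar(motif)
  for (i in seq_len(copies)) {
    start <- sample.int(len - mlen + 1L, 1L)
    substr(seq, start, start + mlen - 1L) <- motif
  }
  seq
}

#' Generate a synthetic benchmark
#'
#' Draws the world a [synthetic_spec()] describes: round-robin block
#' assignment, independent Bernoulli edges (`p_in` within block, `p_out`
#' between), one distinct random motif per block, and uniform-random
#' background sequences with the block motif overwritten at random
#' positions. Deterministic for a fixed seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_benchmark`: `sequences` (tibble of
#'   both molecule kinds), `interactions` (an [interaction_set()] whose id
#'   universes include edge-less nodes), `block_labels` (tibble `id`,
#'   `kind`, `block`) and the `spec`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    circ_ids <- sprintf("circ_%03d", seq_len(spec$n_circ))
    mirna_ids <- sprintf("mirna_%03d", seq_len(spec$n_mirna))
    circ_block <- rep_len(seq_len(spec$n_blocks), spec$n_circ)
    mirna_block <- rep_len(seq_len(spec$n_blocks), spec$n_mirna)
    # distinct motif per block
    repeat {
      motifs <- vapply(
        seq_len(spec$n_blocks),
        function(i) random_seq(spec$motif_len), character(1)
      )
      if (!anyDuplicated(motifs)) break
    }
    circ_len <- sample(
      seq(spec$circ_len_range[1], spec$circ_len_range[2]),
      spec$n_circ,
      replace = TRUE
    )
    mirna_len <- sample(
      seq(spec$mirna_len_range[1], spec$mirna_len_range[2]),
      spec$n_mirna,
      replace = TRUE
    )
    circ_seq <- vapply(seq_len(spec$n_circ), function(i) {
      plant_motif(
        random_seq(circ_len[i]), motifs[circ_block[i]],
        spec$motif_copies_circ
      )
    }, character(1))
    mirna_seq <- vapply(seq_len(spec$n_mirna), function(i) {
      plant_motif(
        random_seq(mirna_len[i]), motifs[mirna_block[i]],
        spec$motif_copies_mirna
      )
    }, character(1))
    prob <- ifelse(outer(circ_block, mirna_block, `==`), spec$p_in, spec$p_out)
    hit <- which(matrix(runif(length(prob)), nrow(prob)) < prob,
      arr.ind = TRUE
    )
    pairs <- tibble::tibble(
      circ_id = circ_ids[hit[, 1]],
      mirna_id = mirna_ids[hit[, 2]]
    )
    pairs <- dplyr::arrange(pairs, .data$circ_id, .data$mirna_id)
    sequences <- dplyr::bind_rows(
      tibble::tibble(id = circ_ids, kind = "circRNA", seq = circ_seq),
      tibble::tibble(id = mirna_ids, kind = "miRNA", seq = mirna_seq)
    )
    structure(
      list(
        sequences = sequences,
        interactions = interaction_set(pairs,
          circ_ids = circ_ids,
          mirna_ids = mirna_ids
        ),
        block_labels = tibble::tibble(
          id = c(circ_ids, mirna_ids),
          kind = rep(c("circRNA", "miRNA"), c(spec$n_circ, spec$n_mirna)),
          block = c(circ_block, mirna_block)
        ),
        spec = spec
      ),
      class = "synthetic_benchmark"
    )
  })
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat(
    "<synthetic_benchmark> ", x$spec$n_circ, " circ x ", x$spec$n_mirna,
    " mirna, ", x$spec$n_blocks, " blocks, ",
    nrow(x$interactions$pairs), " edges\n",
    sep = ""
  )
  invisible(x)
}

#' Hard-coded toy interaction graphs
#'
#' Small fixed graphs used to probe embedding behavior:
#' * `single_edge`: `c1 - m1`.
#' * `two_bicliques_bridge`: two complete 2x2 bicliques
#'   (`{c1,c2} x {m1,m2}` and `{c3,c4} x {m3,m4}`) joined by the single
#'   bridge edge `c2 - m3`: 8 vertices, 9 edges.
#' * `star`: hub `c1` connected to `m1 ... m5`.
#'
#' @param pattern One of `"single_edge"`, `"two_bicliques_bridge"`,
#'   `"star"`.
#' @return An [interaction_set()].
#' @export
generate_toy_graph <- function(pattern = c(
                                 "single_edge",
                                 "two_bicliques_bridge", "star"
                               )) {
  pattern <- match.arg(pattern)
  pairs <- switch(pattern,
    single_edge = tibble::tibble(circ_id = "c1", mirna_id = "m1"),
    two_bicliques_bridge = tibble::tibble(
      circ_id = c("c1", "c1", "c2", "c2", "c3", "c3", "c4", "c4", "c2"),
      mirna_id = c("m1", "m2", "m1", "m2", "m3", "m4", "m3", "m4", "m3")
    ),
    star = tibble::tibble(
      circ_id = "c1",
      mirna_id = paste0("m", 1:5)
    )
  )
  interaction_set(pairs)
}

#' Split known edges into training and held-out sets
#'
#' Uniform random edge split supporting ranking experiments: the held-out
#' positives are removed from the training interaction set (id universes
#' are preserved, so their endpoints may go cold).
#'
#' @param benchmark A `synthetic_benchmark` or an [interaction_set()].
#' @param fraction Fraction of edges held out, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `train` (an [interaction_set()]) and `heldout`
#'   (a tibble of pairs).
#' @export
holdout_edges <- function(benchmark, fraction, seed = 1L) {
  interactions <- if (inherits(benchmark, "synthetic_benchmark")) {
    benchmark$interactions
  } else {
    benchmark
  }
  stopifnot(inherits(interactions, "interaction_set"))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  m <- nrow(interactions$pairs)
  n_out <- round(fraction * m)
  if (n_out == 0L || n_out == m) {
    stop("holdout would leave an empty side (", n_out, " of ", m, " edges)",
      call. = FALSE
    )
  }
  idx <- withr::with_seed(seed, sample.int(m, n_out))
  list(
    train = interaction_set(interactions$pairs[-idx, ],
      circ_ids = interactions$circ_ids,
      mirna_ids = interactions$mirna_ids
    ),
    heldout = interactions$pairs[idx, ]
  )
}

#' Write a synthetic benchmark to FASTA and TSV files
#'
#' Emits the same formats the loaders consume: one FASTA per molecule kind,
#' a two-column pair TSV, and a block-label sidecar TSV.
#'
#' @param benchmark A `synthetic_benchmark`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "synthetic_benchmark"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (kd in c("circRNA", "miRNA")) {
    recs <- dplyr::filter(benchmark$sequences, .data$kind == kd)
    set <- Biostrings::BStringSet(recs$seq)
    names(set) <- recs$id
    Biostrings::writeXStringSet(
      set,
      file.path(dir, paste0(tolower(kd), ".fasta"))
    )
  }
  readr::write_tsv(benchmark$interactions$pairs,
    file.path(dir, "pairs.tsv"),
    col_names = FALSE
  )
  readr::write_tsv(benchmark$block_labels, file.path(dir, "blocks.tsv"))
  invisible(dir)
}
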