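#' Read nucleotide sequences from a FASTA file
#'
#' Reads circRNA or miRNA sequences and normalizes them to the RNA alphabet:
#' sequences are upper-cased and `T` is rewritten to `U`, so DNA-style circRNA
#' exports and RNA-style miRNA exports share one alphabet downstream.
#'
#' @param path Path to a FASTA file (multi-line sequences allowed).
#' @param kind Molecule kind, `"circRNA"` or `"miRNA"`.
#'
#' @return A tibble with columns `id` (header token before the first
#'   whitespace), `kind`, and `seq` (normalized sequence).
#'
#' @details Duplicate ids and empty sequences are errors; characters outside
#'   `A/C/G/T/U` (case-insensitive) are errors as well.
#'
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1 some miRNA", "ACGT", ">m2", "UUUU"), fa)
#' read_fasta(fa, kind = "miRNA")
#' @export
read_fasta <- function(path, kind = c("circRNA", "miRNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("FASTA header with empty id in ", path, call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_seq(unname(as.character(set)), context = ids)
  tibble::tibble(id = ids, kind = kind, seq = seqs)
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' @param seq Character vector of sequences.
#' @param context Optional labels used in error messages.
#' @return Character vector over `A/C/G/U`.
#' @keywords internal
normalize_seq <- function(seq, context = NULL) {
  out <- chartr("acgtu", "ACGUU", seq)
  out <- chartr("T", "U", out)
  if (any(!nzchar(out))) {
    bad <- if (is.null(context)) which(!nzchar(out)) else context[!nzchar(out)]
    stop("empty sequence for: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  illegal <- grepl("[^ACGU]", out)
  if (any(illegal)) {
    bad <- if (is.null(context)) which(illegal) else context[illegal]
    stop(
      "sequence contains characters outside A/C/G/T/U: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Construct an interaction set
#'
#' An interaction set holds the known circRNA-miRNA pairs together with the
#' ordered id universes of both sides. The id universes may contain "cold"
#' ids that occur in no pair (nodes with sequences but no known interaction).
#'
#' @param pairs A data frame with character columns `circ_id` and `mirna_id`.
#' @param circ_ids,mirna_ids Ordered id universes. Default: the distinct ids
#'   occurring in `pairs`, in order of first appearance.
#' @return An object of class `interaction_set`.
#' @export
interaction_set <- function(pairs,
                            circ_ids = unique(pairs$circ_id),
                            mirna_ids = unique(pairs$mirna_id)) {
  pairs <- tibble::as_tibble(pairs)[, c("circ_id", "mirna_id")]
  if (anyDuplicated(pairs)) {
    stop("duplicate pairs in interaction set", call. = FALSE)
  }
  if (anyDuplicated(circ_ids) || anyDuplicated(mirna_ids)) {
    stop("id universes must be free of duplicates", call. = FALSE)
  }
  missing_c <- setdiff(pairs$circ_id, circ_ids)
  missing_m <- setdiff(pairs$mirna_id, mirna_ids)
  if (length(missing_c) || length(missing_m)) {
    stop(
      "pairs reference ids outside the id universe: ",
      paste(c(missing_c, missing_m), collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      pairs = pairs,
      circ_ids = as.character(circ_ids),
      mirna_ids = as.character(mirna_ids)
    ),
    class = "interaction_set"
  )
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(
    "<interaction_set> ", nrow(x$pairs), " pairs, ",
    length(x$circ_ids), " circRNAs x ", length(x$mirna_ids), " miRNAs\n",
    sep = ""
  )
  invisible(x)
}

#' Read known circRNA-miRNA interaction pairs
#'
#' Reads a two-column delimited text file (circRNA id, miRNA id). The
#' delimiter (tab or comma) is sniffed from the first non-comment line;
#' lines starting with `#` are skipped. Duplicate pairs are dropped with a
#' warning; ids absent from the supplied universes are an error.
#'
#' @param path Path to the pair file.
#' @param circ_ids,mirna_ids Known id universes (typically the FASTA ids).
#' @return An [interaction_set()].
#' @export
read_interactions <- function(path, circ_ids, mirna_ids) {
  if (!file.exists(path)) {
    stop("interaction file does not exist: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    stop("interaction file contains no data lines: ", path, call. = FALSE)
  }
  delim <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    stop(
      "expected 2 columns but found ", paste(unique(nf[nf != 2L]), collapse = "/"),
      " on data line(s) ", paste(head(which(nf != 2L), 5), collapse = ", "),
      call. = FALSE
    )
  }
  pairs <- tibble::tibble(
    circ_id = trimws(vapply(fields, `[[`, character(1), 1L)),
    mirna_id = trimws(vapply(fields, `[[`, character(1), 2L))
  )
  dup <- duplicated(pairs)
  if (any(dup)) {
    warning(sum(dup), " duplicate pair(s) dropped", call. = FALSE)
    pairs <- pairs[!dup, ]
  }
  bad_c <- setdiff(pairs$circ_id, circ_ids)
  bad_m <- setdiff(pairs$mirna_id, mirna_ids)
  if (length(bad_c) || length(bad_m)) {
    stop(
      "unknown ids in interaction file: ",
      paste(c(bad_c, bad_m), collapse = ", "),
      call. = FALSE
    )
  }
  interaction_set(pairs, circ_ids = circ_ids, mirna_ids = mirna_ids)
}

#' Size of the unknown-pair candidate pool
#'
#' The number of circRNA-miRNA pairs that are not known positives:
#' `n_circ * n_mirna - n_positive`. Exact integer arithmetic (values are
#' exact in doubles far beyond any realistic dataset size).
#'
#' @param n_circ,n_mirna Node counts on each side of the bipartite graph.
#' @param n_positive Number of known interacting pairs.
#' @return The pool size as a (whole) number.
#' @examples
#' candidate_pool_size(2346, 962, 9905) # 2246947
#' @export
candidate_pool_size <- function(n_circ, n_mirna, n_positive) {
  stopifnot(length(n_circ) == 1, length(n_mirna) == 1, length(n_positive) == 1)
  n_circ <- as.double(n_circ)
  n_mirna <- as.double(n_mirna)
  n_positive <- as.double(n_positive)
  if (n_circ < 0 || n_mirna < 0 || n_positive < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  product <- n_circ * n_mirna
  if (n_positive > product) {
    stop(
      "n_positive (", n_positive, ") exceeds the grid size (", product, ")",
      call. = FALSE
    )
  }
  product - n_positive
}

#' Assemble a labeled pair set by sampling unknown pairs as negatives
#'
#' Keeps every known pair as a positive (label 1) and draws
#' `round(ratio * n_positive)` negatives (label 0) uniformly without
#' replacement from the unknown-pair pool — the standard construction for
#' interaction-prediction training sets, where unobserved pairs stand in
#' for non-interactions.
#'
#' @param interactions An [interaction_set()].
#' @param ratio Negatives per positive (default 1, balanced classes).
#' @param seed Integer seed; a fixed seed gives identical output.
#' @return A tibble with columns `circ_id`, `mirna_id`, `label` (integer 0/1)
#'   and `provenance` (`"known_positive"` / `"sampled_negative"`).
#' @details Negatives are drawn by rejection sampling against a key set of
#'   the positives when the pool is large relative to the request; when the
#'   request exceeds half the pool the complement is enumerated and sampled
#'   directly, so near-saturated grids terminate too.
#' @export
sample_negatives <- function(interactions, ratio = 1, seed = 1L) {
  stopifnot(inherits(interactions, "interaction_set"), ratio > 0)
  pairs <- interactions$pairs
  n_pos <- nrow(pairs)
  if (n_pos == 0L) stop("interaction set has no pairs", call. = FALSE)
  nc <- length(interactions$circ_ids)
  nm <- length(interactions$mirna_ids)
  pool <- candidate_pool_size(nc, nm, n_pos)
  n_neg <- round(ratio * n_pos)
  if (n_neg > pool) {
    stop(
      "requested ", n_neg, " negatives but the unknown-pair pool has only ",
      pool, call. = FALSE
    )
  }
  ci <- match(pairs$circ_id, interactions$circ_ids)
  mi <- match(pairs$mirna_id, interactions$mirna_ids)
  pos_key <- (ci - 1) * nm + mi
  neg_key <- withr::with_seed(seed, {
    if (n_neg > pool / 2) {
      # near-saturated pool: enumerate the complement and sample directly
      complement <- setdiff(seq_len(nc * nm), pos_key)
      sort(sample(complement, n_neg))
    } else {
      taken <- pos_key
      out <- integer(0)
      while (length(out) < n_neg) {
        need <- n_neg - length(out)
        cand <- (sample.int(nc, 2L * need + 8L, replace = TRUE) - 1L) * nm +
          sample.int(nm, 2L * need + 8L, replace = TRUE)
        cand <- cand[!(cand %in% taken)]
        cand <- cand[!duplicated(cand)]
        cand <- head(cand, need)
        out <- c(out, cand)
        taken <- c(taken, cand)
      }
      sort(out)
    }
  })
  neg <- tibble::tibble(
    circ_id = interactions$circ_ids[(neg_key - 1) %/% nm + 1],
    mirna_id = interactions$mirna_ids[(neg_key - 1) %% nm + 1]
  )
  dplyr::bind_rows(
    dplyr::mutate(pairs, label = 1L, provenance = "known_positive"),
    dplyr::mutate(neg, label = 0L, provenance = "sampled_negative")
  )
}

#' Assign labeled pairs to stratified cross-validation folds
#'
#' Shuffles each class independently and deals pairs round-robin over the
#' `k` folds, so the per-fold class balance matches the global balance as
#' closely as integer arithmetic allows.
#'
#' @param dataset A tibble of labeled pairs (needs a `label` column).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; fixed seed gives an identical assignment.
#' @return The input tibble with an integer `fold` column in `1:k`.
#' @export
split_folds <- function(dataset, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  counts <- table(factor(dataset$label, levels = c(0L, 1L)))
  if (any(counts == 0L)) {
    stop("dataset must contain both classes", call. = FALSE)
  }
  if (k > min(counts)) {
    stop(
      "k (", k, ") exceeds the size of the smaller class (", min(counts), ")",
      call. = FALSE
    )
  }
  fold <- integer(nrow(dataset))
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(dataset$label == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  dplyr::mutate(dataset, fold = fold)
}

#' Export fold assignments as a two-column TSV
#'
#' @param dataset A tibble carrying a `fold` column (see [split_folds()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_folds <- function(dataset, path) {
  stopifnot("fold" %in% names(dataset))
  out <- tibble::tibble(pair_index = seq_len(nrow(dataset)), fold = dataset$fold)
  readr::write_tsv(out, path)
  invisible(path)
}
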