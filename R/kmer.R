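#' Distinct k-mer set of a nucleotide sequence
#'
#' Slides a window of length `k` along the sequence with the given stride and
#' collects the distinct substrings (set semantics, no multiplicity). Windows
#' are linear by default; `circular = TRUE` lets windows wrap around the end,
#' which can matter for covalently closed circRNA molecules.
#'
#' @param seq Nucleotide string (already normalized; see [read_fasta()]).
#' @param k Window length (default 5).
#' @param stride Step between window starts (default 1).
#' @param circular Wrap windows across the sequence end? Default `FALSE`.
#' @return An object of class `kmer_set`: a list with `k` and the character
#'   vector `members`.
#' @examples
#' kmer_set("ACGUACGU", k = 5) # 4 distinct 5-mers
#' @export
kmer_set <- function(seq, k = 5L, stride = 1L, circular = FALSE) {
  stopifnot(length(seq) == 1, is.character(seq))
  k <- as.integer(k)
  stride <- as.integer(stride)
  if (k < 1L || stride < 1L) stop("k and stride must be positive", call. = FALSE)
  n <- nchar(seq)
  if (n < k) {
    stop("sequence of length ", n, " is shorter than k = ", k, call. = FALSE)
  }
  if (circular) {
    starts <- seq.int(1L, n, by = stride)
    ext <- paste0(seq, substr(seq, 1L, k - 1L))
    members <- substring(ext, starts, starts + k - 1L)
  } else {
    starts <- seq.int(1L, n - k + 1L, by = stride)
    members <- substring(seq, starts, starts + k - 1L)
  }
  structure(
    list(k = k, members = unique(members)),
    class = "kmer_set"
  )
}

#' @export
print.kmer_set <- function(x, ...) {
  cat("<kmer_set> k =", x$k, "with", length(x$members), "distinct k-mers\n")
  invisible(x)
}

#' Jaccard similarity of two k-mer sets
#'
#' `|a intersect b| / |a union b|`, the set-overlap coefficient used to
#' compare sequences of very different lengths: it depends only on which
#' k-mers occur, not on how long the sequences are.
#'
#' @param a,b `kmer_set` objects with matching `k`.
#' @return A similarity in `[0, 1]`; 1 iff the sets are equal, 0 iff disjoint.
#' @export
jaccard <- function(a, b) {
  stopifnot(inherits(a, "kmer_set"), inherits(b, "kmer_set"))
  if (a$k != b$k) {
    stop("k-mer sets have different k: ", a$k, " vs ", b$k, call. = FALSE)
  }
  if (length(a$members) == 0L || length(b$members) == 0L) {
    stop("jaccard is undefined for empty k-mer sets", call. = FALSE)
  }
  ni <- sum(a$members %in% b$members)
  ni / (length(a$members) + length(b$members) - ni)
}

#' circRNA attribute matrix of pairwise k-mer Jaccard similarities
#'
#' Each circRNA is described by its Jaccard similarity to every circRNA in
#' the corpus (including itself), so the attribute vector of molecule `a` is
#' `[J(a, e)]` over the corpus order `e`. The result is a symmetric matrix
#' with unit diagonal; row `a` is the attribute feature vector of `a`.
#'
#' @param records A tibble of circRNA sequences (columns `id`, `seq`), as
#'   returned by [read_fasta()].
#' @param k,stride,circular Passed to [kmer_set()].
#' @return A numeric matrix with the circRNA ids as both dimnames.
#' @export
circ_attribute_matrix <- function(records, k = 5L, stride = 1L, circular = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  sets <- lapply(records$seq, kmer_set, k = k, stride = stride, circular = circular)
  n <- length(sets)
  sizes <- vapply(sets, function(s) length(s$members), integer(1))
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      mi <- sets[[i]]$members
      for (j in seq.int(i + 1L, n)) {
        ninter <- sum(mi %in% sets[[j]]$members)
        m[i, j] <- m[j, i] <- ninter / (sizes[i] + sizes[j] - ninter)
      }
    }
  }
  dimnames(m) <- list(records$id, records$id)
  m
}

#' Per-pair attribute view
#'
#' Concatenates the circRNA attribute vector (its Jaccard profile row) and
#' the miRNA attribute vector (its sequence embedding) into the attribute
#' view of each candidate pair.
#'
#' @param circ_attr Matrix of circRNA attribute vectors (rows named by id).
#' @param mirna_attr Matrix of miRNA attribute vectors (rows named by id).
#' @param pairs A data frame with columns `circ_id` and `mirna_id` (one or
#'   more rows).
#' @return A numeric matrix with one row per pair,
#'   `ncol(circ_attr) + ncol(mirna_attr)` columns.
#' @export
pair_attribute_view <- function(circ_attr, mirna_attr, pairs) {
  pairs <- as.data.frame(pairs)
  ci <- match(pairs$circ_id, rownames(circ_attr))
  mi <- match(pairs$mirna_id, rownames(mirna_attr))
  if (anyNA(ci)) {
    stop(
      "unknown circRNA id(s): ",
      paste(unique(pairs$circ_id[is.na(ci)]), collapse = ", "),
      call. = FALSE
    )
  }
  if (anyNA(mi)) {
    stop(
      "unknown miRNA id(s): ",
      paste(unique(pairs$mirna_id[is.na(mi)]), collapse = ", "),
      call. = FALSE
    )
  }
  cbind(circ_attr[ci, , drop = FALSE], mirna_attr[mi, , drop = FALSE])
}
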