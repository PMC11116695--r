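#' Export a feature matrix as TSV
#'
#' Writes an attribute or embedding matrix as `id` plus tab-separated
#' floats, one row per molecule/vertex.
#'
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  df <- tibble::as_tibble(m, .name_repair = ~ paste0("V", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(id = rownames(m)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Import a feature matrix from TSV
#'
#' @param path A TSV written by [write_feature_matrix()] (first column id,
#'   remaining columns numeric).
#' @return Numeric matrix with ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Import node embeddings in word2vec text format
#'
#' Reads the plain-text embedding format used by word2vec-family tools: a
#' header line `n_vectors dim` followed by one line per vertex,
#' space-separated (`id v1 v2 ...`).
#'
#' @param path Path to the text file.
#' @return Numeric matrix with ids as rownames.
#' @export
read_embedding_w2v <- function(path) {
  lines <- readr::read_lines(path)
  header <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  if (length(header) != 2L || anyNA(header)) {
    stop("not a word2vec text file: bad header line", call. = FALSE)
  }
  body <- strsplit(trimws(lines[-1]), "\\s+")
  body <- body[lengths(body) > 0]
  if (length(body) != header[1]) {
    stop(
      "header promises ", header[1], " vectors but file has ", length(body),
      call. = FALSE
    )
  }
  ids <- vapply(body, `[[`, character(1), 1L)
  m <- do.call(rbind, lapply(body, function(x) as.numeric(x[-1])))
  if (ncol(m) != header[2] || anyNA(m)) {
    stop("embedding rows do not match the declared dimension", call. = FALSE)
  }
  rownames(m) <- ids
  m
}

#' Load pipeline settings from a key-value text file
#'
#' Reads `key = value` lines (`#` comments allowed) and applies them over
#' [pipeline_config()] defaults. Keys use the flat names of the top-level
#' config plus `embedder.` / `fusion.` / `classifier.` prefixes for the
#' nested blocks, e.g.:
#'
#' ```
#' folds = 10
#' leakage_mode = full_graph
#' line_dim = 64
#' embedder.epochs = 50
#' classifier.n_trees = 500
#' ```
#'
#' @param path Path to the config file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
      call. = FALSE
    )
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[[`, character(1), 2L))
  parse_val <- function(v) {
    if (grepl("^(true|false)$", v, ignore.case = TRUE)) {
      return(toupper(v) == "TRUE")
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) {
      return(if (num == round(num)) as.integer(num) else num)
    }
    v
  }
  args <- list()
  nested <- list(embedder = list(), fusion = list(), classifier = list())
  for (i in seq_along(keys)) {
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% names(nested)) {
      nested[[parts[1]]][[parts[2]]] <- parse_val(vals[i])
    } else {
      args[[keys[i]]] <- parse_val(vals[i])
    }
  }
  if (length(nested$embedder)) {
    args$embedder <- do.call(embedder_config, nested$embedder)
  }
  if (length(nested$fusion)) {
    args$fusion <- do.call(fusion_config, nested$fusion)
  }
  if (length(nested$classifier)) args$classifier <- nested$classifier
  do.call(pipeline_config, args)
}
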