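#' Build the bipartite interaction graph
#'
#' Turns an [interaction_set()] into the undirected bipartite graph
#' `G = (V, E)` whose vertices are the circRNA and miRNA ids (circ first,
#' then miRNA, in universe order) and whose edges are the known pairs with
#' unit weight. Ids in the universe that occur in no pair are kept as
#' "cold" vertices: they stay in the vertex set but take no part in
#' embedding training and receive the zero vector.
#'
#' @param interactions An [interaction_set()].
#' @return An object of class `interaction_graph`: vertex ids and kinds,
#'   an edge tibble (`src`, `dst`, `weight`; 1-based vertex indices),
#'   weighted degrees, a cold-vertex flag vector, and the noise weights
#'   `degree^(3/4)` used for negative sampling.
#' @export
build_graph <- function(interactions) {
  stopifnot(inherits(interactions, "interaction_set"))
  if (nrow(interactions$pairs) == 0L) {
    stop("cannot build a graph from an empty edge list", call. = FALSE)
  }
  vertex_ids <- c(interactions$circ_ids, interactions$mirna_ids)
  vertex_kind <- rep(
    c("circRNA", "miRNA"),
    c(length(interactions$circ_ids), length(interactions$mirna_ids))
  )
  src <- match(interactions$pairs$circ_id, vertex_ids)
  dst <- match(interactions$pairs$mirna_id, vertex_ids)
  edges <- tibble::tibble(src = src, dst = dst, weight = 1)
  degree <- numeric(length(vertex_ids))
  for (i in seq_len(nrow(edges))) {
    degree[edges$src[i]] <- degree[edges$src[i]] + edges$weight[i]
    degree[edges$dst[i]] <- degree[edges$dst[i]] + edges$weight[i]
  }
  names(degree) <- vertex_ids
  structure(
    list(
      vertex_ids = vertex_ids,
      vertex_kind = vertex_kind,
      edges = edges,
      degree = degree,
      cold = degree == 0,
      noise_weights = degree^0.75
    ),
    class = "interaction_graph"
  )
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(
    "<interaction_graph> ", length(x$vertex_ids), " vertices, ",
    nrow(x$edges), " edges (", sum(x$cold), " cold)\n",
    sep = ""
  )
  invisible(x)
}

#' Noise (negative-sampling) distribution over vertices
#'
#' The probability of drawing each vertex as a negative sample,
#' proportional to `degree^(3/4)`.
#'
#' @param graph An [build_graph()] graph.
#' @return Named numeric vector summing to 1.
#' @export
noise_distribution <- function(graph) {
  stopifnot(inherits(graph, "interaction_graph"))
  graph$noise_weights / sum(graph$noise_weights)
}

#' Draw noise vertices from the negative-sampling distribution
#'
#' Constant-time alias sampling from the `degree^(3/4)` distribution, as
#' used inside the embedding trainer; exposed so the sampler itself can be
#' checked empirically.
#'
#' @param graph An [build_graph()] graph.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Character vector of vertex ids.
#' @export
sample_noise_vertices <- function(graph, n, seed = 1L) {
  stopifnot(inherits(graph, "interaction_graph"))
  idx <- cpp_alias_sample(graph$noise_weights, as.integer(n), as.integer(seed))
  graph$vertex_ids[idx]
}

#' First-order proximity probability
#'
#' The joint probability assigned to a directly connected vertex pair:
#' `sigma(u_c . u_m) = 1 / (1 + exp(-u_c . u_m))`.
#'
#' @param u_c,u_m Embedding vectors of equal length.
#' @return A probability in (0, 1).
#' @examples
#' first_order_prob(c(0, 0), c(0, 0)) # 0.5
#' @export
first_order_prob <- function(u_c, u_m) {
  if (length(u_c) != length(u_m)) {
    stop("embedding vectors have different lengths", call. = FALSE)
  }
  plogis(sum(u_c * u_m))
}

#' Second-order proximity probability
#'
#' The probability of "context" vertex `m` given vertex `c`: a softmax of
#' context-vector scores over all vertices,
#' `exp(u'_m . u_c) / sum_k exp(u'_k . u_c)`.
#'
#' @param graph An [build_graph()] graph.
#' @param model A second-order `line_model`.
#' @param c_id,m_id Vertex ids.
#' @return A probability; the distribution over all `m` sums to 1.
#' @export
second_order_prob <- function(graph, model, c_id, m_id) {
  stopifnot(inherits(model, "line_model"))
  if (model$order != "second") {
    stop("second_order_prob needs a second-order model", call. = FALSE)
  }
  ci <- match(c_id, graph$vertex_ids)
  mi <- match(m_id, graph$vertex_ids)
  if (is.na(ci) || is.na(mi)) {
    stop("unknown vertex id: ", c_id[is.na(ci)], m_id[is.na(mi)], call. = FALSE)
  }
  scores <- drop(model$context %*% model$vertex[ci, ])
  scores <- scores - max(scores)
  unname(exp(scores[mi]) / sum(exp(scores)))
}

#' Exact (full-softmax) LINE objective
#'
#' The un-approximated training objective, enumerable only on small graphs
#' and used as the analytic/numerical-gradient oracle: first order
#' `O1 = sum_E W * log sigma(u_c . u_m)`; second order
#' `O2 = sum_E W * log p2(m | c)` with the full softmax over contexts.
#'
#' @param graph An [build_graph()] graph.
#' @param model A `line_model`.
#' @return A finite scalar (<= 0 for unit weights).
#' @export
exact_objective <- function(graph, model) {
  stopifnot(inherits(graph, "interaction_graph"), inherits(model, "line_model"))
  e <- graph$edges
  if (model$order == "first") {
    dots <- rowSums(model$vertex[e$src, , drop = FALSE] *
      model$vertex[e$dst, , drop = FALSE])
    sum(e$weight * log(plogis(dots)))
  } else {
    total <- 0
    for (i in seq_len(nrow(e))) {
      scores <- drop(model$context %*% model$vertex[e$src[i], ])
      mx <- max(scores)
      total <- total + e$weight[i] *
        (scores[e$dst[i]] - mx - log(sum(exp(scores - mx))))
    }
    total
  }
}

#' Analytic gradient of the exact LINE objective
#'
#' Closed-form gradients of [exact_objective()] with respect to every vertex
#' (and, for second order, context) vector; checked against central
#' differences in the test suite.
#'
#' @inheritParams exact_objective
#' @return A list with matrices `vertex` and (second order) `context`,
#'   shaped like the model's.
#' @export
exact_objective_grad <- function(graph, model) {
  stopifnot(inherits(graph, "interaction_graph"), inherits(model, "line_model"))
  e <- graph$edges
  dvert <- matrix(0, nrow(model$vertex), ncol(model$vertex))
  if (model$order == "first") {
    for (i in seq_len(nrow(e))) {
      uc <- model$vertex[e$src[i], ]
      um <- model$vertex[e$dst[i], ]
      coef <- e$weight[i] * (1 - plogis(sum(uc * um)))
      dvert[e$src[i], ] <- dvert[e$src[i], ] + coef * um
      dvert[e$dst[i], ] <- dvert[e$dst[i], ] + coef * uc
    }
    list(vertex = dvert)
  } else {
    dctx <- matrix(0, nrow(model$context), ncol(model$context))
    for (i in seq_len(nrow(e))) {
      uc <- model$vertex[e$src[i], ]
      scores <- drop(model$context %*% uc)
      p <- exp(scores - max(scores))
      p <- p / sum(p)
      dvert[e$src[i], ] <- dvert[e$src[i], ] + e$weight[i] *
        (model$context[e$dst[i], ] - drop(t(model$context) %*% p))
      dctx[e$dst[i], ] <- dctx[e$dst[i], ] + e$weight[i] * uc
      dctx <- dctx - e$weight[i] * outer(p, uc)
    }
    list(vertex = dvert, context = dctx)
  }
}

#' Train LINE embeddings of one proximity order
#'
#' Stochastic gradient ascent on the negative-sampled proximity objective:
#' each step samples an edge (probability proportional to its weight) and,
#' in both directions, updates the positive target and `K` noise vertices
#' drawn from the `degree^(3/4)` distribution (any draw equal to the
#' positive target is resampled). For `order = "first"` the same estimator
#' is used with vertex vectors in both roles; for `order = "second"`
#' targets use separate context vectors. The learning rate decays linearly
#' from `lr` to `lr/100` over the run. Deterministic for a fixed seed.
#'
#' @param graph An [build_graph()] graph.
#' @param dim Embedding length (per order).
#' @param order `"first"` or `"second"`.
#' @param K Negative samples per positive (default 5).
#' @param n_samples Edge-sample count; default `200 * |E|`.
#' @param lr Initial learning rate (default 0.025).
#' @param seed Integer seed.
#' @return An object of class `line_model` with matrices `vertex` (and
#'   `context` for second order), rows named by vertex id.
#' @export
train_line <- function(graph, dim, order = c("first", "second"), K = 5L,
                       n_samples = NULL, lr = 0.025, seed = 1L) {
  stopifnot(inherits(graph, "interaction_graph"), dim >= 1, K >= 1)
  order <- match.arg(order)
  if (is.null(n_samples)) n_samples <- 200 * nrow(graph$edges)
  fit <- cpp_train_line(
    edges = cbind(graph$edges$src, graph$edges$dst) - 1L,
    weights = graph$edges$weight,
    noise = graph$noise_weights,
    n_vertices = length(graph$vertex_ids),
    dim = as.integer(dim),
    order = if (order == "first") 1L else 2L,
    K = as.integer(K),
    n_samples = n_samples,
    lr0 = lr,
    seed = as.integer(seed)
  )
  vertex <- fit$vertex
  rownames(vertex) <- graph$vertex_ids
  context <- fit$context
  if (!is.null(context)) rownames(context) <- graph$vertex_ids
  if (!all(is.finite(vertex))) {
    stop("LINE training produced non-finite vertex vectors", call. = FALSE)
  }
  structure(
    list(
      dim = as.integer(dim), order = order, vertex = vertex,
      context = context, K = as.integer(K), n_samples = n_samples,
      lr = lr, seed = as.integer(seed)
    ),
    class = "line_model"
  )
}

#' Make a line_model from explicit matrices (oracle/testing constructor)
#'
#' @param vertex Vertex-vector matrix (rows = vertices).
#' @param context Optional context-vector matrix (second order).
#' @param order `"first"` or `"second"`.
#' @return A `line_model`.
#' @export
line_model <- function(vertex, context = NULL,
                       order = if (is.null(context)) "first" else "second") {
  structure(
    list(
      dim = ncol(vertex), order = order, vertex = vertex,
      context = context, K = NA_integer_, n_samples = NA_real_,
      lr = NA_real_, seed = NA_integer_
    ),
    class = "line_model"
  )
}

#' Behavioral embedding matrix of the interaction graph
#'
#' Trains an independent first-order and second-order model, each at
#' `total_dim / 2`, and concatenates them per vertex — preserving both local
#' (direct-edge) and neighborhood (shared-context) structure. Cold vertices
#' (no known interactions) receive the zero vector and are flagged.
#'
#' @param graph An [build_graph()] graph.
#' @param total_dim Total behavioral dimension (even; default 128, the
#'   empirically optimal width for this task).
#' @param K,samples_per_edge,lr Training settings shared by both orders;
#'   `n_samples = samples_per_edge * |E|`.
#' @param seed Integer seed (the two orders use `seed` and `seed + 1`).
#' @return A numeric matrix (vertices x `total_dim`, rows named by id) with
#'   attribute `cold`, a named logical flag vector.
#' @export
line_embed <- function(graph, total_dim = 128L, K = 5L,
                       samples_per_edge = 200, lr = 0.025, seed = 1L) {
  stopifnot(inherits(graph, "interaction_graph"))
  total_dim <- as.integer(total_dim)
  if (total_dim %% 2L != 0L) {
    stop("total_dim must be even (first + second order halves)", call. = FALSE)
  }
  n_samples <- samples_per_edge * nrow(graph$edges)
  half <- total_dim %/% 2L
  m1 <- train_line(graph, half, "first",
    K = K, n_samples = n_samples, lr = lr, seed = seed
  )
  m2 <- train_line(graph, half, "second",
    K = K, n_samples = n_samples, lr = lr, seed = seed + 1L
  )
  emb <- cbind(m1$vertex, m2$vertex)
  emb[graph$cold, ] <- 0
  rownames(emb) <- graph$vertex_ids
  attr(emb, "cold") <- graph$cold
  emb
}

#' Per-pair behavior view
#'
#' Concatenates the behavioral embeddings of the two endpoints of each
#' candidate pair. A pair with a cold endpoint gets zeros in that half.
#'
#' @param emb An embedding matrix from [line_embed()].
#' @param pairs A data frame with columns `circ_id` and `mirna_id`.
#' @return Numeric matrix, one row per pair, `2 * ncol(emb)` columns.
#' @export
pair_behavior_view <- function(emb, pairs) {
  pairs <- as.data.frame(pairs)
  ci <- match(pairs$circ_id, rownames(emb))
  mi <- match(pairs$mirna_id, rownames(emb))
  if (anyNA(ci) || anyNA(mi)) {
    bad <- c(pairs$circ_id[is.na(ci)], pairs$mirna_id[is.na(mi)])
    stop("unknown vertex id(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  cbind(emb[ci, , drop = FALSE], emb[mi, , drop = FALSE])
}
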