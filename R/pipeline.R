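#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end predictor. Defaults follow the
#' method's stated operating point where one exists (k-mer window 5 stride
#' 1; behavioral dimension 128; five folds; balanced negative sampling) and
#' field-conventional values elsewhere.
#'
#' @param kmer_k,kmer_stride Moving-window settings for the circRNA Jaccard
#'   profiles (defaults 5 and 1).
#' @param circular_windows Let k-mer windows wrap around the circRNA end
#'   (default `FALSE`; sensitivity-analysis option).
#' @param embedder An [embedder_config()] for the miRNA sequence embedder.
#' @param line_dim Total behavioral embedding dimension, split evenly
#'   between first- and second-order models (default 128).
#' @param line_K Negative samples per edge (default 5).
#' @param line_samples_per_edge SGD edge samples per edge (default 200).
#' @param line_lr Initial LINE learning rate (default 0.025).
#' @param fusion A [fusion_config()] for the autoencoder-in-autoencoder.
#' @param classifier Named list of [train_classifier()] hyperparameters.
#' @param folds Cross-validation folds (default 5).
#' @param negative_ratio Negatives per positive (default 1).
#' @param leakage_mode `"fold_safe"` (behavioral embeddings and fusion are
#'   fit per fold on training data only; the default) or `"full_graph"`
#'   (embeddings use every known edge, reproducing the common but leaky
#'   transductive protocol).
#' @param resample_negatives_per_fold Draw fresh training negatives inside
#'   each fold instead of fixing one negative set up front (default
#'   `FALSE`).
#' @param view_ablation `"none"`, `"attribute_only"` or `"behavior_only"`:
#'   zero out one view to measure the other's contribution.
#' @param standardize_attribute Z-score each attribute-view coordinate,
#'   fit on training folds only (default `TRUE`; Jaccard profiles live in
#'   `[0,1]` while embedder coordinates are unbounded).
#' @param threshold Probability cutoff for the thresholded metrics
#'   (default 0.5).
#' @param seed Master seed; fans out to per-stage seeds through a fixed
#'   splitting scheme.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(kmer_k = 5L, kmer_stride = 1L,
                            circular_windows = FALSE,
                            embedder = embedder_config(),
                            line_dim = 128L, line_K = 5L,
                            line_samples_per_edge = 200,
                            line_lr = 0.025,
                            fusion = fusion_config(),
                            classifier = list(),
                            folds = 5L, negative_ratio = 1,
                            leakage_mode = c("fold_safe", "full_graph"),
                            resample_negatives_per_fold = FALSE,
                            view_ablation = c(
                              "none", "attribute_only",
                              "behavior_only"
                            ),
                            standardize_attribute = TRUE,
                            threshold = 0.5,
                            seed = 1L) {
  leakage_mode <- match.arg(leakage_mode)
  view_ablation <- match.arg(view_ablation)
  if (folds < 2L) stop("folds must be at least 2", call. = FALSE)
  if (negative_ratio <= 0) stop("negative_ratio must be positive", call. = FALSE)
  cls <- utils::modifyList(
    list(
      n_trees = 300L, max_depth = 6L, learning_rate = 0.1,
      lambda = 1, gamma = 0, min_child_weight = 1
    ),
    classifier
  )
  structure(
    list(
      kmer_k = as.integer(kmer_k), kmer_stride = as.integer(kmer_stride),
      circular_windows = circular_windows, embedder = embedder,
      line_dim = as.integer(line_dim), line_K = as.integer(line_K),
      line_samples_per_edge = line_samples_per_edge, line_lr = line_lr,
      fusion = fusion, classifier = cls, folds = as.integer(folds),
      negative_ratio = negative_ratio, leakage_mode = leakage_mode,
      resample_negatives_per_fold = resample_negatives_per_fold,
      view_ablation = view_ablation,
      standardize_attribute = standardize_attribute,
      threshold = threshold, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# master seed -> named per-stage seeds (fixed fan-out so stages can be rerun
# independently); all values stay below 2^31.
stage_seeds <- function(master, folds) {
  n <- 3L + 2L * folds
  s <- withr::with_seed(master, sample.int(.Machine$integer.max - 1L, n))
  list(
    negatives = s[1], folds = s[2], embedder = s[3],
    line = s[3 + seq_len(folds)],
    fusion = s[3 + folds + seq_len(folds)]
  )
}

# ---- shared feature assembly ----------------------------------------------

split_sequences <- function(sequences, interactions) {
  circ <- dplyr::filter(sequences, .data$kind == "circRNA")
  mirna <- dplyr::filter(sequences, .data$kind == "miRNA")
  missing <- c(
    setdiff(interactions$circ_ids, circ$id),
    setdiff(interactions$mirna_ids, mirna$id)
  )
  if (length(missing)) {
    stop("no sequence for id(s): ", paste(head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  # order sequence tables by the interaction universes
  list(
    circ = circ[match(interactions$circ_ids, circ$id), ],
    mirna = mirna[match(interactions$mirna_ids, mirna$id), ]
  )
}

fit_standardizer <- function(x) {
  mu <- colMeans(x)
  sigma <- apply(x, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  list(mu = mu, sigma = sigma)
}

apply_standardizer <- function(x, st) {
  sweep(sweep(x, 2, st$mu), 2, st$sigma, "/")
}

# Assemble the two per-pair views (samples x features), applying ablation.
assemble_views <- function(pairs, circ_attr, mirna_attr, emb, ablation) {
  attr_v <- pair_attribute_view(circ_attr, mirna_attr, pairs)
  behav_v <- pair_behavior_view(emb, pairs)
  if (ablation == "attribute_only") behav_v[] <- 0
  if (ablation == "behavior_only") attr_v[] <- 0
  list(attr = attr_v, behav = behav_v)
}

# One fold (or the full fit): train fusion + classifier on training views,
# score the test views. Returns scores plus the pieces a full model keeps.
fit_score_views <- function(train_views, train_labels, test_views, config,
                            fusion_seed) {
  fus_cfg <- config$fusion
  fus_cfg$seed <- fusion_seed
  vs_train <- view_set(list(t(train_views$attr), t(train_views$behav)))
  ae2 <- train_ae2(vs_train, fus_cfg)
  feat_train <- fused_features(ae2)
  clf <- do.call(train_classifier, c(
    list(features = feat_train, labels = train_labels),
    config$classifier
  ))
  scores <- NULL
  if (!is.null(test_views)) {
    vs_test <- view_set(list(t(test_views$attr), t(test_views$behav)))
    h_test <- infer_latent(ae2, vs_test)
    scores <- predict(clf, fused_features(ae2, h_test))
  }
  list(ae2 = ae2, classifier = clf, scores = scores)
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs the complete method under stratified k-fold cross-validation:
#' negatives are sampled once, folds fixed, then per fold the behavioral
#' embeddings, the fusion network and the classifier are fit on training
#' data and the held-out fold is scored. In `fold_safe` mode (default) the
#' interaction graph seen by the embedding trainer contains no test-fold
#' edge and test latents come from [infer_latent()]; `full_graph` mode
#' reproduces the transductive protocol in which embeddings see every
#' known edge.
#'
#' @param sequences A tibble of sequences of both kinds (see
#'   [read_fasta()]).
#' @param interactions An [interaction_set()] of known pairs.
#' @param config A [pipeline_config()].
#' @return An object of class `cmi_eval`: `per_fold` metrics tibble,
#'   `summary` (mean and SD per metric), `predictions` (per-pair scores by
#'   fold), the fold-wise edge tables used for embedding training
#'   (`fold_edges`, for leakage audits) and the config.
#' @export
cross_validate <- function(sequences, interactions, config = pipeline_config()) {
  stopifnot(inherits(interactions, "interaction_set"),
    inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed, config$folds)
  seqs <- split_sequences(sequences, interactions)

  circ_attr <- circ_attribute_matrix(seqs$circ,
    k = config$kmer_k,
    stride = config$kmer_stride, circular = config$circular_windows
  )
  emb_cfg <- config$embedder
  emb_cfg$seed <- seeds$embedder
  embedder <- train_mlm_embedder(seqs$mirna, emb_cfg)
  mirna_attr <- mirna_attribute_matrix(embedder, seqs$mirna)

  labeled <- sample_negatives(interactions,
    ratio = config$negative_ratio,
    seed = seeds$negatives
  )
  labeled <- split_folds(labeled, k = config$folds, seed = seeds$folds)

  per_fold <- vector("list", config$folds)
  predictions <- vector("list", config$folds)
  fold_edges <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    test <- labeled[labeled$fold == f, ]
    train <- labeled[labeled$fold != f, ]
    if (config$resample_negatives_per_fold) {
      train_pos <- train[train$label == 1L, ]
      fresh <- sample_negatives(
        interaction_set(train_pos[, c("circ_id", "mirna_id")],
          circ_ids = interactions$circ_ids,
          mirna_ids = interactions$mirna_ids
        ),
        ratio = config$negative_ratio, seed = seeds$line[f]
      )
      train <- dplyr::mutate(fresh, fold = 0L)
    }
    edge_pairs <- if (config$leakage_mode == "fold_safe") {
      train[train$label == 1L, c("circ_id", "mirna_id")]
    } else {
      interactions$pairs
    }
    fold_edges[[f]] <- tibble::as_tibble(edge_pairs)
    graph <- build_graph(interaction_set(edge_pairs,
      circ_ids = interactions$circ_ids,
      mirna_ids = interactions$mirna_ids
    ))
    emb <- line_embed(graph,
      total_dim = config$line_dim, K = config$line_K,
      samples_per_edge = config$line_samples_per_edge,
      lr = config$line_lr, seed = seeds$line[f]
    )
    train_views <- assemble_views(
      train, circ_attr, mirna_attr, emb,
      config$view_ablation
    )
    test_views <- assemble_views(
      test, circ_attr, mirna_attr, emb,
      config$view_ablation
    )
    if (config$standardize_attribute) {
      st <- fit_standardizer(train_views$attr)
      train_views$attr <- apply_standardizer(train_views$attr, st)
      test_views$attr <- apply_standardizer(test_views$attr, st)
    }
    fit <- fit_score_views(
      train_views, train$label, test_views, config,
      seeds$fusion[f]
    )
    pred_label <- as.integer(fit$scores >= config$threshold)
    m <- metrics(confusion(test$label, pred_label))
    per_fold[[f]] <- dplyr::mutate(m,
      fold = f,
      auc = roc_auc(test$label, fit$scores),
      aupr = pr_auc(test$label, fit$scores),
      .before = 1
    )
    predictions[[f]] <- tibble::tibble(
      fold = f, circ_id = test$circ_id, mirna_id = test$mirna_id,
      label = test$label, score = fit$scores
    )
  }
  per_fold <- dplyr::bind_rows(per_fold)
  long <- tidyr::pivot_longer(per_fold, -"fold",
    names_to = "metric",
    values_to = "value"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value), sd = sd(.data$value), .groups = "drop"
  )
  structure(
    list(
      per_fold = per_fold, summary = summary,
      predictions = dplyr::bind_rows(predictions),
      fold_edges = fold_edges, config = config
    ),
    class = "cmi_eval"
  )
}

#' @export
print.cmi_eval <- function(x, ...) {
  cat(
    "<cmi_eval> ", x$config$folds, "-fold cross-validation (leakage mode: ",
    x$config$leakage_mode, ")\n",
    sep = ""
  )
  s <- x$summary
  for (m in c("acc", "prec", "rec", "f1", "mcc", "auc", "aupr")) {
    row <- s[s$metric == m, ]
    cat(sprintf(
      "  %-5s %.4f +/- %.4f\n", toupper(m), row$mean, row$sd
    ))
  }
  invisible(x)
}

#' @export
tidy.cmi_eval <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold, -"fold",
    names_to = "metric",
    values_to = "value"
  )
}

#' @export
glance.cmi_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary,
    names_from = "metric",
    values_from = c("mean", "sd"), names_glue = "{metric}_{.value}"
  )
  dplyr::mutate(wide,
    folds = x$config$folds,
    leakage_mode = x$config$leakage_mode
  )
}

#' Plot cross-validated ROC or precision-recall curves
#'
#' @param object A [cross_validate()] result.
#' @param type `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot object with one curve per fold.
#' @export
autoplot.cmi_eval <- function(object, type = c("roc", "pr"), ...) {
  type <- match.arg(type)
  pts <- dplyr::group_modify(
    dplyr::group_by(object$predictions, .data$fold),
    ~ roc_pr_points(.x$label, .x$score)
  )
  pts$fold <- factor(pts$fold)
  if (type == "roc") {
    ggplot2::ggplot(pts, ggplot2::aes(
      .data$fpr, .data$tpr,
      colour = .data$fold
    )) +
      ggplot2::geom_step() +
      ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        colour = "Fold", title = "Cross-validated ROC curves"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(pts, ggplot2::aes(
      .data$recall, .data$precision,
      colour = .data$fold
    )) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::labs(
        x = "Recall", y = "Precision", colour = "Fold",
        title = "Cross-validated precision-recall curves"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Export an evaluation report as TSV
#'
#' Writes the per-fold metrics with the mean/SD summary appended, preceded
#' by comment lines recording the protocol (folds, leakage mode, seed).
#'
#' @param x A [cross_validate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  stopifnot(inherits(x, "cmi_eval"))
  header <- c(
    paste0("# folds: ", x$config$folds),
    paste0("# leakage_mode: ", x$config$leakage_mode),
    paste0("# seed: ", x$config$seed)
  )
  readr::write_lines(header, path)
  readr::write_tsv(x$per_fold, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Fit the full pipeline on all labeled data
#'
#' Trains every stage once on the complete known-interaction set (plus
#' sampled negatives): attribute features, behavioral embeddings on the
#' full graph, fusion, classifier. The returned model scores arbitrary
#' candidate pairs of known molecules via [rank_candidates()].
#'
#' @inheritParams cross_validate
#' @return An object of class `cmi_model`.
#' @export
fit_pipeline <- function(sequences, interactions, config = pipeline_config()) {
  stopifnot(inherits(interactions, "interaction_set"),
    inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed, config$folds)
  seqs <- split_sequences(sequences, interactions)
  circ_attr <- circ_attribute_matrix(seqs$circ,
    k = config$kmer_k,
    stride = config$kmer_stride, circular = config$circular_windows
  )
  emb_cfg <- config$embedder
  emb_cfg$seed <- seeds$embedder
  embedder <- train_mlm_embedder(seqs$mirna, emb_cfg)
  mirna_attr <- mirna_attribute_matrix(embedder, seqs$mirna)
  labeled <- sample_negatives(interactions,
    ratio = config$negative_ratio,
    seed = seeds$negatives
  )
  graph <- build_graph(interactions)
  emb <- line_embed(graph,
    total_dim = config$line_dim, K = config$line_K,
    samples_per_edge = config$line_samples_per_edge,
    lr = config$line_lr, seed = seeds$line[1]
  )
  views <- assemble_views(
    labeled, circ_attr, mirna_attr, emb,
    config$view_ablation
  )
  st <- NULL
  if (config$standardize_attribute) {
    st <- fit_standardizer(views$attr)
    views$attr <- apply_standardizer(views$attr, st)
  }
  fit <- fit_score_views(views, labeled$label, NULL, config, seeds$fusion[1])
  structure(
    list(
      circ_attr = circ_attr, mirna_attr = mirna_attr, behavior = emb,
      attr_standardizer = st, ae2 = fit$ae2, classifier = fit$classifier,
      positives = interactions$pairs, config = config
    ),
    class = "cmi_model"
  )
}

#' @export
print.cmi_model <- function(x, ...) {
  cat(
    "<cmi_model> trained on ", nrow(x$positives), " known pairs; ",
    nrow(x$circ_attr), " circRNAs, ", nrow(x$mirna_attr), " miRNAs\n",
    sep = ""
  )
  invisible(x)
}

#' Score and rank candidate pairs
#'
#' Scores every candidate with the trained pipeline and returns them in
#' descending score order — the ranking used to nominate novel
#' interactions for literature or wet-lab follow-up. Tied scores are
#' ordered lexicographically by `(circ_id, mirna_id)`.
#'
#' @param model A [fit_pipeline()] model.
#' @param candidates A data frame with columns `circ_id`, `mirna_id`;
#'   must be disjoint from the training positives.
#' @param top_n Optionally keep only the first `top_n` rows.
#' @return A tibble `circ_id`, `mirna_id`, `score` sorted by decreasing
#'   score.
#' @export
rank_candidates <- function(model, candidates, top_n = NULL) {
  stopifnot(inherits(model, "cmi_model"))
  candidates <- tibble::as_tibble(candidates)[, c("circ_id", "mirna_id")]
  overlap <- dplyr::inner_join(candidates, model$positives,
    by = c("circ_id", "mirna_id")
  )
  if (nrow(overlap) > 0) {
    stop(
      "candidate(s) overlap the training positives: ",
      paste(paste(overlap$circ_id, overlap$mirna_id, sep = ":"),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  views <- assemble_views(
    candidates, model$circ_attr, model$mirna_attr,
    model$behavior, model$config$view_ablation
  )
  if (!is.null(model$attr_standardizer)) {
    views$attr <- apply_standardizer(views$attr, model$attr_standardizer)
  }
  vs <- view_set(list(t(views$attr), t(views$behav)))
  h <- infer_latent(model$ae2, vs)
  scores <- predict(model$classifier, fused_features(model$ae2, h))
  out <- dplyr::arrange(
    dplyr::mutate(candidates, score = scores),
    dplyr::desc(.data$score), .data$circ_id, .data$mirna_id
  )
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}
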