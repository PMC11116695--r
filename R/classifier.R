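#' Train the gradient-boosted-tree classifier
#'
#' Fits a boosted ensemble of depth-limited regression trees by the
#' second-order (Newton) formulation with logistic loss: each tree is grown
#' greedily on the gradient/hessian statistics of the current margin, with
#' L2-regularized leaf weights `-G/(H + lambda)` and split gain
#' `[G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda)]/2 - gamma`.
#' No row or column subsampling is used, so training is fully deterministic
#' (the `seed` argument is accepted for interface symmetry).
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Binary labels (0/1); both classes must be present.
#' @param n_trees Boosting rounds (default 300).
#' @param max_depth Maximum tree depth (default 6).
#' @param learning_rate Shrinkage per tree (default 0.1).
#' @param lambda L2 penalty on leaf weights (default 1).
#' @param gamma Minimum split gain (default 0).
#' @param min_child_weight Minimum hessian sum per child (default 1).
#' @param seed Unused (determinism is structural); kept in the signature so
#'   pipeline configs can pass one uniformly.
#' @return An object of class `cmi_gbt`.
#' @export
train_classifier <- function(features, labels, n_trees = 300L,
                             max_depth = 6L, learning_rate = 0.1,
                             lambda = 1, gamma = 0, min_child_weight = 1,
                             seed = 1L) {
  features <- as.matrix(features)
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; cannot train a classifier",
      call. = FALSE
    )
  }
  if (nrow(features) != length(labels)) {
    stop("features and labels have different lengths", call. = FALSE)
  }
  fit <- cpp_gbt_train(
    features, as.integer(labels), as.integer(n_trees),
    as.integer(max_depth), learning_rate, lambda, gamma,
    min_child_weight, 0.0
  )
  structure(
    list(
      trees = fit$trees, learning_rate = learning_rate, base_margin = 0.0,
      n_features = ncol(features),
      train_probability = plogis(fit$train_margin),
      hyper = list(
        n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
        learning_rate = learning_rate, lambda = lambda, gamma = gamma,
        min_child_weight = min_child_weight
      )
    ),
    class = "cmi_gbt"
  )
}

#' Predict interaction probabilities with a boosted-tree model
#'
#' @param object A [train_classifier()] model.
#' @param newdata Numeric matrix, samples x features.
#' @param ... Unused.
#' @return Numeric vector of class-1 probabilities.
#' @export
predict.cmi_gbt <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
      object$n_features,
      call. = FALSE
    )
  }
  plogis(cpp_gbt_predict(
    object$trees, newdata, object$learning_rate,
    object$base_margin
  ))
}

#' @export
print.cmi_gbt <- function(x, ...) {
  cat(
    "<cmi_gbt> ", length(x$trees), " trees, depth <= ", x$hyper$max_depth,
    ", eta ", x$hyper$learning_rate, "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
glance.cmi_gbt <- function(x, ...) {
  tibble::tibble(
    n_trees = length(x$trees),
    max_depth = x$hyper$max_depth,
    learning_rate = x$hyper$learning_rate,
    lambda = x$hyper$lambda,
    n_features = x$n_features
  )
}
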