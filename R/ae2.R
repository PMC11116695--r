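#' Bundle per-pair feature views for fusion
#'
#' A view set holds `V` feature matrices `X^v` (features x samples, columns
#' aligned across views): here typically `V = 2`, the attribute view and the
#' behavior view of the labeled pairs.
#'
#' @param views A list of numeric matrices, each `d_v x n` with a shared
#'   sample count `n`.
#' @return An object of class `view_set`.
#' @export
view_set <- function(views) {
  stopifnot(is.list(views), length(views) >= 1)
  views <- lapply(views, as.matrix)
  ns <- vapply(views, ncol, integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all views must share the sample count; got ",
      paste(ns, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(vapply(views, function(x) all(is.finite(x)), logical(1)))) {
    stop("views contain non-finite entries", call. = FALSE)
  }
  structure(
    list(X = views, n = ns[[1]], dims = vapply(views, nrow, integer(1))),
    class = "view_set"
  )
}

#' @export
print.view_set <- function(x, ...) {
  cat(
    "<view_set> ", length(x$X), " view(s), dims ",
    paste(x$dims, collapse = " + "), ", n = ", x$n, "\n",
    sep = ""
  )
  invisible(x)
}

#' Configuration of the autoencoder-in-autoencoder fusion network
#'
#' @param k Shared latent dimension (default 64).
#' @param C Per-view autoencoder depth, even: `C/2` encoding then `C/2`
#'   decoding sigmoid layers (default 4).
#' @param S Degradation-network depth: `S` sigmoid layers mapping the latent
#'   `H` onto each view's inner code (default 2).
#' @param lambda Balance between reconstruction (consistency) and
#'   degradation (complementarity) terms (default 1).
#' @param epochs Alternating-minimization epochs (default 200).
#' @param learning_rate Adam step size for both parameter and latent
#'   updates (default 1e-3).
#' @param inner_H_steps Latent-update steps per epoch (default 5).
#' @param seed Integer seed for initialization.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(k = 64L, C = 4L, S = 2L, lambda = 1,
                          epochs = 200L, learning_rate = 1e-3,
                          inner_H_steps = 5L, seed = 1L) {
  C <- as.integer(C)
  if (C < 2L || C %% 2L != 0L) {
    stop("C must be a positive even layer count", call. = FALSE)
  }
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  structure(
    list(
      k = as.integer(k), C = C, S = as.integer(S), lambda = lambda,
      epochs = as.integer(epochs), learning_rate = learning_rate,
      inner_H_steps = as.integer(inner_H_steps), seed = as.integer(seed)
    ),
    class = "fusion_config"
  )
}

# ---- internals -------------------------------------------------------------
# All layer maps are z_out = sigmoid(W %*% z_in + b); matrices are
# features x samples so the Frobenius-norm losses read off directly.

sigmoid_mat <- function(a) 1 / (1 + exp(-a))

# geometric interpolation of layer widths from `d` down to `k`
width_chain <- function(d, k, steps) {
  t <- seq(0, 1, length.out = steps + 1)
  pmax(1L, as.integer(round(d^(1 - t) * k^t)))
}

init_layer <- function(nin, nout) {
  list(W = glorot(nout, nin), b = numeric(nout))
}

init_ae2_params <- function(dims, config) {
  lapply(dims, function(d) {
    enc_w <- width_chain(d, config$k, config$C %/% 2L)
    chain <- c(enc_w, rev(enc_w)[-1]) # d .. k .. d
    ae <- lapply(seq_len(config$C), function(c) {
      init_layer(chain[c], chain[c + 1])
    })
    dr <- lapply(seq_len(config$S), function(s) init_layer(config$k, config$k))
    list(ae = ae, dr = dr)
  })
}

# forward through one view's autoencoder; returns all layer outputs
ae_forward_chain <- function(layers, x) {
  zs <- vector("list", length(layers) + 1L)
  zs[[1]] <- x
  for (c in seq_along(layers)) {
    zs[[c + 1]] <- sigmoid_mat(layers[[c]]$W %*% zs[[c]] +
      layers[[c]]$b)
  }
  zs
}

# Loss and gradients of the coupled objective on already-scaled views.
# Returns loss (with reconstruction/degradation parts), parameter gradients
# (same shape as params) and the latent gradient dH.
ae2_loss_grads <- function(params, Xs, H, lambda, config,
                           want_params = TRUE, want_H = TRUE) {
  mid <- config$C %/% 2L + 1L # index of the inner code in the z chain
  recon <- 0
  degr <- 0
  grads <- vector("list", length(Xs))
  dH <- matrix(0, nrow(H), ncol(H))
  for (v in seq_along(Xs)) {
    x <- Xs[[v]]
    zs <- ae_forward_chain(params[[v]]$ae, x)
    gs <- ae_forward_chain(params[[v]]$dr, H)
    z_mid <- zs[[mid]]
    z_c <- zs[[length(zs)]]
    g_s <- gs[[length(gs)]]
    recon <- recon + sum((x - z_c)^2)
    degr <- degr + sum((z_mid - g_s)^2)
    gv <- NULL
    if (want_params || want_H) {
      gv <- list(
        ae = lapply(params[[v]]$ae, function(l) {
          list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
        }),
        dr = lapply(params[[v]]$dr, function(l) {
          list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
        })
      )
      if (want_params) {
        # backprop the reconstruction + mid-injection through the autoencoder
        dz <- 2 * (z_c - x)
        for (c in rev(seq_along(params[[v]]$ae))) {
          z_out <- zs[[c + 1]]
          da <- dz * z_out * (1 - z_out)
          gv$ae[[c]]$W <- da %*% t(zs[[c]])
          gv$ae[[c]]$b <- rowSums(da)
          dz <- t(params[[v]]$ae[[c]]$W) %*% da
          if (c == mid) { # dz now sits at the inner code: add the coupling
            dz <- dz + 2 * lambda * (z_mid - g_s)
          }
        }
      }
      # degradation-network backprop (drives both its parameters and H)
      dg <- 2 * lambda * (g_s - z_mid)
      for (s in rev(seq_along(params[[v]]$dr))) {
        g_out <- gs[[s + 1]]
        da <- dg * g_out * (1 - g_out)
        gv$dr[[s]]$W <- da %*% t(gs[[s]])
        gv$dr[[s]]$b <- rowSums(da)
        dg <- t(params[[v]]$dr[[s]]$W) %*% da
      }
      if (want_H) dH <- dH + dg
    }
    grads[[v]] <- gv
  }
  list(
    loss = recon + lambda * degr, recon = recon, degr = degr,
    grads = grads, dH = dH
  )
}

# Optimize H against frozen parameters (exact block-coordinate step of the
# alternating scheme): Adam until the coupling term stops improving.
optimize_H <- function(params, z_mids, H, lambda, lr,
                       max_steps = 20000L, check_every = 100L,
                       rel_tol = 1e-8) {
  state <- adam_state(length(H))
  degr_of <- function(H) {
    sum(vapply(seq_along(z_mids), function(v) {
      gs <- ae_forward_chain(params[[v]]$dr, H)
      sum((z_mids[[v]] - gs[[length(gs)]])^2)
    }, numeric(1)))
  }
  last <- degr_of(H)
  for (s in seq_len(max_steps)) {
    dH <- h_gradient(params, z_mids, H, lambda)
    upd <- adam_step(as.numeric(H), as.numeric(dH), state, lr)
    state <- upd$state
    H <- matrix(upd$theta, nrow(H), ncol(H))
    if (s %% check_every == 0L) {
      cur <- degr_of(H)
      if (abs(last - cur) < rel_tol * (1 + abs(cur))) break
      last <- cur
    }
  }
  H
}

# gradient step on H only, with parameters (hence the inner codes) frozen
h_gradient <- function(params, z_mids, H, lambda) {
  dH <- matrix(0, nrow(H), ncol(H))
  for (v in seq_along(z_mids)) {
    gs <- ae_forward_chain(params[[v]]$dr, H)
    dg <- 2 * lambda * (gs[[length(gs)]] - z_mids[[v]])
    for (l in rev(seq_along(params[[v]]$dr))) {
      g_out <- gs[[l + 1]]
      da <- dg * g_out * (1 - g_out)
      dg <- t(params[[v]]$dr[[l]]$W) %*% da
    }
    dH <- dH + dg
  }
  dH
}

scale_fit <- function(x) {
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng, constant = hi == lo)
}

scale_apply <- function(x, sc) {
  y <- (x - sc$lo) / sc$rng
  y[sc$constant, ] <- 0.5 # constant coordinate: park at sigmoid midpoint
  pmin(pmax(y, 0), 1) # clip test-time values into the reconstructable range
}

#' Train the autoencoder-in-autoencoder fusion network
#'
#' Learns, jointly: a per-view sigmoid autoencoder whose inner code
#' compresses that view, a per-view degradation network mapping one shared
#' latent matrix `H` onto each inner code, and `H` itself. The coupled
#' objective is
#' `sum_v ||X^v - Z^(C,v)||_F^2 + lambda * ||Z^(C/2,v) - G^(S,v)||_F^2`,
#' minimized by alternating Adam steps on the network parameters (with `H`
#' fixed) and on `H` (with parameters fixed). Views are min-max scaled to
#' `[0, 1]` per coordinate (the sigmoid output layer cannot reconstruct
#' values outside that range); the scaling is stored in the model and
#' reapplied at inference.
#'
#' @param views A [view_set()] with `n >= 2` samples.
#' @param config A [fusion_config()].
#' @return An object of class `ae2_model`: parameters, latent `H`
#'   (`k x n`), per-view scaling, config and `loss_history` per epoch.
#' @export
train_ae2 <- function(views, config = fusion_config()) {
  stopifnot(inherits(views, "view_set"), inherits(config, "fusion_config"))
  if (views$n < 2) stop("need at least 2 samples to train", call. = FALSE)
  scaling <- lapply(views$X, scale_fit)
  Xs <- Map(scale_apply, views$X, scaling)
  withr::with_seed(config$seed, {
    params <- init_ae2_params(views$dims, config)
    H <- matrix(runif(config$k * views$n, -0.01, 0.01), config$k, views$n)
    p_state <- adam_state(length(flatten_params(params)))
    h_state <- adam_state(length(H))
    loss_history <- numeric(config$epochs)
    initial <- ae2_loss_grads(params, Xs, H, config$lambda, config,
      want_params = FALSE, want_H = FALSE
    )$loss
    for (ep in seq_len(config$epochs)) {
      lg <- ae2_loss_grads(params, Xs, H, config$lambda, config,
        want_H = FALSE
      )
      upd <- adam_step(
        flatten_params(params), flatten_params(lg$grads),
        p_state, config$learning_rate
      )
      p_state <- upd$state
      params <- unflatten_params(params, upd$theta)
      mid <- config$C %/% 2L + 1L
      z_mids <- lapply(seq_along(Xs), function(v) {
        ae_forward_chain(params[[v]]$ae, Xs[[v]])[[mid]]
      })
      for (hs in seq_len(config$inner_H_steps)) {
        dH <- h_gradient(params, z_mids, H, config$lambda)
        updH <- adam_step(
          as.numeric(H), as.numeric(dH), h_state,
          config$learning_rate
        )
        h_state <- updH$state
        H <- matrix(updH$theta, nrow(H), ncol(H))
      }
      loss_history[ep] <- ae2_loss_grads(params, Xs, H, config$lambda,
        config,
        want_params = FALSE, want_H = FALSE
      )$loss
      if (!is.finite(loss_history[ep]) || loss_history[ep] > 10 * initial) {
        stop("fusion training diverged at epoch ", ep, call. = FALSE)
      }
    }
    # exact block-coordinate finish: with parameters frozen, take H to the
    # minimizer of the coupling term so trained latents and infer_latent()
    # solve the same problem
    if (config$lambda > 0) {
      mid <- config$C %/% 2L + 1L
      z_mids <- lapply(seq_along(Xs), function(v) {
        ae_forward_chain(params[[v]]$ae, Xs[[v]])[[mid]]
      })
      H <- optimize_H(params, z_mids, H, config$lambda, config$learning_rate)
      loss_history <- c(loss_history, ae2_loss_grads(params, Xs, H,
        config$lambda, config,
        want_params = FALSE, want_H = FALSE
      )$loss)
    }
    structure(
      list(
        params = params, H = H, scaling = scaling, config = config,
        dims = views$dims, loss_history = loss_history,
        initial_loss = initial
      ),
      class = "ae2_model"
    )
  })
}

#' @export
print.ae2_model <- function(x, ...) {
  cat(
    "<ae2_model> ", length(x$dims), " view(s) dims ",
    paste(x$dims, collapse = "+"), " -> latent k = ", x$config$k,
    "; loss ", signif(x$initial_loss, 4), " -> ",
    signif(x$loss_history[length(x$loss_history)], 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Forward pass of one view's autoencoder
#'
#' @param model A trained [train_ae2()] model (or one built by internal
#'   initializers in tests).
#' @param v View index.
#' @param X_v The view matrix (`d_v x n`), already on the `[0, 1]` scale.
#' @return List with `Z_mid` (inner code, `k x n`) and `Z_C`
#'   (reconstruction, `d_v x n`).
#' @export
first_ae_forward <- function(model, v, X_v) {
  stopifnot(inherits(model, "ae2_model"))
  if (nrow(X_v) != model$dims[v]) {
    stop("view ", v, " expects ", model$dims[v], " features, got ",
      nrow(X_v),
      call. = FALSE
    )
  }
  zs <- ae_forward_chain(model$params[[v]]$ae, X_v)
  mid <- model$config$C %/% 2L + 1L
  list(Z_mid = zs[[mid]], Z_C = zs[[length(zs)]])
}

#' Forward pass of one view's degradation network
#'
#' @param model A trained [train_ae2()] model.
#' @param v View index.
#' @param H Latent matrix (`k x n`).
#' @return `G_S`, the degraded reconstruction of the view's inner code.
#' @export
degradation_forward <- function(model, v, H) {
  stopifnot(inherits(model, "ae2_model"))
  if (nrow(H) != model$config$k) {
    stop("H must have ", model$config$k, " rows", call. = FALSE)
  }
  gs <- ae_forward_chain(model$params[[v]]$dr, H)
  gs[[length(gs)]]
}

#' Coupled fusion objective
#'
#' Evaluates the training objective of a fitted model on a view set
#' (scaled with the model's stored scaling):
#' reconstruction plus `lambda` times the degradation mismatch.
#'
#' @param model A trained [train_ae2()] model.
#' @param views A [view_set()] with matching dimensions.
#' @param H Latent matrix; defaults to the model's trained `H`.
#' @param parts Return the two terms separately as well?
#' @return The scalar loss, or (with `parts = TRUE`) a list
#'   `loss`/`recon`/`degr`.
#' @export
ae2_objective <- function(model, views, H = model$H, parts = FALSE) {
  stopifnot(inherits(model, "ae2_model"), inherits(views, "view_set"))
  Xs <- Map(scale_apply, views$X, model$scaling)
  out <- ae2_loss_grads(model$params, Xs, H, model$config$lambda,
    model$config,
    want_params = FALSE, want_H = FALSE
  )
  if (parts) out[c("loss", "recon", "degr")] else out$loss
}

#' Infer latent vectors for new samples
#'
#' With every network parameter frozen, finds the latent columns that the
#' trained degradation networks map onto the new samples' inner codes —
#' minimizing the coupling term of the objective over `H_new` only, from a
#' zero initialization, with the same Adam settings (and the same
#' convergence criterion) as the final training step. This keeps
#' cross-validation honest: test samples never alter the encoder, and
#' training columns are recovered because both optimizations solve the same
#' per-column problem to convergence.
#'
#' @param model A trained [train_ae2()] model.
#' @param new_views A [view_set()] with the model's view dimensions.
#' @param max_steps Adam step cap (default 20000; the run usually stops on
#'   the convergence criterion much earlier).
#' @return A `k x n_new` latent matrix.
#' @export
infer_latent <- function(model, new_views, max_steps = 20000L) {
  stopifnot(inherits(model, "ae2_model"), inherits(new_views, "view_set"))
  if (!all(new_views$dims == model$dims)) {
    stop("view dimensions do not match the trained model", call. = FALSE)
  }
  cfg <- model$config
  Xs <- Map(scale_apply, new_views$X, model$scaling)
  mid <- cfg$C %/% 2L + 1L
  z_mids <- lapply(seq_along(Xs), function(v) {
    ae_forward_chain(model$params[[v]]$ae, Xs[[v]])[[mid]]
  })
  H <- matrix(0, cfg$k, new_views$n)
  if (cfg$lambda > 0) {
    H <- optimize_H(model$params, z_mids, H, cfg$lambda, cfg$learning_rate,
      max_steps = max_steps
    )
  }
  H
}

#' Fused per-sample features
#'
#' The shared latent representation transposed to samples-as-rows, ready
#' for classification.
#'
#' @param model A trained [train_ae2()] model.
#' @param H Latent matrix; defaults to the trained `H`.
#' @return An `n x k` numeric matrix.
#' @export
fused_features <- function(model, H = model$H) {
  stopifnot(inherits(model, "ae2_model"))
  t(H)
}
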