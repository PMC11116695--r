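#' Token vocabulary of the sequence embedder
#'
#' Fixed, closed vocabulary: the four nucleotides plus the special tokens
#' `PAD`, `CLS` (sequence-summary position), `SEP` (terminator) and `MASK`
#' (masked-language-model target placeholder).
#'
#' @return Named integer vector mapping token to id.
#' @export
token_vocab <- function() {
  c(PAD = 1L, CLS = 2L, SEP = 3L, MASK = 4L, A = 5L, C = 6L, G = 7L, U = 8L)
}

#' Tokenize a nucleotide sequence
#'
#' Produces `[CLS]`, one token per nucleotide, `[SEP]`. Sequences longer than
#' `max_len - 2` nucleotides are truncated with `[SEP]` retained as the final
#' token. All tokens belong to a single segment.
#'
#' @param seq Normalized nucleotide string (`A/C/G/U`).
#' @param max_len Token cap including the special tokens.
#' @return Integer vector of token ids (see [token_vocab()]).
#' @examples
#' tokenize("ACG") # length 5: CLS A C G SEP
#' @export
tokenize <- function(seq, max_len = 64L) {
  stopifnot(length(seq) == 1, is.character(seq))
  vocab <- token_vocab()
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  ids <- vocab[chars]
  if (anyNA(ids)) {
    stop(
      "sequence contains characters outside the vocabulary: ",
      paste(unique(chars[is.na(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  ids <- unname(c(vocab[["CLS"]], ids, vocab[["SEP"]]))
  if (length(ids) > max_len) {
    ids <- c(ids[seq_len(max_len - 1L)], vocab[["SEP"]])
  }
  ids
}

#' Configuration of the miRNA sequence embedder
#'
#' Desk-scale stand-in for a large pretrained nucleotide language model: a
#' small bidirectional transformer encoder pretrained by masked-language
#' modelling (MLM) on the input miRNA corpus itself. Next-sentence
#' prediction is not used (inputs are independent short sequences).
#'
#' @param n_layers Encoder depth (default 2).
#' @param hidden Model width; also the embedding dimension (default 64).
#' @param n_heads Attention heads; must divide `hidden` (default 4).
#' @param mlm_mask_rate Fraction of non-special tokens masked per sequence
#'   per epoch, in (0, 1) (default 0.15, the BERT convention).
#' @param max_len Token cap (default 64; miRNAs are ~20-22 nt, so no
#'   truncation occurs in practice).
#' @param epochs Training epochs over the corpus (default 30).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed controlling initialization and masking.
#' @return A list of class `embedder_config`.
#' @export
embedder_config <- function(n_layers = 2L, hidden = 64L, n_heads = 4L,
                            mlm_mask_rate = 0.15, max_len = 64L,
                            epochs = 30L, learning_rate = 1e-3, seed = 1L) {
  if (hidden %% n_heads != 0L) {
    stop("hidden (", hidden, ") must be divisible by n_heads (", n_heads, ")",
      call. = FALSE
    )
  }
  if (mlm_mask_rate <= 0 || mlm_mask_rate >= 1) {
    stop("mlm_mask_rate must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(
      n_layers = as.integer(n_layers), hidden = as.integer(hidden),
      n_heads = as.integer(n_heads), mlm_mask_rate = mlm_mask_rate,
      max_len = as.integer(max_len), epochs = as.integer(epochs),
      learning_rate = learning_rate, seed = as.integer(seed)
    ),
    class = "embedder_config"
  )
}

# ---- internal transformer machinery ----------------------------------------
# Matrices are token-major: a sequence of L tokens is an L x hidden matrix.

add_bias <- function(m, b) m + rep(b, each = nrow(m))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

init_embedder_params <- function(config) {
  h <- config$hidden
  v <- length(token_vocab())
  layers <- lapply(seq_len(config$n_layers), function(l) {
    list(
      Wq = glorot(h, h), bq = numeric(h),
      Wk = glorot(h, h), bk = numeric(h),
      Wv = glorot(h, h), bv = numeric(h),
      Wo = glorot(h, h), bo = numeric(h),
      ln1_g = rep(1, h), ln1_b = numeric(h),
      W1 = glorot(h, 4 * h), b1 = numeric(4 * h),
      W2 = glorot(4 * h, h), b2 = numeric(h),
      ln2_g = rep(1, h), ln2_b = numeric(h)
    )
  })
  list(
    tok = matrix(rnorm(v * h, sd = 0.02), v, h),
    seg = rnorm(h, sd = 0.02),
    pos = matrix(rnorm(config$max_len * h, sd = 0.02), config$max_len, h),
    layers = layers,
    out_W = glorot(h, v),
    out_b = numeric(v)
  )
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  s <- sqrt(rowMeans(xc^2) + eps)
  xhat <- xc / s
  list(y = add_bias(xhat * rep(g, each = nrow(x)), b), xhat = xhat, s = s)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- dy * rep(g, each = nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$s
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

row_softmax <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# Forward pass through the encoder stack; returns the final hidden states and,
# when keep_cache, every intermediate needed for backprop.
encoder_forward <- function(params, ids, config, keep_cache = FALSE) {
  h <- config$hidden
  nh <- config$n_heads
  dh <- h %/% nh
  L <- length(ids)
  x <- params$tok[ids, , drop = FALSE] +
    rep(params$seg, each = L) +
    params$pos[seq_len(L), , drop = FALSE]
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    p <- params$layers[[l]]
    q <- add_bias(x %*% p$Wq, p$bq)
    k <- add_bias(x %*% p$Wk, p$bk)
    v <- add_bias(x %*% p$Wv, p$bv)
    a <- matrix(0, L, h)
    pmats <- vector("list", nh)
    for (j in seq_len(nh)) {
      cols <- ((j - 1) * dh + 1):(j * dh)
      s <- q[, cols, drop = FALSE] %*% t(k[, cols, drop = FALSE]) / sqrt(dh)
      pj <- row_softmax(s)
      pmats[[j]] <- pj
      a[, cols] <- pj %*% v[, cols, drop = FALSE]
    }
    o <- add_bias(a %*% p$Wo, p$bo)
    r1 <- x + o
    ln1 <- layernorm_fwd(r1, p$ln1_g, p$ln1_b)
    x1 <- ln1$y
    pre <- add_bias(x1 %*% p$W1, p$b1)
    fh <- pmax(pre, 0)
    f2 <- add_bias(fh %*% p$W2, p$b2)
    r2 <- x1 + f2
    ln2 <- layernorm_fwd(r2, p$ln2_g, p$ln2_b)
    if (keep_cache) {
      caches[[l]] <- list(
        x = x, q = q, k = k, v = v, pmats = pmats, a = a,
        ln1 = ln1, x1 = x1, pre = pre, fh = fh, ln2 = ln2
      )
    }
    x <- ln2$y
  }
  list(hidden = x, caches = caches)
}

# Backprop of d(final hidden) through the encoder stack; returns gradients for
# every parameter block (same shapes as params).
encoder_backward <- function(params, ids, config, fwd, dx_final) {
  h <- config$hidden
  nh <- config$n_heads
  dh <- h %/% nh
  L <- length(ids)
  zero_like <- function(m) if (is.matrix(m)) matrix(0, nrow(m), ncol(m)) else numeric(length(m))
  grads <- list(
    tok = zero_like(params$tok), seg = zero_like(params$seg),
    pos = zero_like(params$pos),
    layers = lapply(params$layers, function(p) lapply(p, zero_like)),
    out_W = zero_like(params$out_W), out_b = zero_like(params$out_b)
  )
  dx <- dx_final
  for (l in rev(seq_len(config$n_layers))) {
    p <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    g <- grads$layers[[l]]
    b2g <- layernorm_bwd(dx, cc$ln2, p$ln2_g)
    g$ln2_g <- g$ln2_g + b2g$dg
    g$ln2_b <- g$ln2_b + b2g$db
    dr2 <- b2g$dx
    # FFN branch
    df2 <- dr2
    g$W2 <- g$W2 + t(cc$fh) %*% df2
    g$b2 <- g$b2 + colSums(df2)
    dfh <- df2 %*% t(p$W2)
    dpre <- dfh * (cc$pre > 0)
    g$W1 <- g$W1 + t(cc$x1) %*% dpre
    g$b1 <- g$b1 + colSums(dpre)
    dx1 <- dr2 + dpre %*% t(p$W1)
    b1g <- layernorm_bwd(dx1, cc$ln1, p$ln1_g)
    g$ln1_g <- g$ln1_g + b1g$dg
    g$ln1_b <- g$ln1_b + b1g$db
    dr1 <- b1g$dx
    # attention branch
    do <- dr1
    g$Wo <- g$Wo + t(cc$a) %*% do
    g$bo <- g$bo + colSums(do)
    da <- do %*% t(p$Wo)
    dq <- matrix(0, L, h)
    dk <- matrix(0, L, h)
    dv <- matrix(0, L, h)
    for (j in seq_len(nh)) {
      cols <- ((j - 1) * dh + 1):(j * dh)
      pj <- cc$pmats[[j]]
      daj <- da[, cols, drop = FALSE]
      dv[, cols] <- t(pj) %*% daj
      dpj <- daj %*% t(cc$v[, cols, drop = FALSE])
      dsj <- pj * (dpj - rowSums(dpj * pj))
      dq[, cols] <- dsj %*% cc$k[, cols, drop = FALSE] / sqrt(dh)
      dk[, cols] <- t(dsj) %*% cc$q[, cols, drop = FALSE] / sqrt(dh)
    }
    g$Wq <- g$Wq + t(cc$x) %*% dq
    g$bq <- g$bq + colSums(dq)
    g$Wk <- g$Wk + t(cc$x) %*% dk
    g$bk <- g$bk + colSums(dk)
    g$Wv <- g$Wv + t(cc$x) %*% dv
    g$bv <- g$bv + colSums(dv)
    grads$layers[[l]] <- g
    dx <- dr1 + dq %*% t(p$Wq) + dk %*% t(p$Wk) + dv %*% t(p$Wv)
  }
  # embedding gradients
  for (i in seq_len(L)) {
    grads$tok[ids[i], ] <- grads$tok[ids[i], ] + dx[i, ]
  }
  grads$seg <- colSums(dx)
  grads$pos[seq_len(L), ] <- grads$pos[seq_len(L), ] + dx
  grads
}

# MLM loss and gradients for one masked sequence. `ids` carries the corrupted
# tokens, `targets` the original tokens, `mask_pos` the positions the loss is
# taken over (mean cross-entropy).
mlm_loss_grad <- function(params, ids, targets, mask_pos, config,
                          want_grads = TRUE) {
  fwd <- encoder_forward(params, ids, config, keep_cache = want_grads)
  logits <- add_bias(fwd$hidden %*% params$out_W, params$out_b)
  lm <- logits[mask_pos, , drop = FALSE]
  lm <- lm - apply(lm, 1, max)
  logz <- log(rowSums(exp(lm)))
  tgt <- targets[mask_pos]
  nmask <- length(mask_pos)
  loss <- mean(logz - lm[cbind(seq_len(nmask), tgt)])
  if (!want_grads) {
    return(list(loss = loss))
  }
  probs <- exp(lm - logz)
  dlm <- probs
  dlm[cbind(seq_len(nmask), tgt)] <- dlm[cbind(seq_len(nmask), tgt)] - 1
  dlm <- dlm / nmask
  dlogits <- matrix(0, length(ids), ncol(logits))
  dlogits[mask_pos, ] <- dlm
  dhid <- dlogits %*% t(params$out_W)
  grads <- encoder_backward(params, ids, config, fwd, dhid)
  grads$out_W <- t(fwd$hidden) %*% dlogits
  grads$out_b <- colSums(dlogits)
  list(loss = loss, grads = grads)
}

# ---- flat parameter utilities (shared with the Adam optimizer) -------------

flatten_params <- function(p) {
  if (is.list(p)) {
    unlist(lapply(p, flatten_params), use.names = FALSE)
  } else {
    as.numeric(p)
  }
}

unflatten_params <- function(template, vec) {
  pos <- 0L
  rebuild <- function(p) {
    if (is.list(p)) {
      lapply(p, rebuild)
    } else {
      n <- length(p)
      out <- vec[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(p)) dim(out) <- dim(p)
      out
    }
  }
  rebuild(template)
}

adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Corrupt one token sequence for MLM: select positions among the non-special
# tokens, replace 80% by MASK, 10% by a random nucleotide, 10% unchanged.
mlm_corrupt <- function(ids, rate) {
  vocab <- token_vocab()
  cand <- which(ids >= vocab[["A"]])
  nmask <- max(1L, round(rate * length(cand)))
  mask_pos <- if (length(cand) == 1L) cand else sample(cand, nmask)
  corrupted <- ids
  u <- runif(length(mask_pos))
  nuc <- vocab[["A"]]:vocab[["U"]]
  for (i in seq_along(mask_pos)) {
    if (u[i] < 0.8) {
      corrupted[mask_pos[i]] <- vocab[["MASK"]]
    } else if (u[i] < 0.9) {
      corrupted[mask_pos[i]] <- sample(nuc, 1L)
    } # else leave unchanged
  }
  list(ids = corrupted, mask_pos = mask_pos)
}

#' Train the miRNA sequence embedder by masked-language modelling
#'
#' Pretrains a small bidirectional transformer encoder on the miRNA corpus:
#' each epoch, a fraction of the nucleotide tokens of every sequence is
#' masked (80% `MASK`, 10% random nucleotide, 10% unchanged) and the model
#' is trained by Adam to recover them from bidirectional context. The input
#' representation is the sum of token, segment and position embeddings.
#'
#' @param corpus A tibble of miRNA sequences (columns `id`, `seq`).
#' @param config An [embedder_config()].
#' @return An object of class `seq_embedder`: trained parameters, the
#'   config, and `loss_history` (mean masked cross-entropy per epoch, nats).
#' @export
train_mlm_embedder <- function(corpus, config = embedder_config()) {
  stopifnot(is.data.frame(corpus), inherits(config, "embedder_config"))
  if (nrow(corpus) == 0L) stop("embedder corpus is empty", call. = FALSE)
  token_lists <- lapply(corpus$seq, tokenize, max_len = config$max_len)
  withr::with_seed(config$seed, {
    params <- init_embedder_params(config)
    state <- adam_state(length(flatten_params(params)))
    loss_history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      order_idx <- sample(length(token_lists))
      losses <- numeric(length(order_idx))
      for (ii in seq_along(order_idx)) {
        ids <- token_lists[[order_idx[ii]]]
        corr <- mlm_corrupt(ids, config$mlm_mask_rate)
        lg <- mlm_loss_grad(params, corr$ids, ids, corr$mask_pos, config)
        if (!is.finite(lg$loss)) {
          stop("MLM training diverged (non-finite loss) at epoch ", ep,
            call. = FALSE
          )
        }
        losses[ii] <- lg$loss
        upd <- adam_step(
          flatten_params(params), flatten_params(lg$grads),
          state, config$learning_rate
        )
        state <- upd$state
        params <- unflatten_params(params, upd$theta)
      }
      loss_history[ep] <- mean(losses)
    }
    structure(
      list(params = params, config = config, loss_history = loss_history),
      class = "seq_embedder"
    )
  })
}

#' @export
print.seq_embedder <- function(x, ...) {
  cat(
    "<seq_embedder> ", x$config$n_layers, "-layer transformer, hidden ",
    x$config$hidden, "; final MLM loss ",
    signif(x$loss_history[length(x$loss_history)], 4), " nats\n",
    sep = ""
  )
  invisible(x)
}

#' Embed a miRNA sequence
#'
#' Runs the trained encoder over the uncorrupted token sequence and returns
#' the final-layer hidden state at the `CLS` position (or the mean over
#' nucleotide positions with `pooling = "mean"`). A pure function of the
#' trained weights and the sequence.
#'
#' @param model A trained [train_mlm_embedder()] model.
#' @param seq Normalized nucleotide string.
#' @param pooling `"cls"` (default) or `"mean"`.
#' @return Numeric vector of length `config$hidden`.
#' @export
embed_mirna <- function(model, seq, pooling = c("cls", "mean")) {
  stopifnot(inherits(model, "seq_embedder"))
  pooling <- match.arg(pooling)
  ids <- tokenize(seq, max_len = model$config$max_len)
  hidden <- encoder_forward(model$params, ids, model$config)$hidden
  if (pooling == "cls") {
    hidden[1, ]
  } else {
    colMeans(hidden[-c(1L, length(ids)), , drop = FALSE])
  }
}

#' miRNA attribute matrix from a trained embedder
#'
#' @param model A trained [train_mlm_embedder()] model.
#' @param records A tibble of miRNA sequences (columns `id`, `seq`).
#' @param pooling Passed to [embed_mirna()].
#' @return Numeric matrix, one row per miRNA (rownames = ids).
#' @export
mirna_attribute_matrix <- function(model, records, pooling = "cls") {
  m <- t(vapply(
    records$seq, embed_mirna,
    numeric(model$config$hidden),
    model = model, pooling = pooling
  ))
  rownames(m) <- records$id
  m
}
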