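test_that("fusion_config validates depth and balance", {
  expect_error(fusion_config(C = 3), "even")
  expect_error(fusion_config(lambda = -1), "non-negative")
  expect_error(view_set(list(matrix(1, 2, 3), matrix(1, 2, 4))), "sample count")
  expect_error(view_set(list(matrix(NA_real_, 2, 2))), "non-finite")
})

test_that("first-AE and degradation forwards match hand arithmetic", {
  cfg <- fusion_config(k = 2L, C = 2L, S = 1L, seed = 1)
  params <- withr::with_seed(1, circmi:::init_ae2_params(3L, cfg))
  model <- manual_ae2_model(params, dims = 3L, config = cfg)

  # zero parameters: every sigmoid layer outputs exactly 0.5
  zero <- rapply(params, function(x) x * 0, how = "replace")
  zmodel <- manual_ae2_model(zero, dims = 3L, config = cfg)
  X <- matrix(runif(6), 3, 2)
  fw <- first_ae_forward(zmodel, 1, X)
  expect_true(all(fw$Z_mid == 0.5))
  expect_true(all(fw$Z_C == 0.5))
  expect_true(all(degradation_forward(zmodel, 1, matrix(0, 2, 2)) == 0.5))

  # pencil-and-paper 2-layer forward on a 2-feature single sample
  cfg2 <- fusion_config(k = 1L, C = 2L, S = 1L, seed = 1)
  p2 <- list(list(
    ae = list(
      list(W = matrix(c(0.5, -1), 1, 2), b = 0.1),
      list(W = matrix(c(2, 0.3), 2, 1), b = c(-0.2, 0))
    ),
    dr = list(list(W = matrix(0.7, 1, 1), b = 0.25))
  ))
  m2 <- manual_ae2_model(p2, dims = 2L, config = cfg2, n = 1L)
  x <- matrix(c(0.4, 0.9), 2, 1)
  z1 <- plogis(0.5 * 0.4 - 1 * 0.9 + 0.1)
  z2 <- plogis(c(2 * z1 - 0.2, 0.3 * z1 + 0))
  fw2 <- first_ae_forward(m2, 1, x)
  expect_equal(as.numeric(fw2$Z_mid), z1, tolerance = 1e-12)
  expect_equal(as.numeric(fw2$Z_C), z2, tolerance = 1e-12)

  h <- matrix(0.3, 1, 1)
  expect_equal(
    as.numeric(degradation_forward(m2, 1, h)),
    plogis(0.7 * 0.3 + 0.25),
    tolerance = 1e-12
  )
  expect_equal(as.numeric(fw2$Z_mid), z1) # shapes preserved for n = 1

  expect_error(first_ae_forward(m2, 1, matrix(0, 3, 1)), "features")
  expect_error(degradation_forward(m2, 1, matrix(0, 2, 1)), "rows")
})

test_that("the objective decomposes into its two tracked terms", {
  cfg <- fusion_config(k = 3L, C = 2L, S = 1L, lambda = 0.7, seed = 2)
  params <- withr::with_seed(2, circmi:::init_ae2_params(c(4L, 5L), cfg))
  model <- manual_ae2_model(params, dims = c(4L, 5L), config = cfg, n = 6L)
  vs <- withr::with_seed(3, view_set(list(
    matrix(runif(24), 4, 6), matrix(runif(30), 5, 6)
  )))
  H <- matrix(0.1, 3, 6)
  parts <- ae2_objective(model, vs, H, parts = TRUE)
  expect_equal(parts$loss, parts$recon + 0.7 * parts$degr, tolerance = 1e-10)
  expect_gte(parts$loss, 0)

  # direct recomputation from the stated formula
  direct <- 0
  for (v in 1:2) {
    fw <- first_ae_forward(model, v, vs$X[[v]])
    gs <- degradation_forward(model, v, H)
    direct <- direct + sum((vs$X[[v]] - fw$Z_C)^2) +
      0.7 * sum((fw$Z_mid - gs)^2)
  }
  expect_equal(parts$loss, direct, tolerance = 1e-10)

  # lambda = 0 reduces to the summed reconstruction losses
  cfg0 <- fusion_config(k = 3L, C = 2L, S = 1L, lambda = 0, seed = 2)
  model0 <- manual_ae2_model(params, dims = c(4L, 5L), config = cfg0, n = 6L)
  parts0 <- ae2_objective(model0, vs, H, parts = TRUE)
  expect_equal(parts0$loss, parts0$recon)
})

test_that("analytic fusion gradients match central differences", {
  # 3 features, 4 samples, C = 2, S = 1
  cfg <- fusion_config(k = 2L, C = 2L, S = 1L, lambda = 0.7, seed = 5)
  params <- withr::with_seed(5, circmi:::init_ae2_params(3L, cfg))
  X <- withr::with_seed(6, matrix(runif(12), 3, 4))
  H <- withr::with_seed(7, matrix(rnorm(8) * 0.3, 2, 4))
  lg <- circmi:::ae2_loss_grads(params, list(X), H, cfg$lambda, cfg)
  theta <- circmi:::flatten_params(params)
  f <- function(th) {
    circmi:::ae2_loss_grads(
      circmi:::unflatten_params(params, th),
      list(X), H, cfg$lambda, cfg,
      want_params = FALSE, want_H = FALSE
    )$loss
  }
  ng <- num_grad(f, theta)
  ag <- circmi:::flatten_params(lg$grads)
  expect_lt(max(abs(ag - ng)) / max(abs(ng)), 1e-4)

  fh <- function(h) {
    circmi:::ae2_loss_grads(params, list(X), matrix(h, 2, 4), cfg$lambda,
      cfg,
      want_params = FALSE, want_H = FALSE
    )$loss
  }
  ngh <- num_grad(fh, as.numeric(H))
  expect_lt(max(abs(as.numeric(lg$dH) - ngh)) / max(abs(ngh)), 1e-4)

  # deeper instance: C = 4, S = 2, two views
  cfg2 <- fusion_config(k = 2L, C = 4L, S = 2L, lambda = 1.3, seed = 8)
  p2 <- withr::with_seed(8, circmi:::init_ae2_params(c(3L, 4L), cfg2))
  Xs <- withr::with_seed(9, list(matrix(runif(9), 3, 3), matrix(runif(12), 4, 3)))
  H2 <- withr::with_seed(10, matrix(rnorm(6) * 0.2, 2, 3))
  lg2 <- circmi:::ae2_loss_grads(p2, Xs, H2, cfg2$lambda, cfg2)
  th2 <- circmi:::flatten_params(p2)
  f2 <- function(th) {
    circmi:::ae2_loss_grads(
      circmi:::unflatten_params(p2, th), Xs, H2,
      cfg2$lambda, cfg2,
      want_params = FALSE, want_H = FALSE
    )$loss
  }
  ng2 <- num_grad(f2, th2)
  ag2 <- circmi:::flatten_params(lg2$grads)
  expect_lt(max(abs(ag2 - ng2)) / max(abs(ng2)), 1e-4)
})

test_that("training descends, is seeded, and a single view degenerates to a plain AE", {
  vs <- withr::with_seed(11, view_set(list(
    matrix(runif(20 * 50), 20, 50),
    matrix(runif(10 * 50), 10, 50)
  )))
  cfg <- fusion_config(k = 8L, epochs = 60L, seed = 2)
  m <- train_ae2(vs, cfg)
  expect_lt(m$loss_history[length(m$loss_history)], m$initial_loss)
  expect_true(all(is.finite(m$H)))

  m2 <- train_ae2(vs, cfg)
  expect_identical(m$H, m2$H)
  expect_identical(m$params, m2$params)

  # V = 1, lambda = 0: plain autoencoder, descent still holds
  vs1 <- view_set(list(vs$X[[1]]))
  cfg1 <- fusion_config(k = 8L, lambda = 0, epochs = 60L, seed = 3)
  m1 <- train_ae2(vs1, cfg1)
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$initial_loss)
})

test_that("larger lambda drives the degradation term harder", {
  vs <- withr::with_seed(12, view_set(list(
    matrix(runif(12 * 30), 12, 30),
    matrix(runif(8 * 30), 8, 30)
  )))
  degr_at <- vapply(c(0.1, 1, 10), function(lam) {
    m <- train_ae2(vs, fusion_config(
      k = 6L, lambda = lam, epochs = 80L,
      seed = 4
    ))
    ae2_objective(m, vs, parts = TRUE)$degr
  }, numeric(1))
  expect_true(all(diff(degr_at) <= 0))
})

test_that("infer_latent recovers training latents and maps duplicates identically", {
  vs <- withr::with_seed(13, view_set(list(
    matrix(runif(15 * 40), 15, 40),
    matrix(runif(9 * 40), 9, 40)
  )))
  m <- train_ae2(vs, fusion_config(k = 6L, epochs = 100L, seed = 5))
  H_new <- infer_latent(m, vs)
  expect_lt(sqrt(mean((H_new - m$H)^2)), 1e-2)

  # single new sample returns a k-vector worth of latents
  one <- view_set(list(vs$X[[1]][, 1, drop = FALSE], vs$X[[2]][, 1, drop = FALSE]))
  h1 <- infer_latent(m, one)
  expect_equal(dim(h1), c(6, 1))

  # duplicated input column -> duplicated latent column (pure function)
  two <- view_set(list(
    vs$X[[1]][, c(3, 3)], vs$X[[2]][, c(3, 3)]
  ))
  h2 <- infer_latent(m, two)
  expect_equal(h2[, 1], h2[, 2])

  expect_error(
    infer_latent(m, view_set(list(matrix(0, 3, 1), matrix(0, 9, 1)))),
    "dimensions"
  )
})

test_that("the shared latent carries class signal from clustered views", {
  # two clusters shifted in both views; a linear read-out of H must beat chance
  n_half <- 30
  withr::with_seed(14, {
    base1 <- matrix(runif(10 * 2 * n_half), 10, 2 * n_half)
    base2 <- matrix(runif(6 * 2 * n_half), 6, 2 * n_half)
    cls <- rep(c(0, 1), each = n_half)
    base1[1:3, cls == 1] <- base1[1:3, cls == 1] + 2
    base2[1:2, cls == 1] <- base2[1:2, cls == 1] + 2
  })
  vs <- view_set(list(base1, base2))
  m <- train_ae2(vs, fusion_config(k = 4L, epochs = 120L, seed = 6))
  feats <- fused_features(m)
  expect_equal(dim(feats), c(2 * n_half, 4))
  fit <- suppressWarnings(stats::glm(cls ~ ., family = stats::binomial(),
    data = data.frame(feats, cls = cls)))
  acc <- mean((stats::fitted(fit) > 0.5) == cls)
  expect_gt(acc, 0.75)
})
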