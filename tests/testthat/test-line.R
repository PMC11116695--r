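test_that("build_graph counts vertices, edges, degrees and cold nodes", {
  s <- interaction_set(
    tibble::tibble(circ_id = c("c1", "c1", "c2"), mirna_id = c("m1", "m2", "m1")),
    circ_ids = c("c1", "c2", "c3"), mirna_ids = c("m1", "m2")
  )
  g <- build_graph(s)
  expect_equal(length(g$vertex_ids), 5)
  expect_equal(nrow(g$edges), 3)
  expect_equal(unname(g$degree[c("c1", "c2", "c3", "m1", "m2")]),
    c(2, 1, 0, 2, 1))
  expect_equal(unname(g$cold["c3"]), TRUE)
  expect_equal(sum(noise_distribution(g)), 1)
  expect_equal(unname(noise_distribution(g)["c3"]), 0)
  expect_error(
    build_graph(interaction_set(
      tibble::tibble(circ_id = character(), mirna_id = character()),
      circ_ids = "c1", mirna_ids = "m1"
    )),
    "empty"
  )
})

test_that("noise sampling is empirically proportional to degree^(3/4)", {
  g <- build_graph(generate_toy_graph("star"))
  p <- noise_distribution(g)
  n <- 1e5
  draws <- sample_noise_vertices(g, n, seed = 99)
  freq <- table(factor(draws, levels = g$vertex_ids)) / n
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(as.numeric(freq) - p) <= 3 * se + 1e-12))
  # hub degree = leaf count, so the hub mass is 5^(3/4) / (5^(3/4) + 5)
  expect_equal(unname(p["c1"]), 5^0.75 / (5^0.75 + 5))
})

test_that("first- and second-order probabilities match hand arithmetic", {
  expect_equal(first_order_prob(c(0, 0, 0), c(0, 0, 0)), 0.5)
  expect_equal(first_order_prob(c(1, 0), c(1, 0)), 1 / (1 + exp(-1)))
  expect_error(first_order_prob(c(1, 0), c(1, 0, 0)), "length")
  # monotone in the dot product, saturating at the limits
  expect_lt(first_order_prob(c(-30, 0), c(1, 0)), 1e-12)
  expect_gt(first_order_prob(c(30, 0), c(1, 0)), 1 - 1e-12)

  g <- build_graph(generate_toy_graph("single_edge"))
  # scores (1, 0): softmax = (e, 1) / (e + 1)
  m <- line_model(
    vertex = matrix(c(1, 0), 2, 1, dimnames = list(c("c1", "m1"), NULL)),
    context = matrix(c(1, 0), 2, 1, dimnames = list(c("c1", "m1"), NULL))
  )
  expect_equal(second_order_prob(g, m, "c1", "c1"), exp(1) / (exp(1) + 1))
  expect_equal(second_order_prob(g, m, "c1", "m1"), 1 / (exp(1) + 1))

  # uniform when all context vectors coincide; always sums to one
  g2 <- build_graph(generate_toy_graph("two_bicliques_bridge"))
  n <- length(g2$vertex_ids)
  mu <- line_model(
    vertex = matrix(rnorm(n * 2), n, 2),
    context = matrix(1, n, 2)
  )
  expect_equal(second_order_prob(g2, mu, "c1", "m4"), 1 / n)
  withr::with_seed(8, {
    mr <- line_model(
      vertex = matrix(rnorm(n * 2), n, 2),
      context = matrix(rnorm(n * 2), n, 2)
    )
  })
  total <- sum(vapply(g2$vertex_ids,
    function(v) second_order_prob(g2, mr, "c1", v), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("exact objective matches hand values and scales with weights", {
  g <- build_graph(generate_toy_graph("single_edge"))
  m0 <- line_model(matrix(0, 2, 4))
  expect_equal(exact_objective(g, m0), log(0.5), tolerance = 1e-10)

  g2 <- build_graph(generate_toy_graph("two_bicliques_bridge"))
  withr::with_seed(2, {
    m <- line_model(matrix(rnorm(16), 8, 2))
  })
  expect_lte(exact_objective(g2, m), 0) # log-probabilities, unit weights
  gw <- g2
  gw$edges$weight <- 2
  expect_equal(exact_objective(gw, m), 2 * exact_objective(g2, m))
})

test_that("analytic gradients of both exact objectives match central differences", {
  g <- build_graph(generate_toy_graph("two_bicliques_bridge")) # 8 vertices
  n <- length(g$vertex_ids)
  d <- 3
  for (ord in c("first", "second")) {
    withr::with_seed(21, {
      vert <- matrix(rnorm(n * d) * 0.4, n, d)
      ctx <- if (ord == "second") matrix(rnorm(n * d) * 0.4, n, d) else NULL
    })
    model <- line_model(vert, ctx, ord)
    analytic <- exact_objective_grad(g, model)
    theta <- c(as.numeric(vert), if (ord == "second") as.numeric(ctx))
    f <- function(th) {
      v <- matrix(th[1:(n * d)], n, d)
      cx <- if (ord == "second") matrix(th[-(1:(n * d))], n, d) else NULL
      exact_objective(g, line_model(v, cx, ord))
    }
    ng <- num_grad(f, theta)
    ag <- c(
      as.numeric(analytic$vertex),
      if (ord == "second") as.numeric(analytic$context)
    )
    expect_lt(max(abs(ag - ng)) / max(abs(ng)), 1e-4)
  }
})

test_that("training increases the exact objective on toy graphs", {
  g <- build_graph(generate_toy_graph("single_edge"))
  m <- train_line(g, dim = 4, order = "first", n_samples = 2000, seed = 7)
  p_edge <- first_order_prob(m$vertex["c1", ], m$vertex["m1", ])
  expect_gt(p_edge, 0.5) # ascent from the sigma(0) start
  expect_gt(exact_objective(g, m), log(0.5))

  g2 <- build_graph(generate_toy_graph("star"))
  init <- line_model(matrix(0, 6, 4), matrix(0, 6, 4), "second")
  m2 <- train_line(g2, dim = 4, order = "second", n_samples = 5000, seed = 3)
  expect_gt(exact_objective(g2, m2), exact_objective(g2, init))
})

test_that("train_line is deterministic and returns finite vectors", {
  g <- build_graph(generate_toy_graph("two_bicliques_bridge"))
  m1 <- train_line(g, dim = 8, order = "second", n_samples = 3000, seed = 5)
  m2 <- train_line(g, dim = 8, order = "second", n_samples = 3000, seed = 5)
  expect_identical(m1$vertex, m2$vertex)
  expect_identical(m1$context, m2$context)
  expect_true(all(is.finite(m1$vertex)))
  expect_equal(dim(m1$vertex), c(8, 8))
  m3 <- train_line(g, dim = 8, order = "second", n_samples = 3000, seed = 6)
  expect_false(identical(m1$vertex, m3$vertex))
})

test_that("embeddings separate the two bicliques across seeds", {
  g <- build_graph(generate_toy_graph("two_bicliques_bridge"))
  block_a <- c("c1", "c2", "m1", "m2")
  block_b <- c("c3", "c4", "m3", "m4")
  cos <- function(emb, a, b) {
    sum(emb[a, ] * emb[b, ]) / sqrt(sum(emb[a, ]^2) * sum(emb[b, ]^2))
  }
  wins <- 0
  for (s in 1:10) {
    emb <- line_embed(g, total_dim = 16, seed = s)
    intra <- c(
      utils::combn(block_a, 2, function(p) cos(emb, p[1], p[2])),
      utils::combn(block_b, 2, function(p) cos(emb, p[1], p[2]))
    )
    inter <- outer(block_a, block_b, Vectorize(function(x, y) cos(emb, x, y)))
    wins <- wins + (mean(intra) > mean(inter))
  }
  expect_gte(wins, 9)
})

test_that("isomorphic graphs train to similar exact objectives", {
  pairs <- generate_toy_graph("two_bicliques_bridge")$pairs
  relabel <- c(
    c1 = "c4", c2 = "c3", c3 = "c2", c4 = "c1",
    m1 = "m4", m2 = "m3", m3 = "m2", m4 = "m1"
  )
  pairs2 <- tibble::tibble(
    circ_id = unname(relabel[pairs$circ_id]),
    mirna_id = unname(relabel[pairs$mirna_id])
  )
  g1 <- build_graph(interaction_set(pairs))
  g2 <- build_graph(interaction_set(pairs2))
  o1 <- exact_objective(g1, train_line(g1, 8, "first", n_samples = 5000, seed = 4))
  o2 <- exact_objective(g2, train_line(g2, 8, "first", n_samples = 5000, seed = 4))
  expect_lt(abs(o1 - o2), 0.2 * abs(o1))
})

test_that("line_embed concatenates orders, zeroes cold vertices, reproduces", {
  s <- interaction_set(
    tibble::tibble(circ_id = c("c1", "c2"), mirna_id = c("m1", "m1")),
    circ_ids = c("c1", "c2", "c3"), mirna_ids = "m1"
  )
  g <- build_graph(s)
  emb <- line_embed(g, total_dim = 8, samples_per_edge = 100, seed = 2)
  expect_equal(dim(emb), c(4, 8))
  expect_equal(unname(emb["c3", ]), rep(0, 8))
  expect_true(attr(emb, "cold")["c3"])
  emb2 <- line_embed(g, total_dim = 8, samples_per_edge = 100, seed = 2)
  expect_identical(emb, emb2)
  expect_error(line_embed(g, total_dim = 7), "even")

  v <- pair_behavior_view(emb, tibble::tibble(
    circ_id = c("c1", "c3", "c2"), mirna_id = c("m1", "m1", "m1")
  ))
  expect_equal(dim(v), c(3, 16))
  expect_equal(unname(v[2, 1:8]), rep(0, 8)) # cold endpoint half
  expect_equal(v[1, 9:16], v[3, 9:16]) # shared miRNA half
  expect_error(pair_behavior_view(emb, tibble::tibble(
    circ_id = "nope", mirna_id = "m1"
  )), "nope")
})
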