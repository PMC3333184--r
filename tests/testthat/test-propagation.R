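two_nodes <- gene_network(data.frame(from = "a", to = "b"))

test_that("transition matrix is weight-proportional and column-stochastic", {
  W <- rw_transition_matrix(two_nodes)
  expect_equal(W["b", "a"], 1)
  expect_equal(W["a", "b"], 1)

  star <- gene_network(data.frame(from = c("a", "a"), to = c("b", "c"),
                                  weight = c(0.5, 1.0)))
  Ws <- rw_transition_matrix(star)
  expect_equal(Ws["b", "a"], 1 / 3)
  expect_equal(Ws["c", "a"], 2 / 3)

  iso <- gene_network(data.frame(from = "a", to = "b"), nodes = "z")
  Wi <- rw_transition_matrix(iso)
  expect_equal(Wi["z", "z"], 1)
  expect_equal(unname(Matrix::colSums(Wi)), rep(1, 3))
})

test_that("random walk reaches the closed-form stationary vector", {
  res <- random_walk(two_nodes, "a")
  expect_equal(unname(res$scores["a"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(res$scores["b"]), 1 / 3, tolerance = 1e-9)
  # restart-only limit: one step back to the seed distribution
  res1 <- random_walk(two_nodes, "a", propagation_config(restart = 1))
  expect_equal(unname(res1$scores), c(1, 0))
  expect_equal(res1$iterations, 1L)
})

test_that("random walk matches the dense linear solve on random graphs", {
  set.seed(71)
  for (trial in 1:10) {
    net <- random_gene_network(sample(10:30, 1), 0.2,
                               weighted = trial %% 2 == 0)
    seeds <- sample(net$nodes, sample(1:3, 1))
    res <- random_walk(net, seeds)
    want <- oracle_rw_solve(net, seeds, 0.5)
    expect_lt(sum(abs(res$scores - want)), 1e-8)
    # mass conservation at every iteration
    expect_lt(diff(res$mass_range), 1e-8)
    expect_equal(mean(res$mass_range), 1, tolerance = 1e-8)
  }
})

test_that("PRINCE normalization matches hand-computed operators", {
  expect_equal(prince_normalized_matrix(two_nodes)["a", "b"], 1)
  tri <- gene_network(data.frame(from = c("a", "b", "c"),
                                 to = c("b", "c", "a")))
  Wt <- prince_normalized_matrix(tri)
  expect_equal(Wt["a", "b"], 0.5)
  expect_equal(Wt["b", "c"], 0.5)
  half <- gene_network(data.frame(from = "a", to = "b", weight = 0.5))
  expect_equal(prince_normalized_matrix(half)["a", "b"], 1)
  iso <- gene_network(data.frame(from = "a", to = "b"), nodes = "z")
  expect_equal(sum(prince_normalized_matrix(iso)["z", ]), 0)
})

test_that("PRINCE propagation reaches its closed form", {
  res <- prince_propagate(two_nodes, "a")
  expect_equal(unname(res$scores["a"]), 0.1 / 0.19, tolerance = 1e-8)
  expect_equal(unname(res$scores["b"]), 0.09 / 0.19, tolerance = 1e-8)
  # prior-only limit
  res0 <- prince_propagate(two_nodes, "a", propagation_config(alpha = 0))
  expect_equal(unname(res0$scores), c(1, 0))

  set.seed(73)
  for (trial in 1:10) {
    net <- random_gene_network(sample(10:30, 1), 0.2,
                               weighted = trial %% 2 == 0)
    seeds <- sample(net$nodes, sample(1:3, 1))
    res <- prince_propagate(net, seeds)
    want <- oracle_prince_solve(net, seeds, 0.9)
    expect_lt(sum(abs(res$scores - want)), 1e-8)
  }
})

test_that("halting triggers exactly when the L1 step change drops below tol", {
  set.seed(79)
  net <- random_gene_network(20, 0.25)
  seeds <- sample(net$nodes, 2)
  res <- random_walk(net, seeds)
  # replay the iteration manually and find the first sub-tolerance step
  W <- as.matrix(rw_transition_matrix(net))
  p0 <- setNames(numeric(length(net$nodes)), net$nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  it <- 0
  repeat {
    p_next <- 0.5 * as.numeric(W %*% p) + 0.5 * p0
    it <- it + 1
    resid <- sum(abs(p_next - p))
    p <- p_next
    if (resid < 1e-10) break
  }
  expect_equal(res$iterations, it)
  expect_lt(res$residual, 1e-10)
  expect_error(random_walk(net, seeds,
                           propagation_config(max_iterations = 2)),
               "did not converge")
})

test_that("residuals contract monotonically after the first iteration", {
  set.seed(83)
  for (trial in 1:10) {
    net <- random_gene_network(sample(10:25, 1), 0.25)
    seeds <- sample(net$nodes, 1)
    # manual replay of both operators, tracking residuals
    W <- as.matrix(rw_transition_matrix(net))
    Wp <- as.matrix(prince_normalized_matrix(net))
    p0 <- setNames(numeric(length(net$nodes)), net$nodes)
    p0[seeds] <- 1
    for (case in c("rw", "pr")) {
      p <- p0
      resids <- numeric()
      for (i in 1:60) {
        p_next <- if (case == "rw") 0.5 * as.numeric(W %*% p) + 0.5 * p0
                  else 0.9 * as.numeric(Wp %*% p) + 0.1 * p0
        resids <- c(resids, sum(abs(p_next - p)))
        p <- p_next
      }
      expect_true(all(diff(resids[-1]) <= 1e-12))
    }
  }
})

test_that("permuting gene labels permutes propagation output identically", {
  set.seed(89)
  net <- random_gene_network(15, 0.3, weighted = TRUE)
  seeds <- sample(net$nodes, 2)
  relabel <- setNames(sprintf("z%02d", sample(15)), net$nodes)
  edges2 <- data.frame(from = unname(relabel[net$edges$from]),
                       to = unname(relabel[net$edges$to]),
                       weight = net$edges$weight)
  net2 <- gene_network(edges2, nodes = unname(relabel), weighted = TRUE)
  for (fn in c(random_walk, prince_propagate)) {
    a <- fn(net, seeds)$scores
    b <- fn(net2, unname(relabel[seeds]))$scores
    expect_equal(unname(b[relabel[names(a)]]), unname(a), tolerance = 1e-12)
  }
})

test_that("propagation scores restrict and rank over candidates", {
  scores <- structure(list(scores = c(a = 0.5, b = 0.3, c = 0.2),
                           iterations = 1L, converged = TRUE,
                           residual = 0, mass_range = c(1, 1),
                           method = "rw"),
                      class = "node_scores")
  rl <- propagation_ranked_list(scores, c("b", "c"))
  expect_equal(rl$gene, c("b", "c"))
  expect_equal(rl$rank, c(1, 2))
  expect_error(propagation_ranked_list(scores, c("b", "zz")),
               "without a score")
  tied <- structure(list(scores = c(a = 0, b = 0, c = 0), iterations = 1L,
                         converged = TRUE, residual = 0,
                         mass_range = c(0, 0), method = "rw"),
                    class = "node_scores")
  expect_true(all(propagation_ranked_list(tied, c("a", "b", "c"))$rank == 2))
})
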