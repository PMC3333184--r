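# Independent oracles and small random-graph generators used across the
# suite. Everything here is deliberately naive (explicit loops, dense
# algebra) so it shares no code path with the package implementation.

# naive ICN: enumerate the shared-neighbour set with intersect() and
# evaluate the formula term by term
oracle_icn <- function(network, i, j) {
  stopifnot(i != j)
  edge_w <- function(a, b) {
    e <- network$edges
    hit <- (e$from == a & e$to == b) | (e$from == b & e$to == a)
    if (any(hit)) e$weight[hit] else 0
  }
  k <- sapply(network$nodes, function(g) {
    nb <- gene_neighbors(network, g)
    if (length(nb)) sum(sapply(nb, edge_w, a = g)) else 0
  })
  connectors <- intersect(gene_neighbors(network, i),
                          gene_neighbors(network, j))
  conn_sum <- 0
  for (u in connectors) conn_sum <- conn_sum + edge_w(i, u) * edge_w(u, j)
  E <- k[[i]] * k[[j]] / sum(k)
  edge_w(i, j) + if (E > 0) conn_sum / E else 0
}

# naive seed-sum scoring + sort (skips self-pairs like the implementation)
oracle_candidate_ranking <- function(network, seeds, candidates) {
  score <- sapply(candidates, function(cand) {
    s <- 0
    for (sd in setdiff(seeds, cand)) s <- s + oracle_icn(network, cand, sd)
    s
  })
  data.frame(gene = candidates, score = unname(score),
             rank = rank(-score, ties.method = "average"),
             stringsAsFactors = FALSE)
}

# dense closed-form solves for the propagation fixed points
oracle_rw_solve <- function(network, seeds, r) {
  W <- as.matrix(rw_transition_matrix(network))
  n <- length(network$nodes)
  p0 <- setNames(numeric(n), network$nodes)
  p0[seeds] <- 1 / length(seeds)
  setNames(as.numeric(solve(diag(n) - (1 - r) * W, r * p0)), network$nodes)
}

oracle_prince_solve <- function(network, seeds, alpha) {
  Wp <- as.matrix(prince_normalized_matrix(network))
  n <- length(network$nodes)
  Y <- setNames(numeric(n), network$nodes)
  Y[seeds] <- 1
  setNames(as.numeric((1 - alpha) * solve(diag(n) - alpha * Wp, Y)),
           network$nodes)
}

# Erdos-Renyi graph over n nodes; guarantees at least one edge
random_gene_network <- function(n, p = 0.3, weighted = FALSE) {
  nodes <- sprintf("g%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  repeat {
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) break
  }
  w <- if (weighted) runif(sum(keep), 0.05, 1) else rep(1, sum(keep))
  gene_network(data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                          weight = w, stringsAsFactors = FALSE),
               nodes = nodes, weighted = weighted)
}

# small planted-module graph via the package generator with random seed
random_planted_network <- function(n_modules = 2, module_size = 5,
                                   n_background = 10, weighted = FALSE) {
  spec <- synthetic_spec(n_modules, module_size, n_background,
                         p_within = 0.7, p_between = 0.1,
                         weight_model = if (weighted) "uniform" else "unit",
                         weight_par = c(0.1, 1),
                         rng_seed = sample.int(1e6, 1))
  generate_planted_network(spec)
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
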