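#' Propagation settings
#'
#' Bundles the parameters of the two propagation baselines. The defaults are
#' the fixed values used throughout the benchmark: restart probability
#' `r = 0.5` for the random walk, `alpha = 0.9` for PRINCE-style
#' propagation, and iteration until the L1 change between successive score
#' vectors falls below `1e-10`.
#'
#' @param restart restart probability \eqn{r \in [0, 1]}: per step, the
#'   probability the walker jumps back to the seed distribution.
#' @param alpha \eqn{\alpha \in [0, 1]}: relative weight of network
#'   smoothing versus the prior in PRINCE-style propagation.
#' @param tolerance positive convergence threshold on the L1 step change.
#' @param max_iterations iteration cap; exceeding it is an error carrying
#'   the last residual.
#' @return A list of class `propagation_config`.
#' @export
propagation_config <- function(restart = 0.5, alpha = 0.9,
                               tolerance = 1e-10, max_iterations = 1e6) {
  stopifnot(restart >= 0, restart <= 1, alpha >= 0, alpha <= 1,
            tolerance > 0, max_iterations >= 1)
  structure(list(restart = restart, alpha = alpha, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "propagation_config")
}

#' Random-walk transition matrix
#'
#' Column-stochastic operator of the random walk: from gene *v* the walker
#' moves to neighbour *u* with probability \eqn{\omega_{v,u} / k_v},
#' proportional to the connecting edge's weight. Isolated genes get a
#' self-transition of 1 so the matrix stays stochastic and probability mass
#' is conserved.
#'
#' @param network a [gene_network].
#' @return A sparse column-stochastic matrix with dimnames = network nodes.
#' @export
rw_transition_matrix <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  k <- network$strength
  iso <- k == 0
  inv <- ifelse(iso, 0, 1 / k)
  W <- network$adjacency %*% Matrix::Diagonal(x = inv)
  if (any(iso)) {
    n <- length(k)
    W <- W + Matrix::sparseMatrix(i = which(iso), j = which(iso),
                                  x = 1, dims = c(n, n))
  }
  dimnames(W) <- list(network$nodes, network$nodes)
  W
}

#' Random walk with restart
#'
#' Simulates a walker starting from the seed genes: at each step it moves to
#' a neighbour with probability proportional to the edge weight, or restarts
#' at the seed distribution with probability `restart`. Iterates
#' \deqn{p^{(t+1)} = (1 - r)\,W\,p^{(t)} + r\,p^0}
#' with \eqn{p^0} uniform over the seeds and \eqn{p^{(0)} = p^0}, halting as
#' soon as \eqn{\lVert p^{(t+1)} - p^{(t)} \rVert_1} drops below the
#' configured tolerance. The stationary vector scores every network gene.
#'
#' @param network a [gene_network].
#' @param seeds non-empty character vector of seed genes in the network.
#' @param config a [propagation_config()].
#' @return A `node_scores` object: list with `scores` (named numeric over
#'   all nodes), `iterations`, `converged`, `residual` (last L1 change) and
#'   `mass_range` (range of the score-vector sum across iterations; stays at
#'   1 for this mass-conserving walk).
#' @export
random_walk <- function(network, seeds, config = propagation_config()) {
  stopifnot(inherits(network, "gene_network"),
            inherits(config, "propagation_config"))
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("empty seed set")
  .check_genes(network, seeds)
  W <- rw_transition_matrix(network)
  p0 <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  p0[seeds] <- 1 / length(seeds)
  r <- config$restart
  .iterate_propagation(
    step = function(p) (1 - r) * as.numeric(W %*% p) + r * p0,
    init = p0, config = config, method = "rw"
  )
}

#' PRINCE-style normalized adjacency
#'
#' Symmetric strength-normalized operator
#' \eqn{W' = D^{-1/2} W D^{-1/2}} where \eqn{W} is the weighted adjacency
#' and \eqn{D} the diagonal matrix of strengths. Rows and columns of
#' isolated genes are zero.
#'
#' @param network a [gene_network].
#' @return A sparse symmetric matrix with dimnames = network nodes.
#' @export
prince_normalized_matrix <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  k <- network$strength
  s <- ifelse(k > 0, 1 / sqrt(k), 0)
  D <- Matrix::Diagonal(x = s)
  Wp <- D %*% network$adjacency %*% D
  dimnames(Wp) <- list(network$nodes, network$nodes)
  Wp
}

#' PRINCE-style label propagation
#'
#' Smooths a seed-gene prior over the network so adjacent genes receive
#' similar values: iterates
#' \deqn{F^{(t)} = \alpha\,W'\,F^{(t-1)} + (1 - \alpha)\,Y}
#' from \eqn{F^{(0)} = Y}, with \eqn{Y} the binary seed indicator and
#' \eqn{W'} the symmetric strength-normalized adjacency, halting when the L1
#' change drops below the tolerance. The limit equals
#' \eqn{(1-\alpha)(I - \alpha W')^{-1} Y}. The prior here is the plain seed
#' indicator: no phenotype-similarity weighting enters the trials.
#'
#' @inheritParams random_walk
#' @return A `node_scores` object (see [random_walk()]).
#' @export
prince_propagate <- function(network, seeds, config = propagation_config()) {
  stopifnot(inherits(network, "gene_network"),
            inherits(config, "propagation_config"))
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("empty seed set")
  .check_genes(network, seeds)
  Wp <- prince_normalized_matrix(network)
  Y <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  Y[seeds] <- 1
  a <- config$alpha
  .iterate_propagation(
    step = function(f) a * as.numeric(Wp %*% f) + (1 - a) * Y,
    init = Y, config = config, method = "prince"
  )
}

# Shared fixed-point loop with the L1 halting rule; errors past the
# iteration cap, carrying the last residual.
.iterate_propagation <- function(step, init, config, method) {
  p <- init
  mass <- sum(p)
  mass_range <- c(mass, mass)
  residual <- Inf
  iter <- 0L
  repeat {
    p_next <- step(p)
    names(p_next) <- names(init)
    iter <- iter + 1L
    residual <- sum(abs(p_next - p))
    m <- sum(p_next)
    mass_range <- range(mass_range, m)
    p <- p_next
    if (residual < config$tolerance) break
    if (iter >= config$max_iterations)
      stop(sprintf("%s did not converge in %d iterations (last L1 residual %.3g)",
                   method, iter, residual))
  }
  structure(list(scores = p, iterations = iter, converged = TRUE,
                 residual = residual, mass_range = mass_range,
                 method = method),
            class = "node_scores")
}

#' @export
print.node_scores <- function(x, ...) {
  cat(sprintf("node_scores (%s): %d genes, %d iterations, residual %.2e\n",
              x$method, length(x$scores), x$iterations, x$residual))
  invisible(x)
}

#' Restrict propagation scores to a candidate set and rank
#'
#' @param scores a `node_scores` object from [random_walk()] or
#'   [prince_propagate()].
#' @param candidates character vector of candidate genes; each must have a
#'   score.
#' @return A [ranked_list] labelled with the propagation method.
#' @export
propagation_ranked_list <- function(scores, candidates) {
  stopifnot(inherits(scores, "node_scores"))
  candidates <- as.character(candidates)
  missing <- setdiff(candidates, names(scores$scores))
  if (length(missing))
    stop("candidate(s) without a score: ", paste(missing, collapse = ", "))
  assign_ranks(scores$scores[candidates], method = scores$method)
}

#' Score and rank candidates with one method
#'
#' Single entry point used by the evaluation harness and the CLI: computes
#' the score vector for the seed set with the requested method and returns
#' the ranked candidate list. `"icn"` is the parameter-free
#' interconnectedness score; `"rw"` the random walk with restart; `"pr"`
#' PRINCE-style propagation.
#'
#' @param network a [gene_network].
#' @param seeds non-empty seed gene set.
#' @param candidates non-empty candidate gene set.
#' @param method one of `"icn"`, `"rw"`, `"pr"`.
#' @param config a [propagation_config()] (ignored by `"icn"`).
#' @return A [ranked_list].
#' @export
prioritize_candidates <- function(network, seeds, candidates,
                                  method = c("icn", "rw", "pr"),
                                  config = propagation_config()) {
  method <- match.arg(method)
  switch(method,
    icn = candidate_scores(network, seeds, candidates),
    rw = {
      rl <- propagation_ranked_list(random_walk(network, seeds, config),
                                    candidates)
      attr(rl, "method") <- "rw"
      attr(rl, "seeds") <- seeds
      rl
    },
    pr = {
      rl <- propagation_ranked_list(prince_propagate(network, seeds, config),
                                    candidates)
      attr(rl, "method") <- "pr"
      attr(rl, "seeds") <- seeds
      rl
    }
  )
}
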