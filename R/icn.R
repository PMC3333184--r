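#' Interconnectedness (ICN) score between two genes
#'
#' The interconnectedness of genes *i* and *j* measures their closeness in
#' the network by combining their direct connection with the evidence from
#' shared interaction partners ("connectors"): genes adjacent to both *i*
#' and *j*. The connector contribution is normalized by the number of
#' connectors expected from the two genes' strengths, so that hub genes do
#' not dominate merely by having many neighbours:
#'
#' \deqn{ICN_{i,j} = \omega_{i,j} +
#'   \frac{\sum_{u \in N_i \cap N_j} \omega_{i,u}\,\omega_{u,j}}{E_{i,j}},
#'   \qquad E_{i,j} = \frac{k_i\,k_j}{\sum_g k_g}}
#'
#' where \eqn{N_i} is the neighbour set of gene *i*, \eqn{\omega} the edge
#' weight and \eqn{k_i} the strength ([gene_strength()]). On an unweighted
#' network the connector sum is simply the shared-neighbour count and
#' \eqn{k_i} the degree. When \eqn{E_{i,j} = 0} (an isolated endpoint) the
#' connector term is 0 — the connector sum is then necessarily 0 as well.
#' The score has no tunable parameter. It is symmetric in *i* and *j*, and
#' it is 0 exactly when the genes share neither an edge nor a neighbour.
#'
#' The score of a gene with itself is undefined and raises an error.
#'
#' @param network a [gene_network].
#' @param i,j distinct gene identifiers present in the network.
#' @return Non-negative numeric scalar.
#' @examples
#' net <- gene_network(data.frame(
#'   from = c("a", "u", "u", "u"), to = c("u", "b", "c", "d")))
#' icn_score(net, "a", "b")
#' @export
icn_score <- function(network, i, j) {
  stopifnot(inherits(network, "gene_network"))
  .check_genes(network, c(i, j))
  if (i == j) stop("ICN of a gene with itself is undefined")
  drop(.icn_matrix(network, i, j))
}

# ICN for all (rows x cols) gene pairs at once, via sparse row/column
# products: connector sums are entries of A[rows,] %*% A[,cols]. This is the
# production path; tests check it against a naive neighbour-enumeration
# oracle. Diagonal (i == j) entries, if rows and cols intersect, are
# meaningless here and must be masked by the caller.
.icn_matrix <- function(network, rows, cols) {
  A <- network$adjacency
  k <- network$strength
  K <- sum(k)
  Ar <- A[rows, , drop = FALSE]
  Ac <- A[, cols, drop = FALSE]
  conn <- as.matrix(Ar %*% Ac)
  direct <- as.matrix(A[rows, cols, drop = FALSE])
  E <- outer(unname(k[rows]), unname(k[cols])) / K
  connector_term <- ifelse(E > 0, conn / E, 0)
  direct + connector_term
}

#' Score and rank candidate genes against a seed set
#'
#' Scores each candidate gene by the sum of its interconnectedness to the
#' seed genes \eqn{S_d} (the known genes of the disease family):
#' \deqn{Score_i = \sum_{j \in S_d} ICN_{i,j}}
#' and ranks candidates by descending score with average ranks for ties.
#' A candidate that is itself a seed (possible when a family member falls
#' inside a linkage window) contributes no self-pair term: the sum runs over
#' the other seeds only.
#'
#' @param network a [gene_network].
#' @param seeds non-empty character vector of seed genes (all in the network).
#' @param candidates non-empty character vector of candidate genes (all in
#'   the network).
#' @return A [ranked_list] with method label `"icn"`.
#' @export
candidate_scores <- function(network, seeds, candidates) {
  stopifnot(inherits(network, "gene_network"))
  seeds <- unique(as.character(seeds))
  candidates <- as.character(candidates)
  if (!length(seeds)) stop("empty seed set")
  if (!length(candidates)) stop("empty candidate set")
  if (anyDuplicated(candidates)) stop("duplicate candidate genes")
  .check_genes(network, c(seeds, candidates))
  icn <- .icn_matrix(network, candidates, seeds)
  # mask self-pairs for candidates that are also seeds
  overlap <- intersect(candidates, seeds)
  for (g in overlap) icn[g, g] <- 0
  scores <- rowSums(icn)
  assign_ranks(data.frame(gene = candidates, score = unname(scores),
                          stringsAsFactors = FALSE),
               method = "icn", seeds = seeds)
}
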