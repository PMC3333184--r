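#' Construct a gene network
#'
#' Builds an undirected, optionally weighted gene network from an edge table.
#' The network is the substrate for every scoring method in the package: a
#' set of gene identifiers (opaque strings), a set of unordered gene pairs
#' with weights in (0, 1], and a sparse symmetric adjacency matrix used by
#' the interconnectedness and propagation computations.
#'
#' The constructor enforces the container invariants: no self-loops, each
#' unordered pair stored once, all weights in (0, 1]. Inputs violating them
#' raise an error; use [load_edge_list()] to read and sanitize raw edge-list
#' files (it removes self-loops and collapses duplicates before calling this
#' constructor).
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`
#'   (defaulted to 1 when absent or when `weighted = FALSE`).
#' @param nodes optional character vector of node identifiers; the node set
#'   is the union of `nodes` and all edge endpoints, so isolated genes can be
#'   represented.
#' @param weighted logical; `FALSE` forces every weight to 1 (the
#'   protein-interaction-network convention where an edge is present or not).
#'
#' @return An object of class `gene_network`: a list with elements `nodes`
#'   (sorted character vector), `edges` (data.frame `from`, `to`, `weight`
#'   with `from < to` lexicographically), `weighted` (logical), `adjacency`
#'   (sparse symmetric `dgCMatrix` with zero diagonal) and `strength` (named
#'   numeric, row sums of the adjacency).
#' @seealso [load_edge_list()], [gene_strength()], [icn_score()]
#' @export
gene_network <- function(edges, nodes = NULL, weighted = TRUE) {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges)))
    stop("'edges' must be a data.frame with columns 'from' and 'to'")
  from <- as.character(edges$from)
  to   <- as.character(edges$to)
  if (!weighted || is.null(edges$weight)) {
    weight <- rep(1, length(from))
  } else {
    weight <- as.numeric(edges$weight)
  }
  if (any(from == to))
    stop("self-loops are not allowed in a gene_network")
  if (anyNA(weight) || any(weight <= 0) || any(weight > 1))
    stop("edge weights must lie in (0, 1]")
  # canonical orientation: smaller identifier first
  a <- pmin(from, to)
  b <- pmax(from, to)
  if (anyDuplicated(paste(a, b, sep = "\r")))
    stop("duplicate gene pairs are not allowed in a gene_network")
  ord <- order(a, b, method = "radix")
  a <- a[ord]; b <- b[ord]; weight <- weight[ord]
  nodes <- sort(unique(c(as.character(nodes), a, b)), method = "radix")
  n <- length(nodes)
  ia <- match(a, nodes)
  ib <- match(b, nodes)
  adjacency <- Matrix::sparseMatrix(
    i = c(ia, ib), j = c(ib, ia), x = c(weight, weight),
    dims = c(n, n), dimnames = list(nodes, nodes)
  )
  strength <- Matrix::rowSums(adjacency)
  names(strength) <- nodes
  structure(
    list(
      nodes = nodes,
      edges = data.frame(from = a, to = b, weight = weight,
                         stringsAsFactors = FALSE),
      weighted = weighted,
      adjacency = adjacency,
      strength = strength
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (%s)\n",
              length(x$nodes), nrow(x$edges),
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Number of nodes and edges
#'
#' @param network a `gene_network`.
#' @return Integer count.
#' @export
network_size <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  c(nodes = length(network$nodes), edges = nrow(network$edges))
}

#' Neighbours of a gene
#'
#' @param network a `gene_network`.
#' @param gene a gene identifier present in the network.
#' @return Character vector of adjacent gene identifiers (possibly empty).
#' @export
gene_neighbors <- function(network, gene) {
  stopifnot(inherits(network, "gene_network"))
  .check_genes(network, gene)
  row <- network$adjacency[gene, ]
  names(row)[row > 0]
}

#' Strength of a gene
#'
#' The strength \eqn{k_i} of gene *i* is the sum of the weights of its
#' incident edges; on an unweighted network it equals the degree. It is the
#' normalizing quantity of the interconnectedness score and the column
#' normalizer of the random-walk transition matrix.
#'
#' @inheritParams gene_neighbors
#' @return Non-negative numeric scalar (0 for an isolated gene).
#' @examples
#' net <- gene_network(data.frame(from = c("a", "a"), to = c("b", "c"),
#'                                weight = c(0.5, 0.7)))
#' gene_strength(net, "a")  # 1.2
#' @export
gene_strength <- function(network, gene) {
  stopifnot(inherits(network, "gene_network"))
  .check_genes(network, gene)
  unname(network$strength[gene])
}

.check_genes <- function(network, genes) {
  missing <- setdiff(genes, network$nodes)
  if (length(missing))
    stop("gene(s) not in network: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

# igraph view of the network for shortest-path queries; edge weights are
# deliberately ignored downstream (hop distances only).
.as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")],
    directed = FALSE,
    vertices = network$nodes
  )
}
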