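#' Load a gene network from a tab-separated edge list
#'
#' Reads a TSV edge list (`gene_a<TAB>gene_b[<TAB>weight]`), sanitizes it and
#' returns a [gene_network]. Sanitation follows the usual
#' interaction-database hygiene rules: self-interacting pairs are removed,
#' duplicate pairs (in either orientation) are collapsed keeping the maximum
#' weight, and raw weights are rescaled to (0, 1] by `weight_scale` so that
#' STRING-style combined scores on a 0-1000 scale can be ingested directly.
#' Edges whose weight is exactly 0 after rescaling are dropped (an edge of
#' weight 0 is indistinguishable from no edge in every score).
#'
#' Lines starting with `#` and blank lines are ignored. In weighted mode a
#' header line is auto-detected: if the third column of the first data line
#' does not parse as a number, that line is skipped.
#'
#' @param path path to the edge-list file.
#' @param weighted logical; if `FALSE` the third column (if any) is ignored
#'   and every weight is forced to 1.
#' @param weight_scale positive number dividing raw weights; use 1 for
#'   weights already in \[0, 1\] and 1000 for STRING combined scores.
#' @return A `gene_network` whose `"report"` attribute is a list with the
#'   load statistics: `n_nodes`, `n_edges`, `self_loops_removed`,
#'   `duplicates_collapsed`, `zero_weight_dropped`.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\t800", "B\tC\t400"), f)
#' net <- load_edge_list(f, weighted = TRUE, weight_scale = 1000)
#' attr(net, "report")$n_edges  # 2
#' @export
load_edge_list <- function(path, weighted = FALSE, weight_scale = 1) {
  stopifnot(length(weight_scale) == 1, is.finite(weight_scale), weight_scale > 0)
  raw <- .read_tsv_lines(path)
  if (!nrow(raw$fields))
    stop("empty network: no data lines in ", path)
  fields <- raw$fields
  lineno <- raw$lineno

  bad <- is.na(fields[[2]]) | fields[[1]] == "" | fields[[2]] == ""
  if (any(bad))
    stop("malformed edge line (need >= 2 columns) at line ", lineno[which(bad)[1]],
         " of ", path)

  if (weighted) {
    if (ncol(fields) < 3 || all(is.na(fields[[3]])))
      stop("weighted mode requires a third (weight) column in ", path)
    w_raw <- suppressWarnings(as.numeric(fields[[3]]))
    # header auto-detection: non-numeric weight on the first data line only
    if (is.na(w_raw[1]) && !is.na(fields[[3]][1]) && nrow(fields) > 1) {
      fields <- fields[-1, , drop = FALSE]
      lineno <- lineno[-1]
      w_raw <- w_raw[-1]
    }
    if (anyNA(w_raw))
      stop("non-numeric weight at line ", lineno[which(is.na(w_raw))[1]],
           " of ", path)
    out_of_range <- w_raw < 0 | w_raw > weight_scale
    if (any(out_of_range))
      stop("weight outside (0, ", weight_scale, "] at line ",
           lineno[which(out_of_range)[1]], " of ", path)
    weight <- w_raw / weight_scale
  } else {
    weight <- rep(1, nrow(fields))
  }

  from <- fields[[1]]
  to <- fields[[2]]

  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]; weight <- weight[!self]

  zero <- weight == 0
  n_zero <- sum(zero)
  from <- from[!zero]; to <- to[!zero]; weight <- weight[!zero]

  if (!length(from))
    stop("empty network: no edges survive sanitation in ", path)

  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  # duplicate resolution: keep the maximum weight (order-independent)
  agg <- tapply(weight, key, max)
  n_dup <- length(key) - length(agg)
  pair <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(
    from = vapply(pair, `[`, "", 1L),
    to = vapply(pair, `[`, "", 2L),
    weight = as.numeric(agg),
    stringsAsFactors = FALSE
  )
  net <- gene_network(edges, weighted = weighted)
  attr(net, "report") <- list(
    n_nodes = length(net$nodes),
    n_edges = nrow(net$edges),
    self_loops_removed = n_self,
    duplicates_collapsed = n_dup,
    zero_weight_dropped = n_zero
  )
  net
}

#' Load a disease-family table
#'
#' Reads TSV `family_id<TAB>gene_id` associations and applies the two
#' filtering rules of the evaluation protocol, in order: (1) member genes
#' absent from the network are dropped from their families; (2) families
#' left with fewer than two members are dropped entirely (a single-gene
#' family cannot supply seed genes once its one member is held out).
#'
#' @param path path to the association file.
#' @param network the `gene_network` the families must live on.
#' @return A named list of class `disease_families` mapping family id to a
#'   character vector of member genes, with a `"report"` attribute listing
#'   `genes_dropped` and `families_dropped`.
#' @export
load_disease_families <- function(path, network) {
  stopifnot(inherits(network, "gene_network"))
  raw <- .read_tsv_lines(path)
  fields <- raw$fields
  if (!nrow(fields))
    stop("no disease-gene associations in ", path)
  bad <- is.na(fields[[2]]) | fields[[1]] == "" | fields[[2]] == ""
  if (any(bad))
    stop("malformed association line at line ", raw$lineno[which(bad)[1]],
         " of ", path)
  fam <- split(fields[[2]], fields[[1]])
  fam <- lapply(fam, unique)
  kept <- lapply(fam, intersect, network$nodes)
  genes_dropped <- sum(lengths(fam)) - sum(lengths(kept))
  sizes <- lengths(kept)
  out <- kept[sizes >= 2]
  families_dropped <- length(kept) - length(out)
  if (!length(out))
    stop("no disease family with >= 2 network genes survives filtering in ", path)
  structure(out, class = "disease_families",
            report = list(genes_dropped = genes_dropped,
                          families_dropped = families_dropped))
}

#' @export
print.disease_families <- function(x, ...) {
  cat(sprintf("disease_families: %d families, %d associations\n",
              length(x), sum(lengths(x))))
  invisible(x)
}

#' Load a gene-position table
#'
#' Reads TSV `gene_id<TAB>chromosome<TAB>start` rows giving each gene one
#' genomic position. Only the relative order of starts within a chromosome
#' is ever used (to pick flanking genes in the simulated-linkage scenario);
#' ties in start are broken by lexicographic gene id so the per-chromosome
#' order is total and deterministic.
#'
#' @param path path to the position file.
#' @return A data.frame of class `gene_positions` with columns `gene`,
#'   `chromosome`, `start`, sorted by (chromosome, start, gene).
#' @export
load_positions <- function(path) {
  raw <- .read_tsv_lines(path)
  fields <- raw$fields
  if (!nrow(fields) || ncol(fields) < 3)
    stop("position file needs 3 columns (gene, chromosome, start): ", path)
  bad <- is.na(fields[[3]]) | fields[[1]] == "" | fields[[2]] == ""
  if (any(bad))
    stop("malformed position line at line ", raw$lineno[which(bad)[1]],
         " of ", path)
  start <- suppressWarnings(as.numeric(fields[[3]]))
  nonint <- is.na(start) | start != floor(start) | start < 0
  if (any(nonint))
    stop("start is not a non-negative integer at line ",
         raw$lineno[which(nonint)[1]], " of ", path)
  gene <- fields[[1]]
  if (anyDuplicated(gene))
    stop("duplicate gene id in position table: ",
         gene[duplicated(gene)][1])
  out <- data.frame(gene = gene, chromosome = fields[[2]],
                    start = as.integer(start), stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$start, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("gene_positions", "data.frame")
  out
}

#' Write package objects back to their TSV formats
#'
#' Writers matching the three loaders, used by the simulation CLI and to
#' assert the round-trip invariant (write then reload reproduces the same
#' object). Weights are written with 17 significant digits so doubles
#' survive the round trip exactly.
#'
#' @param network a `gene_network`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  e <- network$edges
  lines <- if (network$weighted) {
    sprintf("%s\t%s\t%.17g", e$from, e$to, e$weight)
  } else {
    sprintf("%s\t%s", e$from, e$to)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param families a `disease_families` object.
#' @export
write_disease_families <- function(families, path) {
  stopifnot(inherits(families, "disease_families"))
  lines <- unlist(lapply(names(families), function(f)
    sprintf("%s\t%s", f, families[[f]])))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param positions a `gene_positions` table.
#' @export
write_positions <- function(positions, path) {
  stopifnot(inherits(positions, "gene_positions"))
  writeLines(sprintf("%s\t%s\t%d", positions$gene, positions$chromosome,
                     positions$start), path)
  invisible(path)
}

# Shared low-level reader: UTF-8 TSV, '#' comments and blank lines skipped.
# Returns the split fields as a data.frame of characters (ragged rows padded
# with NA) plus the original line numbers for error messages.
.read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- if (length(parts)) max(lengths(parts)) else 0L
  fields <- as.data.frame(
    do.call(rbind, lapply(parts, function(p) c(p, rep(NA_character_, ncol - length(p))))),
    stringsAsFactors = FALSE
  )
  list(fields = fields, lineno = lineno)
}
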