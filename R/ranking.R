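#' Rank a score table
#'
#' Converts per-gene scores into a ranked candidate list. Ranking is by
#' descending score; tied scores share the average of the rank positions
#' they span (two genes tied at the top both get rank 1.5), which keeps the
#' ranking independent of input order and feeds the rank-product combination
#' deterministically.
#'
#' @param scores a data.frame with columns `gene` and `score`, or a named
#'   numeric vector.
#' @param method optional method label stored on the result.
#' @param seeds optional seed set stored on the result.
#' @return A `ranked_list`: a data.frame with columns `gene`, `score`,
#'   `rank`, ordered by increasing rank, with attributes `method` and
#'   `seeds`.
#' @examples
#' assign_ranks(c(a = 2, b = 2, c = 1))  # a, b share rank 1.5
#' @export
assign_ranks <- function(scores, method = NA_character_, seeds = NULL) {
  if (is.numeric(scores) && !is.null(names(scores)))
    scores <- data.frame(gene = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE)
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)))
  if (!nrow(scores)) stop("cannot rank an empty score table")
  if (anyNA(scores$score) || any(is.nan(scores$score)))
    stop("NaN/NA score cannot be ranked")
  rk <- rank(-scores$score, ties.method = "average")
  out <- data.frame(gene = as.character(scores$gene), score = scores$score,
                    rank = rk, stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), ]
  rownames(out) <- NULL
  structure(out, class = c("ranked_list", "data.frame"),
            method = method, seeds = seeds)
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  m <- attr(x, "method")
  cat(sprintf("ranked_list (%s): %d candidates\n",
              if (is.na(m)) "unlabelled" else m, nrow(x)))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

# rank of one gene inside a ranked_list (NA if absent)
.rank_of <- function(ranked, gene) {
  i <- match(gene, ranked$gene)
  if (is.na(i)) NA_real_ else ranked$rank[i]
}
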