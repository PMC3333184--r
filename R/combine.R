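#' Combine method rankings by rank product
#'
#' Merges the ranked lists produced by different prioritization methods over
#' the same candidate set into one ordering. Each candidate's combined score
#' is the product of its per-method ranks,
#' \deqn{CS_i = \prod_j R_{i,j},}
#' and candidates are re-ranked by ascending combined score — the lower the
#' product, the higher the priority. Fractional ranks arising from
#' tie-averaging multiply as-is; ties in the combined score get average
#' final ranks. The result does not depend on the order in which the method
#' rankings are supplied.
#'
#' @param rankings a list of [ranked_list] objects over the identical
#'   candidate set (at least two, unless `allow_single`).
#' @param allow_single permit a degenerate single-method "combination"
#'   (returns the input ordering).
#' @return A `combined_ranking`: data.frame with columns `gene`,
#'   `combined_score`, `rank`, ordered by increasing rank, with attribute
#'   `methods` naming the contributing methods.
#' @examples
#' a <- assign_ranks(c(A = 3, B = 2, C = 1), method = "m1")
#' b <- assign_ranks(c(A = 1, B = 3, C = 2), method = "m2")
#' combine_rankings(list(a, b))
#' @export
combine_rankings <- function(rankings, allow_single = FALSE) {
  if (!is.list(rankings) || !length(rankings))
    stop("'rankings' must be a non-empty list of ranked_list objects")
  if (!all(vapply(rankings, inherits, TRUE, "ranked_list")))
    stop("every element of 'rankings' must be a ranked_list")
  if (length(rankings) < 2 && !allow_single)
    stop("need at least two rankings to combine")
  genes <- sort(rankings[[1]]$gene)
  for (rl in rankings[-1]) {
    other <- sort(rl$gene)
    if (!identical(genes, other)) {
      diff <- c(setdiff(genes, other), setdiff(other, genes))
      stop("rankings cover different candidate sets; symmetric difference: ",
           paste(diff, collapse = ", "))
    }
  }
  cs <- rep(1, length(genes))
  for (rl in rankings)
    cs <- cs * rl$rank[match(genes, rl$gene)]
  final <- rank(cs, ties.method = "average")
  out <- data.frame(gene = genes, combined_score = cs, rank = final,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), ]
  rownames(out) <- NULL
  methods <- sort(vapply(rankings, function(rl) {
    m <- attr(rl, "method")
    if (is.null(m) || is.na(m)) "?" else m
  }, ""))
  structure(out, class = c("combined_ranking", "data.frame"),
            methods = methods)
}

#' @export
print.combined_ranking <- function(x, n = 10, ...) {
  cat(sprintf("combined_ranking (%s): %d candidates\n",
              paste(attr(x, "methods"), collapse = " * "), nrow(x)))
  print.data.frame(utils::head(x, n), ...)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

# Named combination presets over the base method labels.
.combine_presets <- list(
  "icn-rw" = c("icn", "rw"),
  "icn-pr" = c("icn", "pr"),
  "rw-pr" = c("rw", "pr"),
  "icn-rw-pr" = c("icn", "rw", "pr")
)

#' Combination presets
#'
#' Names of the built-in rank-product combination schemes over the base
#' methods (`icn`, `rw`, `pr`): `icn-rw`, `icn-pr`, `rw-pr`, `icn-rw-pr`.
#'
#' @param methods base methods available; only presets fully covered by them
#'   are returned.
#' @return Named list mapping preset name to its component method labels.
#' @export
combination_presets <- function(methods = c("icn", "rw", "pr")) {
  Filter(function(m) all(m %in% methods), .combine_presets)
}
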