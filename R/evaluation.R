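#' Candidate set for the simulated-linkage scenario
#'
#' Emulates a linkage interval around a test disease gene: the candidate set
#' is the test gene plus the `flank_total` network-present genes nearest to
#' it on the same chromosome, split evenly up- and downstream (50/50 by
#' default) and borrowing from the other side at chromosome ends. Restricting
#' to network-present genes keeps every candidate scoreable; a chromosome
#' with too few genes yields a smaller set with a warning.
#'
#' @param test_gene the held-out disease gene (must have a position).
#' @param positions a [load_positions()] table.
#' @param network a [gene_network]; only its member genes are candidates.
#' @param flank_total even number of flanking genes to take in total.
#' @return Character vector of candidate genes in chromosomal order,
#'   including `test_gene`.
#' @export
linkage_candidate_set <- function(test_gene, positions, network,
                                  flank_total = 100) {
  stopifnot(inherits(positions, "gene_positions"),
            inherits(network, "gene_network"))
  if (flank_total %% 2 != 0) stop("flank_total must be even")
  i <- match(test_gene, positions$gene)
  if (is.na(i)) stop("test gene has no position: ", test_gene)
  chrom <- positions$chromosome[i]
  on_chrom <- positions[positions$chromosome == chrom, ]
  on_chrom <- on_chrom[on_chrom$gene %in% network$nodes | on_chrom$gene == test_gene, ]
  if (!test_gene %in% network$nodes)
    stop("test gene not in network: ", test_gene)
  idx <- match(test_gene, on_chrom$gene)
  left <- idx - 1L
  right <- nrow(on_chrom) - idx
  h <- flank_total / 2
  nL <- min(left, h)
  nR <- min(right, h)
  # borrow the shortfall of one side from the other
  rem <- flank_total - nL - nR
  nL <- nL + min(left - nL, rem)
  rem <- flank_total - nL - nR
  nR <- nR + min(right - nR, rem)
  if (nL + nR < flank_total)
    warning(sprintf("chromosome %s has only %d flanking genes for %s (wanted %d)",
                    chrom, nL + nR, test_gene, flank_total))
  on_chrom$gene[(idx - nL):(idx + nR)]
}

#' Candidate set for the whole-genome-scan scenario
#'
#' All network genes except the *other* members of the test gene's disease
#' family: the held-out gene stays in, its family mates (the seeds) are
#' excluded so they cannot compete with it.
#'
#' @param test_gene the held-out disease gene.
#' @param family character vector of the family's genes (contains
#'   `test_gene`).
#' @param network a [gene_network].
#' @return Character vector of candidate genes in network node order.
#' @export
genome_scan_candidate_set <- function(test_gene, family, network) {
  stopifnot(inherits(network, "gene_network"))
  if (!test_gene %in% family) stop("test gene must belong to its family")
  setdiff(network$nodes, setdiff(family, test_gene))
}

#' Leave-one-out benchmark
#'
#' Runs the full evaluation protocol: for every (family, member) association
#' one trial is performed in which that member is held out, the remaining
#' family genes become the seed set, a candidate set is built according to
#' the scenario, and every method ranks the identical candidates. The rank
#' of the held-out gene per method is recorded, and success rates at each
#' rank cutoff *k* (fraction of trials with rank \eqn{\le k}) are computed.
#' Rank-product combinations of the per-method rankings are evaluated from
#' the same trials.
#'
#' A trial in which a method fails (e.g. non-convergence) counts as
#' unsuccessful for that method (rank `NA`). In the linkage scenario, a test
#' gene without a position is skipped with a recorded reason. With
#' tie-average ranks, a held-out gene tied across the cutoff (rank k + 0.5)
#' counts as a failure.
#'
#' @param network a [gene_network].
#' @param families a `disease_families` table (already filtered).
#' @param scenario `"linkage"` (test gene + flanking genes) or
#'   `"genome_scan"` (all genes minus the other family members).
#' @param positions a `gene_positions` table; required for `"linkage"`.
#' @param methods base methods to evaluate (subset of `icn`, `rw`, `pr`).
#' @param combine names of combination presets to evaluate (see
#'   [combination_presets()]); defaults to all presets covered by `methods`.
#' @param k_values integer rank cutoffs for success rates.
#' @param flank_total linkage window size (total flanking genes).
#' @param config a [propagation_config()].
#' @return A `loo_summary`: list with `trials` (one row per trial; columns
#'   `family`, `gene`, `n_candidates` and `rank_<method>` for every method
#'   and combination), `success_rates` (methods x k matrix), `methods`,
#'   `combos`, `k_values`, `scenario`, `skipped` (data.frame of skipped
#'   trials with reasons) and `failures` (per-method failure notes).
#' @export
run_leave_one_out <- function(network, families,
                              scenario = c("linkage", "genome_scan"),
                              positions = NULL,
                              methods = c("icn", "rw", "pr"),
                              combine = NULL,
                              k_values = c(1, 5, 10),
                              flank_total = 100,
                              config = propagation_config()) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(network, "gene_network"))
  methods <- match.arg(methods, c("icn", "rw", "pr"), several.ok = TRUE)
  if (scenario == "linkage" && is.null(positions))
    stop("the linkage scenario requires a gene-position table")
  presets <- combination_presets(methods)
  if (is.null(combine)) combine <- names(presets)
  if (length(combine)) {
    unknown <- setdiff(combine, names(.combine_presets))
    if (length(unknown))
      stop("unknown combination preset(s): ", paste(unknown, collapse = ", "))
    uncovered <- setdiff(combine, names(presets))
    if (length(uncovered))
      stop("combination(s) need methods not evaluated: ",
           paste(uncovered, collapse = ", "))
  }

  all_labels <- c(methods, combine)
  rows <- list()
  skipped <- list()
  failures <- list()

  for (fam in names(families)) {
    members <- families[[fam]]
    for (g in members) {
      seeds <- setdiff(members, g)
      cands <- if (scenario == "linkage") {
        tryCatch(
          suppressWarnings(linkage_candidate_set(g, positions, network,
                                                 flank_total)),
          error = function(e) {
            skipped[[length(skipped) + 1L]] <<- data.frame(
              family = fam, gene = g, reason = conditionMessage(e),
              stringsAsFactors = FALSE)
            NULL
          })
      } else {
        genome_scan_candidate_set(g, members, network)
      }
      if (is.null(cands)) next

      ranked <- list()
      ranks <- stats::setNames(rep(NA_real_, length(all_labels)), all_labels)
      for (m in methods) {
        rl <- tryCatch(
          prioritize_candidates(network, seeds, cands, method = m,
                                config = config),
          error = function(e) {
            failures[[length(failures) + 1L]] <<- data.frame(
              family = fam, gene = g, method = m,
              reason = conditionMessage(e), stringsAsFactors = FALSE)
            NULL
          })
        ranked[[m]] <- rl
        if (!is.null(rl)) ranks[m] <- .rank_of(rl, g)
      }
      for (cb in combine) {
        parts <- ranked[presets[[cb]]]
        if (all(!vapply(parts, is.null, TRUE))) {
          comb <- combine_rankings(parts)
          ranks[cb] <- .rank_of(comb, g)
        }
      }
      row <- data.frame(family = fam, gene = g,
                        n_candidates = length(cands),
                        stringsAsFactors = FALSE)
      for (lab in all_labels) row[[paste0("rank_", lab)]] <- ranks[[lab]]
      rows[[length(rows) + 1L]] <- row
    }
  }

  trials <- if (length(rows)) do.call(rbind, rows) else
    stop("no trials could be run (all skipped?)")
  rownames(trials) <- NULL

  success_rates <- matrix(NA_real_, nrow = length(all_labels),
                          ncol = length(k_values),
                          dimnames = list(all_labels, paste0("k", k_values)))
  for (lab in all_labels) {
    r <- trials[[paste0("rank_", lab)]]
    for (ki in seq_along(k_values))
      success_rates[lab, ki] <- mean(!is.na(r) & r <= k_values[ki])
  }

  structure(
    list(trials = trials,
         success_rates = success_rates,
         methods = methods,
         combos = combine,
         k_values = k_values,
         scenario = scenario,
         skipped = if (length(skipped)) do.call(rbind, skipped) else
           data.frame(family = character(), gene = character(),
                      reason = character(), stringsAsFactors = FALSE),
         failures = if (length(failures)) do.call(rbind, failures) else
           data.frame(family = character(), gene = character(),
                      method = character(), reason = character(),
                      stringsAsFactors = FALSE)),
    class = "loo_summary"
  )
}

#' @export
print.loo_summary <- function(x, ...) {
  cat(sprintf("leave-one-out summary (%s): %d trials, %d skipped\n",
              x$scenario, nrow(x$trials), nrow(x$skipped)))
  cat("success rates:\n")
  print(round(x$success_rates, 4))
  invisible(x)
}

#' @export
summary.loo_summary <- function(object, ...) {
  print(object)
  resc <- rescued_cases(object)
  if (nrow(resc)) {
    cat("rescued cases (failed at k=1 by every base method):\n")
    print(resc, row.names = FALSE)
  }
  invisible(object)
}

# per-method logical success indicator at cutoff k over the trial table
.success_at <- function(summary, label, k = 1) {
  r <- summary$trials[[paste0("rank_", label)]]
  !is.na(r) & r <= k
}

#' Overlap of top-1 successes between methods
#'
#' Counts, for every subset of the base methods, the trials whose held-out
#' gene was ranked top-1 by exactly that subset (the exclusive regions of a
#' Venn diagram), plus the union: trials succeeded by at least one method.
#'
#' @param summary a `loo_summary` with at least two base methods.
#' @param k rank cutoff (default 1).
#' @return A list with `exclusive` (data.frame `methods`, `count`; subset
#'   labels join method names with `+`), `per_method` (named success
#'   counts) and `union` (count of trials succeeded by any method).
#' @export
success_overlap <- function(summary, k = 1) {
  stopifnot(inherits(summary, "loo_summary"))
  methods <- summary$methods
  if (length(methods) < 2) stop("need at least two methods for an overlap")
  succ <- vapply(methods, function(m) .success_at(summary, m, k),
                 logical(nrow(summary$trials)))
  succ <- matrix(succ, ncol = length(methods),
                 dimnames = list(NULL, methods))
  pattern <- apply(succ, 1, function(z)
    paste(methods[z], collapse = "+"))
  pattern <- pattern[pattern != ""]
  counts <- table(pattern)
  exclusive <- data.frame(methods = names(counts),
                          count = as.integer(counts),
                          stringsAsFactors = FALSE)
  list(exclusive = exclusive,
       per_method = colSums(succ),
       union = sum(rowSums(succ) > 0))
}

#' Trials rescued by a combination scheme
#'
#' A rescued case is a trial whose held-out gene was missed at the top-1
#' cutoff by every base method alone but recovered (ranked top-1) by a
#' rank-product combination.
#'
#' @param summary a `loo_summary`.
#' @param k rank cutoff (default 1).
#' @return A data.frame with one row per combination: `combo`, `n_failed_all`
#'   (trials failed by every base method) and `n_rescued`.
#' @export
rescued_cases <- function(summary, k = 1) {
  stopifnot(inherits(summary, "loo_summary"))
  if (!length(summary$combos))
    return(data.frame(combo = character(), n_failed_all = integer(),
                      n_rescued = integer(), stringsAsFactors = FALSE))
  base_fail <- rep(TRUE, nrow(summary$trials))
  for (m in summary$methods)
    base_fail <- base_fail & !.success_at(summary, m, k)
  out <- lapply(summary$combos, function(cb) {
    data.frame(combo = cb, n_failed_all = sum(base_fail),
               n_rescued = sum(base_fail & .success_at(summary, cb, k)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Topology of method-unique successes
#'
#' For each base method, collects the trials whose held-out gene was ranked
#' top-1 by that method *alone*, and characterizes those genes
#' topologically: the degree (number of interacting partners) and the mean
#' unweighted shortest-path hop distance to the other members of the gene's
#' disease family (unreachable members are excluded from the mean and
#' counted). Method-unique groups are then compared pairwise on each metric
#' with a two-sided Wilcoxon rank-sum test.
#'
#' @param summary a `loo_summary` with at least two base methods evaluated
#'   at a k=1 cutoff.
#' @param network the `gene_network` the benchmark ran on.
#' @param families the `disease_families` table used.
#' @return A `topology_report`: list with `cases` (data.frame `method`,
#'   `family`, `gene`, `degree`, `mean_distance`, `n_unreachable`), `tests`
#'   (data.frame `metric`, `method_a`, `method_b`, `statistic`, `p_value`)
#'   and `notes` (character; e.g. comparisons skipped for empty groups).
#' @export
unique_case_topology <- function(summary, network, families) {
  stopifnot(inherits(summary, "loo_summary"),
            inherits(network, "gene_network"))
  methods <- summary$methods
  if (length(methods) < 2) stop("need at least two methods")
  succ <- vapply(methods, function(m) .success_at(summary, m, 1),
                 logical(nrow(summary$trials)))
  succ <- matrix(succ, ncol = length(methods),
                 dimnames = list(NULL, methods))
  n_succ <- rowSums(succ)
  g <- .as_igraph(network)
  deg <- igraph::degree(g)

  cases <- list()
  for (m in methods) {
    uniq <- which(succ[, m] & n_succ == 1)
    for (i in uniq) {
      gene <- summary$trials$gene[i]
      fam <- summary$trials$family[i]
      others <- setdiff(families[[fam]], gene)
      d <- as.numeric(igraph::distances(g, v = gene, to = others,
                                        weights = NA))
      reach <- is.finite(d)
      cases[[length(cases) + 1L]] <- data.frame(
        method = m, family = fam, gene = gene,
        degree = unname(deg[gene]),
        mean_distance = if (any(reach)) mean(d[reach]) else NA_real_,
        n_unreachable = sum(!reach),
        stringsAsFactors = FALSE)
    }
  }
  cases <- if (length(cases)) do.call(rbind, cases) else
    data.frame(method = character(), family = character(),
               gene = character(), degree = numeric(),
               mean_distance = numeric(), n_unreachable = integer(),
               stringsAsFactors = FALSE)

  tests <- list()
  notes <- character()
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  for (metric in c("degree", "mean_distance")) {
    for (pr in pairs) {
      xa <- cases[[metric]][cases$method == pr[1]]
      xb <- cases[[metric]][cases$method == pr[2]]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (!length(xa) || !length(xb)) {
        notes <- c(notes, sprintf(
          "comparison %s vs %s on %s skipped: empty unique-case group",
          pr[1], pr[2], metric))
        next
      }
      wt <- suppressWarnings(stats::wilcox.test(xa, xb,
                                                alternative = "two.sided"))
      tests[[length(tests) + 1L]] <- data.frame(
        metric = metric, method_a = pr[1], method_b = pr[2],
        statistic = unname(wt$statistic), p_value = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(metric = character(), method_a = character(),
               method_b = character(), statistic = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)

  structure(list(cases = cases, tests = tests, notes = notes),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("topology report: %d method-unique cases\n", nrow(x$cases)))
  if (nrow(x$cases)) {
    tab <- table(x$cases$method)
    cat("unique cases per method:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (nrow(x$tests)) print(x$tests, row.names = FALSE)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
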