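# a line of genes on one chromosome, all present in a connected network
line_world <- function(n_genes) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  net <- gene_network(data.frame(from = genes[-n_genes], to = genes[-1]))
  pos <- data.frame(gene = genes, chromosome = "chr1",
                    start = seq_len(n_genes) * 10L,
                    stringsAsFactors = FALSE)
  class(pos) <- c("gene_positions", "data.frame")
  list(genes = genes, net = net, pos = pos)
}

test_that("linkage windows are balanced and borrow at chromosome ends", {
  w <- line_world(201)
  mid <- w$genes[101]
  cands <- linkage_candidate_set(mid, w$pos, w$net)
  expect_length(cands, 101)
  expect_equal(cands, w$genes[51:151])

  # first gene on the chromosome: everything borrowed downstream
  first <- linkage_candidate_set(w$genes[1], w$pos, w$net)
  expect_equal(first, w$genes[1:101])

  # short chromosome: smaller set plus warning
  w80 <- line_world(80)
  expect_warning(c80 <- linkage_candidate_set(w80$genes[40], w80$pos, w80$net),
                 "only")
  expect_length(c80, 80)
  expect_error(linkage_candidate_set("nope", w$pos, w$net), "no position")
  expect_error(linkage_candidate_set(mid, w$pos, w$net, flank_total = 99),
               "even")
})

test_that("genome-scan candidates exclude exactly the other family members", {
  gen <- random_planted_network(2, 4, 20)
  net <- gen$network
  fam <- gen$families[[1]]
  g <- fam[1]
  cands <- genome_scan_candidate_set(g, fam, net)
  expect_true(g %in% cands)
  expect_length(intersect(cands, setdiff(fam, g)), 0)
  expect_length(cands, length(net$nodes) - (length(fam) - 1))
  expect_error(genome_scan_candidate_set("B0001", fam, net), "belong")
})

test_that("leave-one-out runs one trial per association with sane records", {
  fix <- benchmark_fixture("tiny")
  res <- run_leave_one_out(fix$network, fix$families, scenario = "linkage",
                           positions = fix$positions,
                           k_values = c(1, 5, 10), flank_total = 20)
  n_assoc <- sum(lengths(fix$families))
  expect_equal(nrow(res$trials) + nrow(res$skipped), n_assoc)
  # every trial's held-out gene is in its candidate window by construction
  expect_true(all(!is.na(res$trials$rank_icn)))
  # success rates non-decreasing in k, bounded
  for (lab in rownames(res$success_rates)) {
    sr <- res$success_rates[lab, ]
    expect_true(all(diff(sr) >= 0))
    expect_true(all(sr >= 0 & sr <= 1))
  }
  # success rate equals the fraction of ranks within k
  expect_equal(res$success_rates["icn", "k1"],
               mean(res$trials$rank_icn <= 1))
  # reruns are identical
  res2 <- run_leave_one_out(fix$network, fix$families, scenario = "linkage",
                            positions = fix$positions,
                            k_values = c(1, 5, 10), flank_total = 20)
  expect_identical(res, res2)
})

test_that("genome-scan trials keep the held-out gene and drop its family", {
  fix <- benchmark_fixture("tiny")
  res <- run_leave_one_out(fix$network, fix$families,
                           scenario = "genome_scan",
                           methods = c("icn", "rw"), k_values = 1)
  expect_equal(nrow(res$trials), sum(lengths(fix$families)))
  expect_equal(unique(res$trials$n_candidates),
               length(fix$network$nodes) - (lengths(fix$families)[[1]] - 1))
  # combination column present and consistent with its parts
  expect_true("rank_icn-rw" %in% names(res$trials))
})

test_that("overlap counts are internally consistent", {
  fix <- benchmark_fixture("tiny")
  res <- run_leave_one_out(fix$network, fix$families, scenario = "linkage",
                           positions = fix$positions, k_values = 1,
                           flank_total = 20)
  ov <- success_overlap(res)
  expect_equal(sum(ov$exclusive$count), ov$union)
  expect_gte(ov$union, max(ov$per_method))
  expect_lte(ov$union, sum(ov$per_method))
  # per-method totals recoverable from the exclusive regions
  for (m in res$methods) {
    in_region <- grepl(paste0("(^|\\+)", m, "($|\\+)"), ov$exclusive$methods)
    expect_equal(sum(ov$exclusive$count[in_region]),
                 unname(ov$per_method[m]))
  }
  resc <- rescued_cases(res)
  expect_equal(nrow(resc), length(res$combos))
  expect_true(all(resc$n_rescued <= resc$n_failed_all))
})

test_that("overlap arithmetic matches hand-built success sets", {
  # forge a summary with known success patterns
  trials <- data.frame(family = "F", gene = sprintf("t%d", 1:3),
                       n_candidates = 10,
                       rank_icn = c(1, 1, 5), rank_rw = c(4, 1, 1))
  fake <- structure(list(trials = trials, methods = c("icn", "rw"),
                         combos = character(), k_values = 1,
                         scenario = "linkage",
                         success_rates = matrix(0, 2, 1,
                           dimnames = list(c("icn", "rw"), "k1")),
                         skipped = data.frame(), failures = data.frame()),
                    class = "loo_summary")
  ov <- success_overlap(fake)
  expect_equal(ov$union, 3)
  excl <- setNames(ov$exclusive$count, ov$exclusive$methods)
  expect_equal(excl[["icn"]], 1)
  expect_equal(excl[["rw"]], 1)
  expect_equal(excl[["icn+rw"]], 1)
})

test_that("unique-case topology reports degree and family distances", {
  # path a-b-c-d; family {a, d}; plus a hub gene with 5 spokes
  net <- gene_network(data.frame(
    from = c("a", "b", "c", "h", "h", "h", "h", "h"),
    to = c("b", "c", "d", "s1", "s2", "s3", "s4", "s5")))
  families <- structure(list(FA = c("a", "d"), FH = c("h", "s1")),
                        class = "disease_families")
  trials <- data.frame(family = c("FA", "FH"), gene = c("a", "h"),
                       n_candidates = 5,
                       rank_icn = c(1, 3), rank_rw = c(2, 1))
  fake <- structure(list(trials = trials, methods = c("icn", "rw"),
                         combos = character(), k_values = 1,
                         scenario = "linkage",
                         success_rates = matrix(0, 2, 1,
                           dimnames = list(c("icn", "rw"), "k1")),
                         skipped = data.frame(), failures = data.frame()),
                    class = "loo_summary")
  rep <- unique_case_topology(fake, net, families)
  a_row <- rep$cases[rep$cases$gene == "a", ]
  expect_equal(a_row$method, "icn")
  expect_equal(a_row$degree, 1)
  expect_equal(a_row$mean_distance, 3)  # a-b-c-d is 3 hops
  h_row <- rep$cases[rep$cases$gene == "h", ]
  expect_equal(h_row$method, "rw")
  expect_equal(h_row$degree, 5)
  expect_equal(h_row$mean_distance, 1)
  expect_true(all(c("degree", "mean_distance") %in% rep$tests$metric))
})

test_that("identical success sets leave no unique cases", {
  trials <- data.frame(family = "F", gene = c("x", "y"), n_candidates = 5,
                       rank_icn = c(1, 2), rank_rw = c(1, 2))
  net <- gene_network(data.frame(from = "x", to = "y"))
  fake <- structure(list(trials = trials, methods = c("icn", "rw"),
                         combos = character(), k_values = 1,
                         scenario = "linkage",
                         success_rates = matrix(0, 2, 1,
                           dimnames = list(c("icn", "rw"), "k1")),
                         skipped = data.frame(), failures = data.frame()),
                    class = "loo_summary")
  rep <- unique_case_topology(fake, net,
                              structure(list(F = c("x", "y")),
                                        class = "disease_families"))
  expect_equal(nrow(rep$cases), 0)
  expect_true(length(rep$notes) > 0)
})

test_that("ties straddling the cutoff count as failures", {
  # two genes tied for rank 1-2 both get 1.5 > 1: neither succeeds at k=1
  rl <- assign_ranks(c(a = 1, b = 1, c = 0))
  expect_false(any(rl$rank <= 1))
})
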