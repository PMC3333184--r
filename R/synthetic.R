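#' Specification of a planted-module synthetic network
#'
#' Describes a planted-partition benchmark network: `n_modules` disease
#' modules of `module_size` genes each plus `n_background` unaffiliated
#' genes. Pairs inside a module are connected with probability `p_within`,
#' every other pair with probability `p_between`; each module is emitted as
#' one disease family. This emulates the working hypothesis behind
#' network-based prioritization — genes causing one disease sit close
#' together in the network — with a directly controllable signal strength.
#'
#' @param n_modules number of planted modules (>= 1).
#' @param module_size genes per module (>= 2, so families survive the
#'   singleton filter).
#' @param n_background genes belonging to no module.
#' @param p_within within-module edge probability.
#' @param p_between edge probability for every other pair; must be strictly
#'   below `p_within`.
#' @param weight_model `"unit"` (all weights 1), `"uniform"` or `"beta"`.
#' @param weight_par numeric pair: `(lo, hi)` for uniform, `(a, b)` shape
#'   parameters for beta; ignored for unit weights.
#' @param hold_out_fraction fraction of each module's genes left out of its
#'   disease-family label (default 0: whole module = family).
#' @param rng_seed integer seed; every generated artifact is a pure function
#'   of the spec including this seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_modules, module_size, n_background,
                           p_within, p_between,
                           weight_model = c("unit", "uniform", "beta"),
                           weight_par = c(2, 2),
                           hold_out_fraction = 0,
                           rng_seed = 1L) {
  weight_model <- match.arg(weight_model)
  stopifnot(n_modules >= 1, module_size >= 2, n_background >= 0,
            p_within > 0, p_within <= 1,
            p_between >= 0, p_between < p_within,
            hold_out_fraction >= 0, hold_out_fraction < 1,
            length(rng_seed) == 1, is.finite(rng_seed))
  if (weight_model != "unit")
    stopifnot(length(weight_par) == 2, all(is.finite(weight_par)))
  if (weight_model == "uniform")
    stopifnot(weight_par[1] > 0, weight_par[2] <= 1,
              weight_par[1] <= weight_par[2])
  if (weight_model == "beta")
    stopifnot(all(weight_par > 0))
  structure(list(n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 n_background = as.integer(n_background),
                 p_within = p_within, p_between = p_between,
                 weight_model = weight_model, weight_par = weight_par,
                 hold_out_fraction = hold_out_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d modules x %d + %d background, p_within %g, p_between %g, %s weights, seed %d\n",
    x$n_modules, x$module_size, x$n_background, x$p_within, x$p_between,
    x$weight_model, x$rng_seed))
  invisible(x)
}

# run code under a private RNG stream seeded from `seed`, restoring any
# pre-existing global state afterwards
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a planted-module network and its disease families
#'
#' Draws the planted-partition graph described by a [synthetic_spec()]:
#' every unordered gene pair is connected independently, with probability
#' `p_within` inside a module and `p_between` elsewhere; edge weights follow
#' the spec's weight model. Edge indicators are drawn before weights, so two
#' specs differing only in the weight model share the same topology. Each
#' module becomes one disease family (minus a held-out fraction, if
#' configured). Module genes are named `M<m>G<i>`, background genes
#' `B<i>`; isolated genes remain in the node set.
#'
#' @param spec a `synthetic_spec`.
#' @return A list with elements `network` (a [gene_network]) and `families`
#'   (a `disease_families` table, one family `F<m>` per module).
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_mod_genes <- spec$n_modules * spec$module_size
  n <- n_mod_genes + spec$n_background
  module <- c(rep(seq_len(spec$n_modules), each = spec$module_size),
              rep(0L, spec$n_background))
  nodes <- character(n)
  nodes[module > 0] <- sprintf("M%dG%02d", module[module > 0],
                               sequence(rep(spec$module_size, spec$n_modules)))
  nodes[module == 0] <- sprintf("B%04d", seq_len(spec$n_background))

  .with_seed(spec$rng_seed, {
    same <- outer(module, module, `==`) & outer(module, module,
                                                function(a, b) a > 0)
    p <- ifelse(same, spec$p_within, spec$p_between)
    up <- upper.tri(p)
    u <- matrix(0, n, n)
    u[up] <- stats::runif(sum(up))
    present <- up & u < p
    idx <- which(present, arr.ind = TRUE)
    m <- nrow(idx)
    if (!m) stop("synthetic spec yields an empty edge set")
    weight <- switch(spec$weight_model,
      unit = rep(1, m),
      uniform = stats::runif(m, spec$weight_par[1], spec$weight_par[2]),
      beta = pmax(stats::rbeta(m, spec$weight_par[1], spec$weight_par[2]),
                  .Machine$double.eps))
    edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                        weight = weight, stringsAsFactors = FALSE)
    network <- gene_network(edges, nodes = nodes,
                            weighted = spec$weight_model != "unit")
    fams <- lapply(seq_len(spec$n_modules), function(mm) {
      members <- nodes[module == mm]
      n_drop <- floor(spec$hold_out_fraction * length(members))
      if (n_drop > 0) members <- sample(members,
                                        length(members) - n_drop)
      sort(members)
    })
    names(fams) <- sprintf("F%d", seq_len(spec$n_modules))
    fams <- Filter(function(f) length(f) >= 2, fams)
    list(network = network,
         families = structure(fams, class = "disease_families",
                              report = list(genes_dropped = 0,
                                            families_dropped =
                                              spec$n_modules - length(fams))))
  })
}

#' Generate gene positions for the linkage scenario
#'
#' Assigns every network gene a chromosome and a start coordinate: genes are
#' shuffled by the seeded generator, dealt round-robin across chromosomes,
#' and given strictly increasing starts along each chromosome. Members of a
#' disease family are thereby scattered across the genome, mimicking a locus
#' that harbors one causative gene amid unrelated neighbors.
#'
#' @param network a [gene_network].
#' @param n_chromosomes number of chromosomes (>= 1).
#' @param rng_seed integer seed.
#' @return A `gene_positions` table covering every network gene.
#' @export
generate_positions <- function(network, n_chromosomes = 1, rng_seed = 1L) {
  stopifnot(inherits(network, "gene_network"), n_chromosomes >= 1)
  genes <- network$nodes
  .with_seed(rng_seed, {
    shuffled <- sample(genes)
    chrom <- sprintf("chr%d", rep_len(seq_len(n_chromosomes),
                                      length(genes)))
    start <- integer(length(genes))
    for (cc in unique(chrom)) {
      on_c <- chrom == cc
      start[on_c] <- seq_len(sum(on_c)) * 1000L
    }
    out <- data.frame(gene = shuffled, chromosome = chrom, start = start,
                      stringsAsFactors = FALSE)
    out <- out[order(out$chromosome, out$start, out$gene), ]
    rownames(out) <- NULL
    class(out) <- c("gene_positions", "data.frame")
    out
  })
}

# canned fixture specifications; seeds are fixed so fixtures are stable
.fixture_profiles <- list(
  tiny = list(spec = list(n_modules = 2, module_size = 5, n_background = 50,
                          p_within = 0.8, p_between = 0.05,
                          weight_model = "unit", rng_seed = 101L),
              n_chromosomes = 1, pos_seed = 102L),
  default = list(spec = list(n_modules = 8, module_size = 15,
                             n_background = 1500,
                             p_within = 0.3, p_between = 0.005,
                             weight_model = "unit", rng_seed = 2011L),
                 n_chromosomes = 4, pos_seed = 2012L),
  weighted = list(spec = list(n_modules = 8, module_size = 15,
                              n_background = 1500,
                              p_within = 0.3, p_between = 0.005,
                              weight_model = "beta", weight_par = c(2, 2),
                              rng_seed = 2011L),
                  n_chromosomes = 4, pos_seed = 2012L)
)

#' Canned benchmark fixtures
#'
#' Three reproducible synthetic benchmarks with fixed seeds: `tiny` (2
#' modules of 5 genes + 50 background; dense modules for fast unit tests),
#' `default` (8 modules of 15 + 1500 background, p_within 0.3 / p_between
#' 0.005, unit weights; the standard benchmark profile) and `weighted` (the
#' `default` topology with beta(2, 2) edge weights, exercising the
#' functional-association-network style weighted path).
#'
#' @param profile one of `"tiny"`, `"default"`, `"weighted"`.
#' @return A list with `network`, `families`, `positions` and the
#'   `synthetic_spec` used (`spec`).
#' @export
benchmark_fixture <- function(profile) {
  if (!is.character(profile) || length(profile) != 1 ||
      !profile %in% names(.fixture_profiles))
    stop("unknown profile; available: ",
         paste(names(.fixture_profiles), collapse = ", "))
  prof <- .fixture_profiles[[profile]]
  spec <- do.call(synthetic_spec, prof$spec)
  gen <- generate_planted_network(spec)
  positions <- generate_positions(gen$network, prof$n_chromosomes,
                                  prof$pos_seed)
  list(network = gen$network, families = gen$families,
       positions = positions, spec = spec)
}
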