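---
title: "Prioritizing candidate disease genes by network interconnectedness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate disease genes by network interconnectedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netprio)
```

## The problem

Genome-wide approaches to disease-gene discovery — linkage analysis,
association studies, exome sequencing — typically end with a list of tens to
hundreds of candidate genes, of which at most a few are causal. Network-based
prioritization orders such a list by exploiting the observation that genes
causing the same disease tend to sit close to one another in molecular
interaction networks: near known disease genes is where new ones are most
likely to be found.

`netprio` implements one parameter-free closeness measure, the
*interconnectedness* (ICN) score, alongside two widely used propagation
baselines (random walk with restart, and PRINCE-style label propagation), a
rank-product scheme for combining the methods' rankings, and a leave-one-out
benchmarking harness driven by synthetic networks with planted disease
modules.

## The interconnectedness score

For genes $i$ and $j$ in an undirected network with edge weights
$\omega \in (0, 1]$, let $N_i$ be the neighbours of $i$ and
$k_i = \sum_{v \in N_i} \omega_{i,v}$ the *strength* of $i$ (the degree, on
an unweighted network). A *connector* is a gene $u$ adjacent to both $i$ and
$j$. The ICN score combines the direct connection with the connector
evidence:

$$
ICN_{i,j} \;=\; \omega_{i,j} \;+\;
  \frac{\sum_{u \in N_i \cap N_j} \omega_{i,u}\,\omega_{u,j}}{E_{i,j}},
\qquad
E_{i,j} \;=\; \frac{k_i\,k_j}{\sum_g k_g}.
$$

The normalizer $E_{i,j}$ is the connector count expected from the two genes'
strengths alone (the configuration-model expectation of shared partners), so
two hubs are not called close merely for having many neighbours; a shared
partner between two low-strength genes, conversely, is strong evidence. The
connector edge weights enter multiplicatively, so a connector attached by two
confident edges counts more than one attached weakly. The score is symmetric,
non-negative, zero exactly when the pair shares neither an edge nor a
neighbour, and has no tunable parameter — the property that motivates it:
propagation methods must be re-tuned whenever the underlying network changes,
ICN need not.

Two algebraic conventions were genuinely open when the formula was pinned
down: whether the two connector-edge weights combine by product or by
average, and the precise form of the expected-connector denominator. The
package adopts the product and the $k_i k_j / \sum_g k_g$ expectation, both
implemented in a single internal function (`.icn_matrix()`), so an
alternative transcription is a one-line change; the test suite's
neighbour-enumeration oracle is written against the same declared form.

Edge cases are resolved as follows. $E_{i,j} = 0$ occurs only when an
endpoint is isolated, in which case the connector sum is necessarily zero
too; the connector term is defined as 0 rather than 0/0. The ICN of a gene
with itself is left undefined (it is an error): no downstream formula needs
it, and any convention (1, $k_i$, ...) would silently distort seed-sum
scores.

A candidate gene $i$ is scored against the seed set $S_d$ (the known genes
of disease $d$) by summation, $Score_i = \sum_{j \in S_d} ICN_{i,j}$, and
candidates are ranked by descending score. When a seed gene itself appears
in a candidate list (possible in the linkage scenario, where the window is
chosen genomically), its self-pair is skipped in the sum.

## The propagation baselines

**Random walk with restart.** A walker starts at the seed genes and at each
step either moves to a neighbour with probability proportional to the edge
weight, or restarts at the seed distribution with probability $r$:
$p^{(t+1)} = (1-r)\,W p^{(t)} + r\,p^0$, with $W$ the column-stochastic
weight-normalized adjacency and $p^0$ uniform over seeds. The default
$r = 0.5$ is the conventional benchmark setting. Isolated genes receive a
self-transition so $W$ stays stochastic and probability mass is conserved
(the suite asserts $\sum p = 1$ to $10^{-8}$ at every iteration).

**PRINCE-style propagation.** The seed indicator $Y$ is smoothed over the
network by $F^{(t)} = \alpha W' F^{(t-1)} + (1-\alpha) Y$ with the symmetric
normalization $W' = D^{-1/2} W D^{-1/2}$ and default $\alpha = 0.9$; the
iteration converges to $(1-\alpha)(I - \alpha W')^{-1} Y$. Two deliberate
simplifications relative to the full PRINCE method: the prior is the plain
binary seed indicator (no phenotype-similarity-weighted logistic prior — the
benchmark trials carry no phenotype input), and no protein-complex
elucidation stage is included. Isolated genes keep a zero row in $W'$, so
their limit score is $(1-\alpha) Y$.

Both iterations halt as soon as the $L_1$ change between successive score
vectors falls below $10^{-10}$ (strictly below; the halting iteration is
asserted in the tests against a manual replay). An iteration cap
($10^6$) turns pathological non-convergence into an error carrying the last
residual; with $r > 0$ and $\alpha < 1$ both maps are contractions, so the
cap is never reached in practice.

## Combining rankings

Methods err on different cases: ICN is purely local (two hops), the
propagations are global. The package combines per-method rankings by rank
product: $CS_i = \prod_j R_{i,j}$, re-ranked ascending. Tie-averaged
fractional ranks multiply as-is, ties in $CS$ again receive average ranks, so
the combination is deterministic and invariant to the order in which methods
are supplied. The four presets `icn-rw`, `icn-pr`, `rw-pr`, `icn-rw-pr` are
evaluated by the harness alongside the base methods.

## The leave-one-out benchmark

Each (family, member) association yields one trial: the member is held out,
the rest of its family becomes the seed set, and every method ranks the same
candidate list. Two scenarios set the candidate list:

* **Simulated linkage**: the held-out gene plus the 100 network-present
  genes nearest to it on its chromosome (50 per side, borrowing across the
  midpoint at chromosome ends) — 101 candidates. The window is restricted to
  network-present genes so every candidate is scoreable; padding with
  unscoreable genes would automatically rank them last and flatter every
  method. A chromosome with too few genes yields a smaller window (recorded
  per trial in `n_candidates`); a test gene without a position skips the
  trial with a logged reason.
* **Whole genome scan**: all network genes except the *other* family
  members.

A trial succeeds at cutoff $k$ when the held-out gene's rank is $\le k$;
with tie-averaged ranks a gene tied across the boundary (rank $k + 0.5$)
conservatively counts as a failure. A method failing on a trial (e.g.
non-convergence) counts as unsuccessful there. The *success rate* at $k$ is
the fraction of successful trials. Trials whose held-out gene is
disconnected from all seeds are kept — they are legitimately hard cases, not
artifacts.

On top of the per-trial records the harness reports: the overlap of top-1
successes between methods (the exclusive Venn regions and the union), the
*rescued* cases (failed at top-1 by every base method, recovered by a
combination), and a topological profile of each method's *unique* successes
— the degree and the mean unweighted hop distance to the other family
members of genes only that method ranked first. Unreachable family members
are excluded from the mean (and counted) rather than mapped to infinity, and
hop counts are used on weighted networks too, since no weighted distance is
defined by the scores being compared. Unique-case groups are compared
pairwise with a *two-sided Wilcoxon rank-sum test*: the groups are unpaired
(different trials), so the unpaired rank test is the appropriate choice even
though a paired (signed-rank) test is sometimes named in this context.

## Synthetic benchmark networks

Real interaction networks and curated disease families cannot ship with a
package, and frozen snapshots would make every result hostage to a
particular download. The generator instead plants the very structure the
methods are supposed to exploit: a planted-partition graph in which
`n_modules` disease modules of `module_size` genes are wired internally with
probability `p_within`, all other pairs with `p_between < p_within`, and
each module is labelled as one disease family. Gene positions are assigned
by shuffling genes across chromosomes, so family members scatter genomically
and a linkage window around a held-out gene contains (almost only) unrelated
neighbours — the situation the linkage scenario mimics.

Three canned profiles with fixed seeds make results reproducible:

| profile  | shape                         | p_within / p_between | weights   | use |
|----------|-------------------------------|----------------------|-----------|-----|
| tiny     | 2 modules x 5 + 50 background | 0.8 / 0.05           | unit      | unit tests |
| default  | 8 x 15 + 1500                 | 0.3 / 0.005          | unit      | standard benchmark |
| weighted | same topology as default      | 0.3 / 0.005          | beta(2,2) | weighted path |

The default profile's edge probabilities give a held-out module gene about
four direct links to its 14 seeds plus shared neighbours, against a
background direct-link expectation of 0.07 — a strong but not saturated
signal (top-1 success sits well below 100%), sized so a full three-method
leave-one-out run takes seconds. The tiny profile is dense so that every
family survives filtering under any sub-sampling. Edge indicators are drawn
before edge weights, which is why the `weighted` profile shares the
`default` topology exactly. All generation runs on a private RNG stream: a
single integer seed determines every artifact, and the caller's `.Random.seed`
is left untouched.

What the generator does *not* emulate: scale-free degree distributions,
assortativity, overlapping modules, incomplete family annotation (available
via `hold_out_fraction`, default 0) and measurement noise in edge weights.
Passing the planted-module benchmark therefore shows that a method recovers
modular proximity signal, not that it will match any particular success rate
on real interactome data, where hubs and annotation bias matter.

## Numerical and format choices

* Duplicate edges in input files (either orientation) are collapsed keeping
  the **maximum** weight: order-independent, and preserves the strongest
  evidence when interaction databases disagree.
* A weight of exactly 0 after rescaling drops the edge — indistinguishable
  from no edge in every formula. Raw weights outside `(0, weight_scale]`
  are errors, catching unit mistakes (e.g. forgetting `weight_scale = 1000`
  for STRING-style scores).
* Gene identifiers are opaque strings; identifier unification is the
  caller's responsibility.
* Ranks are tie-averaged everywhere (scores, combined scores), which removes
  input-order artifacts and feeds the rank product deterministically.
* Edge lists cannot express isolated genes, so writing and reloading a
  network preserves nodes up to genes of degree 0 (edges and weights are
  preserved exactly; weights are printed with 17 significant digits).
* Per-chromosome gene order breaks start-coordinate ties by lexicographic
  gene id, making linkage windows deterministic.

## Problem sizes used by the test suite

The oracle-equivalence tests run ~200 random graphs of up to 30 nodes
against a naive neighbour-enumeration ICN oracle, and 50 graphs of up to 50
nodes against dense closed-form solves of both propagation fixed points.
The harness checks run the tiny profile end to end; the planted-module
recovery check runs the default profile (120 trials, 101 candidates each)
and asserts the ICN top-1 success rate clears the 1/101 chance rate at a
one-sided binomial $p < 10^{-6}$. These sizes keep the whole suite in the
tens of seconds while leaving each assertion statistically meaningful.

## Limitations

* ICN sees at most two hops; a candidate three hops from every seed scores 0
  regardless of path multiplicity. That is by design (it is what makes the
  score parameter-free and cheap) and is precisely where the propagation
  methods complement it — the motivation for the rank-product combination.
* The propagation re-implementations are the benchmark variants described
  above, not full re-implementations of their source methods (no phenotype
  prior, no complex elucidation, fixed $r$ and $\alpha$).
* Success rates on planted-partition graphs are not forecasts of performance
  on curated interactomes; use the harness on your own network and
  association table for that.
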