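Package: netprio
Title: Network-Based Candidate Disease Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease genes by their closeness to known
    disease genes in a gene network. Implements the parameter-free
    interconnectedness (ICN) score, which combines the direct edge weight of
    a gene pair with a shared-neighbour ("connector") term normalized by the
    expected connector count, together with two propagation baselines
    (random walk with restart and PRINCE-style label propagation), a
    rank-product scheme for combining method rankings, and a leave-one-out
    benchmarking harness with simulated-linkage and whole-genome-scan test
    scenarios. A planted-module synthetic network generator makes every
    component testable without external interaction databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
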