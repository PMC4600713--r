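Package: netctrl
Title: Network Controllability Analysis of Structural Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linear network control theory applied to weighted,
    undirected structural connectomes. From a region-by-region streamline
    count matrix the package stabilizes a discrete-time linear dynamical
    model, solves the infinite-horizon controllability Gramian for
    single-region control sets, and derives four regional diagnostics:
    global controllability (smallest Gramian eigenvalue, with a
    log-determinant positivity certificate), average controllability
    (Gramian trace), modal controllability (scaled eigenmode excitability)
    and boundary controllability (iterative consensus-partition and
    Fiedler-bipartition depth values). Cohort utilities aggregate ranked
    diagnostics across subjects and scans, extract control hubs, and compute
    size-normalized enrichment over cognitive systems. A seeded generator
    produces synthetic modular, hub-rich connectome cohorts with
    scan-to-scan noise for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
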