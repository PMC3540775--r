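Package: fcnet
Title: Resting-State Functional Connectivity Network Analysis with Synthetic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares resting-state functional connectivity networks
    from parcellated region-by-time signal matrices. Implements the full analysis
    chain: row demeaning and global-signal removal, Pearson correlation matrices
    and their non-negative and proportionally thresholded variants, binary network
    construction at fixed edge density, small-world and modularity metrics against
    random benchmarks, Euclidean connection-reach statistics, hub ranking and
    seed-region connection profiling, and group-level inference via pooled t-tests,
    label-permutation tests with Benjamini-Hochberg false discovery rate control,
    and pooled two-proportion z-tests. Includes a calibrated latent-factor
    generator of synthetic multi-subject cohorts with modular community structure,
    a shared global signal, and node-specific long-range coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
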