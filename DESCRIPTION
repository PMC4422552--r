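Package: haploclust
Title: Haplotype Assembly by Correlation Clustering with Low-Rank
    Semidefinite Relaxations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-individual haplotype assembly for diploid and polyploid
    genomes. Sequencing reads covering heterozygous SNP sites are cast as
    vertices of a weighted correlation graph and partitioned into K haplotype
    clusters by a low-rank factorized semidefinite-programming relaxation of
    MAX-CUT (diploid) or a Lagrangian minorize-maximize scheme enforcing the
    simplex inner-product constraints (polyploid), followed by randomized
    projection rounding, per-cluster majority-vote consensus with
    homozygous-site correction, and greedy refinement of the minimum error
    correction (MEC) objective. Includes a paired-end read simulator with
    geometric SNP spacing, MEC scoring, and switch-error-rate evaluation via
    a permutation dynamic program, so the whole pipeline can be exercised
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
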