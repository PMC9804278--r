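Package: frogcu
Title: Conservation-Unit Delineation for Great Basin Spotted Frog Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for delineating conservation units from
    SNP genotypes in naturally fragmented amphibian populations, built around
    the Great Basin Columbia spotted frog (Rana luteiventris) study system.
    Provides a RADseq-style SNP filter cascade, per-site diversity and
    Weir-Cockerham differentiation statistics, Nei's standard genetic
    distance, linkage-disequilibrium effective population size with
    chromosome-number correction and jackknife confidence intervals,
    redundancy-analysis genotype-environment outlier detection, singly
    constrained gravity models of functional connectivity with AICc
    hypothesis competition and smearing-corrected flow prediction to
    unsampled sites, and hierarchical AMOVA comparison of candidate
    management-unit groupings. A simulation module generates landscapes,
    site networks, Balding-Nichols and Wright-Fisher genotypes, and gravity
    flows with known truth so that every stage is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
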