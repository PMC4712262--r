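Package: ecomlsa
Title: Multi-Locus Sequence Analysis and Ecotype Demarcation for Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-locus sequence analysis (MLSA) of microbial
    populations sampled without cultivation, such as hot-spring Synechococcus
    clone libraries. Assigns alleles and multi-locus sequence types, clusters
    sequence types into clonal complexes by single-locus-variant linkage
    (eBURST-style), computes per-alignment population-genetic summaries
    (segregating sites, Watterson's theta, pairwise-difference moments,
    Hudson-Kaplan Rmin, a moment estimate of the population recombination
    rate), detects putative homologous recombination from SNP patterning
    against dominant variants and reconciles event lists across detection
    methods, simulates genealogies under the Stable Ecotype Model (ecotype
    formation and periodic selection) to fit its parameters and demarcate
    putative ecotypes with confidence intervals, tests habitat association of
    demarcated ecotypes, classifies clone mate-pairs by synteny against a
    reference, and generates ecotype-structured synthetic datasets with known
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    withr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    ape,
    igraph,
    Biostrings,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
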