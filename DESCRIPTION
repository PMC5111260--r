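Package: stratanet
Title: Stage-Resolved Co-Expression Connectedness Analysis of Gene Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds correlation-threshold co-expression networks for a set of
    genes of interest (for example, differentially expressed genes from a
    case/control study) within strata of a developmental brain transcriptome
    compendium defined by brain region and developmental stage.  Assesses
    whether the gene set is more interconnected than expected by chance using
    a permutation null in which random genes are drawn with within-stratum
    expression ranks matched to the query genes, with Benjamini-Hochberg
    correction across strata.  Also provides hub-gene ranking and cross-stratum
    rank-correlation summaries, network expansion to top-connected background
    genes, copy-number dosage and positional contingency statistics along
    chromosomes, detection of high-interaction genomic regions from a binned
    interaction-correlation track, a UPGMA-based sample batching step with a
    simple location/scale adjustment, and a synthetic-data generator that
    emulates a region-by-stage expression compendium with planted co-expression
    modules, a hemizygous deletion interval, and an interaction track, so the
    whole analysis is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
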