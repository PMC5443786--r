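Package: smdiv
Title: Secondary Metabolite Biosynthetic Domain Diversity from Rhizosphere Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline for surveying non-ribosomal peptide
    synthetase (NRPS) and polyketide synthase (PKS) biosynthetic domain
    diversity in rhizosphere amplicon sequencing data. Provides IUPAC
    degenerate-primer arithmetic and in-silico amplicon extraction,
    pyrosequencing-style read quality control (rolling-window quality
    truncation, demultiplexing, dereplication, abundance-skew chimera
    flagging), greedy centroid clustering at multiple identity thresholds,
    Chao1 richness with rarefaction and an effective-species alpha/gamma
    community-overlap statistic, replicate-consistency and Venn sharing
    reports, neighbor-joining phylogenies of cluster representatives,
    ordination and negative-binomial differential-abundance statistics with
    bootstrap inference, rule-based functional assignment of domains by
    translated local alignment, and a synthetic amplicon community
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
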