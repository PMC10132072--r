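Package: ksclf
Title: Annotation-Free Discovery of Type II Polyketide Synthase KS-CLF Gene Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An annotation-free workflow for mining type II polyketide
    synthase ketosynthase/chain-length-factor (KS-CLF) gene pairs from raw
    nucleotide sequence. Starting from tabular translated-homology (tblastn
    style) hits, the pipeline calls, for every hit, the longest open reading
    frame containing it under alternative bacterial start codons, classifies
    the translated candidates with profile hidden Markov models whose
    retention thresholds are calibrated on a distantly related reference
    cluster, pairs KS and CLF genes by genomic proximity, extracts merged
    cluster regions around each pair, and prepares alignments and trees for
    phylogenetic analysis (gap-column trimming, support-based polytomy
    collapse, outgroup rooting). A synthetic-genome generator plants
    KS/CLF-like gene pairs and decoys with ground truth so the whole pipeline
    is testable without any database download.
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
    jsonlite,
    phytools,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
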