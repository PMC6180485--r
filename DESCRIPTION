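Package: termscape
Title: Spike-In Calibrated ChIP-Seq Analysis of Pol II Transcription Termination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying RNA polymerase II transcription termination
    from spike-in calibrated ChIP-seq. Implements species-partitioned read
    filtering and spike-in scale factors with input-mixture correction,
    strand-aware selection of non-overlapping protein-coding genes, TSS- and
    PAS-anchored metagene matrices and profiles, the post-polyadenylation-site
    termination (readthrough) index with median-based scaling and Wilcoxon
    rank-sum strain comparisons, validation of crosslinking mass-spectrometry
    restraints against structures with cross-species residue transfer by
    sequence alignment, and fluorescence-anisotropy binding-curve fitting.
    A synthetic-data generator produces two-species read mixtures, annotations,
    structures with planted crosslinks, and titrations with known ground truth
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    stringr,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    bio3d,
    minpack.lm,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
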