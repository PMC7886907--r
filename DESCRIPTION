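Package: loopcomp
Title: Loop Competition and Extrusion Modeling of CTCF Chromatin Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts which pairs of CTCF-binding sites form chromatin
    loops from four ingredients: ChIP-seq binding intensity, motif
    orientation, genomic distance, and competition between overlapping
    loops. Implements the closed-form loop probability, its approximate
    and iteratively solved loop-competition terms, a Cohesin pass-through
    extension for WAPL-depleted cells, AUPRC-based grid calibration with
    chromosomal cross-validation, matched-negative sampling,
    enhancer-promoter constraint analysis, cell-type loop comparison,
    in-silico CTCF site perturbation, and a synthetic landscape
    generator so the whole pipeline is testable without external data.
    Readers and writers are provided for narrowPeak, BEDPE, JASPAR PFM
    and FASTA inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
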