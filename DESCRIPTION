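Package: rnasm
Title: Somatic Mutation Discovery from Tumor RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects somatic mutations from tumor RNA-seq data by rejecting
    RNA-specific artifacts. Variant candidates from a caller are screened by a
    configurable bank of eighteen filters over per-site read evidence
    (dual-aligner and dual-caller concordance, known RNA-editing sites,
    soft-clip and splice-junction proximity, uneven flanking coverage, strand
    bias, germline matching and more), then scored by a stacking ensemble
    (random forest, gradient boosting and a neural network under a logistic
    meta-learner) trained on 26 per-site features to separate DNA-backed
    mutations from RNA-only variants such as A-to-I editing. Downstream
    analytics cover pyrimidine-collapsed substitution spectra in the 96-channel
    SBS layout, non-negative least-squares exposure fitting against reference
    mutational signatures with per-mutation assignment, and validation against
    DNA-derived mutation sets with coverage-aware precision and sensitivity. A
    seeded simulator of truth-labelled candidates and evidence provides a
    reproducible benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    xgboost,
    yaml
Suggests:
    e1071,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
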