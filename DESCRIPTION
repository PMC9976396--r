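Package: msivote
Title: Microsatellite Instability Screening by Per-Locus Classifier Voting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens tumor samples for microsatellite instability (MSI) from
    small-panel targeted sequencing alignments without a paired normal. Each
    microsatellite locus is summarised as a max-normalized indel-length
    distribution; a logistic-regression and a support-vector classifier are
    trained per locus against mismatch-repair (dMMR/pMMR) labels, and a locus
    is called unstable only when both models agree. The fraction of unstable
    loci is the sample score, thresholded into MSS/gray-zone/MSI. Includes
    panel I/O, BAM feature extraction with the read filters of the method,
    locus auto-selection, model bundling, ROC/threshold evaluation with
    likelihood ratios, a bootstrap robustness driver, and a stutter-model
    read simulator that generates labelled synthetic cohorts and BAM
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    ggplot2,
    glmnet,
    generics,
    GenomicRanges,
    IRanges,
    pROC,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
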