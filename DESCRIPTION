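Package: ebfpkm
Title: Empirical Bayes Differential Expression from FPKM Point Estimates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hierarchical empirical Bayes differential expression analysis
    for RNA-seq abundance estimates on the FPKM scale. Per-condition FPKM
    point estimates with confidence intervals (as produced by
    Cufflinks-style quantification) are expanded into synthesized normal
    pseudo-replicates, extreme-abundance transcripts are filtered, and a
    normal-normal mixture model over user-declared expression patterns is
    fitted by EM, yielding a posterior probability for each transcript and
    pattern. Also provides read-level benchmark construction (rank
    proportional spike-in of uniquely mapping SAM reads and negative
    binomial over-dispersion noise), simulation designs, and ROC /
    true-discovery evaluation utilities.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
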