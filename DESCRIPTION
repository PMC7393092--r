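Package: epifinemap
Title: Functional Fine-Mapping of Noncoding GWAS Variants from Epigenetic
    Feature Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-GWAS functional fine-mapping of noncoding risk variants.
    Builds association blocks around lead SNPs from genome-wide association
    summary statistics, annotates member SNPs with binary epigenetic features
    (DNase hypersensitivity, histone marks, transcription-factor binding
    sites, pathway membership), and scores SNPs with a two-layer
    convolutional network trained under a multiple-instance, uncertainty-
    weighted cross-entropy loss against shuffled-feature control blocks.
    Downstream stages provide random-forest surrogate feature importance
    with permutation p-values, hypergeometric and binomial category
    enrichment, promoter/enhancer SNP-to-gene mapping, and candidate
    prioritization. A self-contained synthetic-data generator with planted
    causal SNPs supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
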