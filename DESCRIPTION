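Package: pairsig
Title: Rank-Based Gene-Pair Signature Discovery and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of relative-expression gene-pair
    signatures that separate Kawasaki disease from febrile bacterial and
    viral infection. Implements top-scoring-pair (TSP/k-TSP) scoring with a
    Wilcoxon rank-sum gene prefilter, a resampling stability-selection
    framework that ranks pairs by their repetition rate across thousands of
    stratified train/test splits, a majority-vote top-ranked gene-pair
    (TRGP) classifier with a fixed decision threshold at zero, a
    permutation null for pair scores, probeset-to-gene collapsing,
    confusion/ROC evaluation with confidence intervals, and a synthetic
    cohort generator with planted order-reversal pairs for ground-truth
    testing.
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
    generics,
    readr,
    jsonlite,
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
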