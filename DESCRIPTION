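Package: mcbench
Title: Benchmarking Multiclass Classifiers over Dataset Size and Train/Test Split Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A factorial benchmarking harness for multiclass classification on
    molecular-descriptor data. Generates synthetic multiclass descriptor tables,
    balances classes by undersampling, subsamples to fixed dataset sizes, splits
    at several train/test ratios, fits five classifier families (gradient-boosted
    trees, Gaussian naive Bayes, RBF support vector machine, multilayer
    perceptron, and a Parzen-kernel probabilistic neural network), and scores
    every model with a battery of 25 performance parameters including the
    early-recognition metrics RIE, BEDROC, enrichment factor and ROC enrichment.
    Results feed factorial ANOVA with Tukey post hoc tests and the Sum of
    Ranking Differences (SRD) multicriteria statistic with its randomization
    (CRRN) null distribution and cross-validated variant.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    nnet,
    xgboost,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
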