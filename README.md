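# mcbench

How much do **dataset size** and the **train/test split ratio** matter in
multiclass QSAR/QSPR classification — and does the answer depend on which of
the many performance metrics you look at?

mcbench is an R package (Bioconductor-style, S4) that implements the full
experimental machinery for answering that question reproducibly:

* a **synthetic descriptor-data generator** that emulates curated
  molecular-descriptor tables (multiclass, partially collinear z-scored
  columns, tunable class separation and imbalance), so the whole pipeline is
  testable without any external downloads;
* a **factorial benchmarking harness**: equal-balance undersampling →
  stratified subsampling to a fixed dataset size (NS) → stratified
  train/test splitting at a given split ratio (SR) → model fitting →
  scoring, with three nested seeded repetition loops that train 5 × 5 × 5 =
  **125 models per (algorithm, NS, SR) cell** at default settings, each
  scored by cross-validation and test validation;
* five classifier families behind one contract: gradient-boosted trees
  (XGBoost), Gaussian naive Bayes, RBF-kernel SVM, a multilayer perceptron,
  and a Parzen-kernel probabilistic neural network (PNN, implemented here);
* a battery of **25 performance parameters** per model: RIE and BEDROC at
  α = 20 and 160.9, enrichment factors and ROC enrichment at 1% and 5%,
  AUAC, AUC, average precision, and the one-vs-rest macro-averaged
  confusion-matrix family (TPR, TNR, PPV, NPV, BM, MK, LRp, DOR, MCC,
  Cohen's kappa, ACC, BACC, Jaccard, F1);
* two statistical summarization layers: **factorial ANOVA** (Type III, with
  Tukey HSD post hoc tests and interaction means with 95% CIs) over the
  factors PP × ML × NS × SR, and the **Sum of Ranking Differences**.

## The SRD statistic

For a matrix with objects in rows (here: the 25 performance parameters) and
systems in columns (here: the 4 split ratios), each column *j* and a
reference vector (row maximum — an ideal system that maximizes every
metric) are rank-transformed, and

SRD_j = Σ_i | rank(x_ij) − rank(ref_i) |,

reported as a percent of the exact maximum footrule distance (n²/2 for even
n, (n²−1)/2 for odd). Smaller is closer to ideal. Validation is two-step:
the **CRRN** randomization test (the exact null distribution of SRD under
random ranking, enumerated for n ≤ 10, Monte Carlo beyond — a column below
the 5% point beats random ranking), and **k-fold cross-validated SRD**
whose fold-level values feed a one-way ANOVA over the systems.

## Worked example

```r
library(mcbench)

x <- generateDataset(SyntheticSpec(seed = 7))
x
#> DescriptorSet: 400 samples x 50 descriptors
#> classes: class_1 (150), class_2 (130), class_3 (120)

z <- zscoreStandardize(x)
cfg <- GridConfig(nsLevels = c("60", "120"), srLevels = c(50, 80),
                  balanceReps = 1L, sampleReps = 2L, splitReps = 2L,
                  algorithms = c("NB", "SVM"), masterSeed = 1L)
res <- runGrid(z, cfg)
res
#> BenchmarkResults: 64 records ( 32 CV / 32 test ) | 0 failed cell(s)
#> ML: NB, SVM | NS: 60, 120 | SR: 50, 80

long <- meltResults(normalizeEuclidean(res), "both")
interactionMeans(long, c("ML", "NS"))
#>    ML  NS   n       mean          se      lower      upper
#> 1  NB  60 400 0.09835101 0.001784685 0.09484245 0.10185957
#> 3  NB 120 400 0.12448216 0.001980286 0.12058906 0.12837526
#> 2 SVM  60 400 0.08463917 0.002940582 0.07885819 0.09042014
#> 4 SVM 120 400 0.14966224 0.001927890 0.14587215 0.15345233
```

Both algorithms improve with dataset size (the learning-curve effect), and
SVM overtakes naive Bayes once it has 120 samples to learn from. The
factorial ANOVA quantifies the factor effects on the normalized values —
here NS dominates (F ≈ 527), followed by SR (F ≈ 196):

```r
factorialAnova(long)$terms
#>          term       sumsq   df            F             p
#> 2          PP  0.13352615   24     3.529100  1.978146e-08
#> 3          ML  0.01315204    1     8.342613  3.926504e-03
#> 4          NS  0.83090917    1   527.062801 1.322288e-100
#> 5          SR  0.30916804    1   196.111658  4.859197e-42
#> ...
```

And the SRD comparison of split ratios (25 metrics × systems, row-maximum
reference):

```r
prof <- interactionMeans(long, c("PP", "SR"))
srdAnalysis(unclass(xtabs(mean ~ PP + SR, data = prof)), folds = 5, seed = 1)
#> SRDResult over 25 objects x 2 systems
#>             50 80
#> SRD raw 186.00  0
#> SRD %    59.62  0
#> CRRN random-ranking percentiles (SRD %): 5% = 52.6 | median = 66.7 | 95% = 80.8
#> better than random ranking (below 5% point): 80
```

The 80% split sits at SRD = 0 — identical to the row-maximum reference, i.e.
best on every one of the 25 metrics in this small design — while the 50%
split (59.6%) is indistinguishable from random ranking.

See `vignettes/mcbench-methods.Rmd` for the model, its assumptions, every
tunable parameter, and the numerical conventions.

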