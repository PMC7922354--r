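---
title: "Benchmarking multiclass classifiers over dataset size and split ratio: methods"
author: "mcbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking multiclass classifiers over dataset size and split ratio: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcbench)
```

## The question and the experimental design

In QSAR/QSPR classification the same algorithm on the same chemical series can
look very different depending on two mundane choices: how many samples go into
the model, and how the sampled set is split between training and test. mcbench
implements a factorial benchmark that treats these choices — dataset size (NS),
train/test split ratio (SR), learning algorithm (ML), and the performance
parameter used for scoring (PP) — as crossed experimental factors, and then
analyzes their effects with factorial ANOVA and with the Sum of Ranking
Differences (SRD) multicriteria statistic.

The experimental unit is a *model*: one algorithm fitted on one training set.
The harness (`runGrid()`) nests three seeded repetition loops:

1. **Balance** (`balanceReps`, default 5): the input table is reduced to equal
   class sizes by undersampling every class to the minority count, re-drawn
   each repetition so all majority-class rows get a chance to participate.
2. **Subsample** (`sampleReps`, default 5): a stratified random subset of NS
   rows is drawn; the sentinel level `"total"` keeps the whole balanced table
   and collapses this loop to a single iteration.
3. **Split** (`splitReps`, default 5): a stratified train/test split at the
   SR percentage.

With defaults this trains $5 \times 5 \times 5 = 125$ models per
(ML, NS, SR) cell — 25 per cell at `NS = "total"` — and scores each model
twice with the full 25-parameter battery: on pooled out-of-fold predictions of
a 5-fold stratified cross-validation of the training part (`Split = "CV"`) and
on the held-out test rows (`Split = "test"`). All algorithms run at fixed
default settings; the harness deliberately performs no feature selection or
hyperparameter optimization so that factor effects, not tuning skill, are
compared.

All randomness derives from one master seed through a counter-based
child-seed scheme (stage index plus loop indices hashed modulo a Mersenne
prime), so a grid is exactly reproducible and any single cell can be re-run
in isolation.

## The synthetic descriptor generator

The benchmark is exercised on synthetic data whose statistical shape mimics a
curated molecular-descriptor table: `generateDataset()` draws class-$k$
samples in a `latentDim`-dimensional latent space as Gaussians whose means sit
`classSeparation` latent-noise standard deviations apart along orthonormal
directions, embeds the latent coordinates linearly into `nInformative`
descriptor columns, adds per-column Gaussian noise, fills the remaining
columns with pure noise, and finally mixes all columns with
$(1-\rho)I + \rho Q$ ($Q$ random orthogonal, $\rho$ = `correlationStrength`)
to induce the collinearity that real descriptor blocks show.

The defaults define the package's reference study conditions and were chosen
to place the benchmark in the *data-limited* regime where the dataset-size
question is meaningful:

* `nClasses = 3`, `nPerClass = c(150, 130, 120)` — a mildly imbalanced
  three-class problem, so balancing has real work to do;
* `nDescriptors = 50`, `nInformative = 40`, `latentDim = 15` — most columns
  carry signal, but the signal lives on a 15-dimensional manifold, giving a
  redundancy ratio of about 2.7. This emulates the strong intercorrelation of
  descriptor families and is also the structural feature that the
  independence assumption of naive Bayes is known to break on;
* `classSeparation = 3.2`, `descriptorNoiseSd = 1` — moderate difficulty:
  held-out accuracy around 0.6–0.8 at a few hundred samples and still rising
  at $N = 240$, so performance grows with sample size instead of saturating;
* `correlationStrength = 0.5` — substantial, but well below the degenerate
  $\rho \to 1$ limit.

What the generator does **not** emulate: molecular realism (no structures, no
descriptor semantics), non-Gaussian or multimodal class shapes (real activity
classes are scaffold-clustered), heavy-tailed descriptor distributions, and
the descriptor-curation steps (intercorrelation filtering beyond a
near-constant drop). Consequently, passing trend tests here shows that the
pipeline reproduces the *mechanisms* — learning curves, split-ratio effects,
metric sensitivity — on data satisfying its assumptions; it is not evidence
about any particular chemical dataset.

`zscoreStandardize()` standardizes columns with the sample-SD ($n-1$)
convention, recording the convention in the object metadata; columns with SD
below `1e-8` are near-constant, cannot be scaled, and are dropped with a
message (or rejected when `drop = FALSE`).

## The 25-parameter battery

Every model is scored one-vs-rest per class and macro-averaged over the
classes present in the truth, except accuracy (trace of the $K \times K$
confusion matrix over $N$) and Cohen's kappa
$(p_o - p_e)/(1 - p_e)$, which are computed on the full multiclass matrix.
The ranking metrics use the adapter's class-$c$ score column with fractional
(mid) ranks on ties: AUC as the Mann–Whitney concordance probability (ties
half credit), AUAC under the continuous-rank convention
$\frac1n\sum_i(1 - x_i) + \frac{1}{2N}$ with $x_i = r_i/N$, average precision,
the robust initial enhancement
$\mathrm{RIE}(\alpha) = \sum_i e^{-\alpha x_i} \big/
\frac{n}{N}\frac{1-e^{-\alpha}}{e^{\alpha/N}-1}$ at $\alpha = 20$ and $160.9$,
BEDROC as min–max-scaled RIE (scaled between the all-actives-first and
all-actives-last configurations), the enrichment factor at the top 1% and 5%
of the ranked list, and ROC enrichment (TPR at FPR = 1% and 5%, linearly
interpolated on the empirical ROC, which draws diagonal segments across tied
blocks).

Numerical choices worth knowing about:

* **Unbounded ratios.** LRp and DOR are infinite whenever a one-vs-rest
  confusion cell is empty — routine on small test sets.  Clipping their
  denominators at $1/(2N)$ makes the ceiling itself scale with the
  evaluation-set size, which in pilot runs made mean DOR *fall* with dataset
  size — a pure artifact, and opposite to the size sensitivity these two
  metrics are known for. The package therefore applies the Haldane–Anscombe
  correction instead (0.5 added to every cell of the one-vs-rest table when
  any cell is empty); the bounded ratios keep a plain $\varepsilon = 1/(2N)$
  denominator clip, which only fires in degenerate inputs.
* **Ties.** Fractional ranks mean a classifier that emits hard 0/1 scores
  gets chance-level early-recognition credit within its tied blocks; adapters
  therefore always emit continuous scores (log densities or probabilities).
* **Degenerate classes.** A class with zero actives or zero inactives in the
  evaluation set cannot be ranked one-vs-rest and is skipped from the macro
  average with a message; an empty prediction set is an error.
* **CV scoring.** The CV battery is computed once per model on the pooled
  out-of-fold predictions rather than averaged over per-fold batteries:
  early-recognition metrics are unstable on 10-row folds, and pooling keeps
  one row per (model, validation) in the results table.

## Classifier adapters

Five families are exposed under one contract (`trainAndScore()`):
gradient-boosted trees (xgboost, softprob objective, `nrounds = 50`,
`max_depth = 4`, single thread), Gaussian naive Bayes (e1071, with the
posterior recomputed in log space from the fitted per-feature tables so that
products of thousands of densities cannot underflow), an RBF-kernel SVM with
probability output (e1071), a single-hidden-layer softmax perceptron (nnet,
`size = 5`, `decay = 0.1`), and a Parzen/Gaussian-kernel probabilistic neural
network implemented in the package: the class score is the log mean Gaussian
kernel density of the class's training points at the query, with a shared
bandwidth defaulting to the median pairwise training distance divided by
$\sqrt K$ (a scale-free default; the median is estimated on at most 200
training rows).  The NN and PNN components are standard fixed-architecture
stand-ins rather than reimplementations of any particular platform's
variants (resilient backpropagation, dynamic decay adjustment); the
benchmark's conclusions concern factor effects, for which the family-level
behavior is what matters.  The defaults above are deliberately modest —
models at these sample sizes are meant to be comparable, not optimal.

## Normalization, ANOVA, and SRD

The 25 metrics live on wildly different scales (DOR in the hundreds, kappa in
$[-1,1]$), so before any cross-metric averaging each metric column is divided
by its Euclidean norm over the rows analyzed together
(`normalizeEuclidean()`); when several result tables are compared jointly
they must be normalized jointly, which the function supports by accepting
merged data frames.

`meltResults()` turns the record-level table into one observation per
(record, PP). `factorialAnova()` fits a fixed-effects linear model with the
four main factors and configurable two-way interactions — defaulting to
PP×NS, NS×SR and ML×NS, the interactions the summary figures need; a full
25×5×4×4 factorial would burn thousands of degrees of freedom for nothing —
and reports Type III tests on sum contrasts, which remain meaningful under
the mild imbalance that failed cells introduce. Tukey's HSD
(`tukeyHsd()`) gives family-wise-adjusted pairwise comparisons for one
factor; `interactionMeans()` produces the cell means with t-based 95%
confidence intervals that back the summary plots (for the (ML, NS) pair these
are exactly the bubble values of an algorithm-by-size plot).

SRD (`computeSRD()`) rank-transforms each column and a reference vector —
row maximum by default, i.e. a hypothetical setting that maximizes every
performance parameter — and sums absolute rank differences per column;
fractional ranks keep the statistic integer-or-half valued and tie-order
independent. The percent scale divides by the exact maximum footrule
distance, $n^2/2$ ($n$ even) or $(n^2-1)/2$ ($n$ odd). Validation is
two-step, following standard SRD practice:

* **CRRN randomization test** (`crrnNull()`): the null distribution of SRD
  between the reference and a uniformly random permutation, exact for
  $n \le 10$ (computed by dynamic programming over the set of used ranks,
  which equals full $n!$ enumeration and is verified against it in the test
  suite), Monte Carlo ($10^5$ draws by default) beyond. A column below the
  5% point ranks significantly better than random.
* **Cross-validated SRD** (`srdCrossValidate()`): rows are partitioned into
  5–10 folds; each fold's leave-out SRD is rescaled to percent of the
  *reduced*-$n$ maximum (so fold values are comparable across fold sizes),
  and the fold-level values feed a one-way ANOVA (`onewayAnova()`) over the
  column systems.

In the headline analysis the SRD input matrix has the 25 performance
parameters as rows and the four split ratios as columns, each entry the mean
normalized value of that metric at that split ratio.

## Problem sizes and degenerate inputs

The package's own reference experiments run at desk scale: the bundled
acceptance analysis uses the default generator (400 samples, 50 descriptors),
NS levels 60/120/240, all four split ratios, repetition counts (2, 2, 2), and
five master seeds for the stochastic trend checks — about 480 models per
seed. The full-size design (NS up to thousands, repetitions 5/5/5) is the
same code with a different `GridConfig`.

Degenerate situations are contracts, not surprises: a split that cannot give
every class at least `cvFolds` training rows and one test row raises a
degenerate-split error naming the cell; inside `runGrid()` such cells — and
any adapter failure — are recorded in the `failures` slot and the grid
continues. Constant ANOVA responses are flagged degenerate rather than
producing NaN F statistics; all-zero metric columns are left unnormalized
with a message.

## Known limitations

* The trend properties (learning curves rising, naive Bayes trailing, the
  80% split winning the SRD comparison) are stochastic facts about the
  reference conditions, asserted as majorities over master seeds — on
  individual seeds a well-tuned small model can break an ordering.
* Macro one-vs-rest is the only averaging scheme; prevalence-weighted and
  micro variants, and Gorodkin's multiclass $R_K$ generalization of MCC,
  are out of scope (the macro-averaged binary MCC is used for internal
  consistency with the other one-vs-rest parameters).
* The repetition structure is analyzed as independent observations in a
  fixed-effects ANOVA; a mixed-model treatment of the nested repetitions is
  deliberately not attempted.
* Balanced undersampling discards data by design; oversampling approaches
  (SMOTE-type) are intentionally absent.
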