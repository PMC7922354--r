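#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' DescriptorSet: a multiclass descriptor table
#'
#' Container for a samples-by-descriptors matrix of real-valued molecular
#' descriptors together with a categorical class label per sample.  Internally
#' the matrix is stored in the \linkS4class{SummarizedExperiment} orientation
#' (descriptors as rows, samples as columns) with the class label in
#' `colData()$label`; use [descriptorMatrix()] to obtain the conventional
#' samples-by-descriptors view.
#'
#' @slot ... inherits all slots from `SummarizedExperiment`.
#' @seealso [DescriptorSet()], [descriptorMatrix()], [classLabels()]
#' @export
setClass("DescriptorSet", contains = "SummarizedExperiment")

setValidity("DescriptorSet", function(object) {
    msg <- character()
    if (!"descriptors" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'descriptors' is required")
    else if (!all(is.finite(SummarizedExperiment::assay(object, "descriptors"))))
        msg <- c(msg, "descriptor values must all be finite")
    cd <- SummarizedExperiment::colData(object)
    if (!"label" %in% colnames(cd))
        msg <- c(msg, "colData must contain a 'label' column")
    else if (nlevels(factor(cd$label)) < 2L)
        msg <- c(msg, "labels must cover at least 2 distinct classes")
    if (length(msg)) msg else TRUE
})

#' Specification of a synthetic multiclass descriptor dataset
#'
#' Parameters of the generative model used by [generateDataset()]: class
#' structure lives in a low-rank latent Gaussian space whose class means are
#' `classSeparation` latent-noise standard deviations apart; the latent signal
#' is embedded linearly into `nInformative` of the `nDescriptors` columns, the
#' rest are pure noise, and a mixing operator of strength
#' `correlationStrength` induces descriptor collinearity.
#'
#' @slot nClasses integer, number of classes K (>= 2).
#' @slot nPerClass integer vector of per-class sample counts (length K).
#' @slot nDescriptors integer, number of descriptor columns D.
#' @slot nInformative integer, columns carrying class signal (<= D).
#' @slot classSeparation non-negative numeric, distance between latent class
#'   means in units of the latent noise SD.
#' @slot latentDim integer, dimension of the latent signal space.
#' @slot descriptorNoiseSd non-negative numeric, per-column additive noise SD.
#' @slot correlationStrength numeric in \[0, 1), descriptor mixing strength.
#' @slot seed integer master seed; all randomness is derived from it.
#' @seealso [SyntheticSpec()], [generateDataset()]
#' @export
setClass("SyntheticSpec",
    representation(
        nClasses = "integer",
        nPerClass = "integer",
        nDescriptors = "integer",
        nInformative = "integer",
        classSeparation = "numeric",
        latentDim = "integer",
        descriptorNoiseSd = "numeric",
        correlationStrength = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nClasses < 2L)
        msg <- c(msg, "nClasses must be >= 2")
    if (length(object@nPerClass) != object@nClasses)
        msg <- c(msg, "nPerClass must have one entry per class")
    if (any(object@nPerClass < 1L))
        msg <- c(msg, "all per-class counts must be >= 1")
    if (object@nDescriptors < 1L || object@nInformative < 1L || object@latentDim < 1L)
        msg <- c(msg, "all counts must be >= 1")
    if (object@nInformative > object@nDescriptors)
        msg <- c(msg, "nInformative must be <= nDescriptors")
    if (object@classSeparation < 0)
        msg <- c(msg, "classSeparation must be >= 0")
    if (object@descriptorNoiseSd < 0)
        msg <- c(msg, "descriptorNoiseSd must be >= 0")
    if (object@correlationStrength < 0 || object@correlationStrength >= 1)
        msg <- c(msg, "correlationStrength must lie in [0, 1)")
    if (length(msg)) msg else TRUE
})

#' Configuration of the 25-parameter performance battery
#'
#' @slot alphas two positive reals: the RIE/BEDROC exponential weights
#'   (defaults 20 and 160.9).
#' @slot fractions two reals in (0,1): the enrichment fractions for the
#'   enrichment factor and ROC enrichment (defaults 0.01 and 0.05).
#' @slot averaging averaging policy; only `"macro"` (one-vs-rest macro
#'   averaging) is implemented.
#' @slot epsilon small positive real used to clip ratio denominators; `NA`
#'   means the sample-size-dependent default 1/(2N).
#' @slot tiePolicy how tied scores are ranked; only `"fractional"`
#'   (mid-rank) is implemented.
#' @seealso [MetricConfig()], [metricBattery()]
#' @export
setClass("MetricConfig",
    representation(
        alphas = "numeric",
        fractions = "numeric",
        averaging = "character",
        epsilon = "numeric",
        tiePolicy = "character"
    )
)

setValidity("MetricConfig", function(object) {
    msg <- character()
    if (length(object@alphas) != 2L || any(object@alphas <= 0))
        msg <- c(msg, "alphas must be two positive reals")
    if (length(object@fractions) != 2L ||
        any(object@fractions <= 0 | object@fractions >= 1))
        msg <- c(msg, "fractions must be two reals in (0, 1)")
    if (!identical(object@averaging, "macro"))
        msg <- c(msg, "only macro one-vs-rest averaging is implemented")
    if (!is.na(object@epsilon) && object@epsilon <= 0)
        msg <- c(msg, "epsilon must be positive (or NA for 1/(2N))")
    if (!identical(object@tiePolicy, "fractional"))
        msg <- c(msg, "only the fractional (mid-rank) tie policy is implemented")
    if (length(msg)) msg else TRUE
})

#' Predictions of one fitted classifier on one evaluation set
#'
#' @slot trueLabels factor of observed class labels.
#' @slot predictedLabels factor of predicted class labels, same levels.
#' @slot classScores numeric N x K matrix of per-class scores used for
#'   ranking; columns named by class level.  Rows need not sum to one.
#' @seealso [PredictionSet()], [metricBattery()]
#' @export
setClass("PredictionSet",
    representation(
        trueLabels = "factor",
        predictedLabels = "factor",
        classScores = "matrix"
    )
)

setValidity("PredictionSet", function(object) {
    msg <- character()
    n <- length(object@trueLabels)
    lev <- levels(object@trueLabels)
    if (n < 1L)
        msg <- c(msg, "at least one sample is required")
    if (length(object@predictedLabels) != n)
        msg <- c(msg, "predictedLabels must match trueLabels in length")
    if (!all(levels(object@predictedLabels) %in% lev) ||
        !all(as.character(object@predictedLabels) %in% lev))
        msg <- c(msg, "predicted labels must lie in the declared class set")
    if (nrow(object@classScores) != n)
        msg <- c(msg, "classScores must have one row per sample")
    if (!identical(colnames(object@classScores), lev))
        msg <- c(msg, "classScores columns must be named by the class levels")
    if (!all(is.finite(object@classScores)))
        msg <- c(msg, "classScores must be finite")
    if (length(msg)) msg else TRUE
})

#' Factorial experiment design of the benchmarking harness
#'
#' Factor levels and repetition counts of the balance / subsample / split /
#' fit loop executed by [runGrid()].  With the default repetition counts
#' (5, 5, 5) each (algorithm, dataset size, split ratio) cell trains
#' 5 x 5 x 5 = 125 models; the sentinel dataset-size level `"total"` keeps
#' all rows of the balanced table and collapses the subsampling loop, giving
#' 25 models per cell.
#'
#' @slot nsLevels character vector of dataset sizes; integers as strings
#'   plus optionally the sentinel `"total"`.
#' @slot srLevels numeric vector of training-set percentages in (0, 100).
#' @slot balanceReps,sampleReps,splitReps positive integers.
#' @slot cvFolds integer >= 2, folds of the stratified cross-validation.
#' @slot algorithms character vector of algorithm names (see
#'   [trainAndScore()]).
#' @slot algorithmSettings named list of per-algorithm setting overrides.
#' @slot stratified logical; stratify subsampling and splitting by class.
#' @slot masterSeed integer; every stage seed is derived from it.
#' @seealso [GridConfig()], [runGrid()]
#' @export
setClass("GridConfig",
    representation(
        nsLevels = "character",
        srLevels = "numeric",
        balanceReps = "integer",
        sampleReps = "integer",
        splitReps = "integer",
        cvFolds = "integer",
        algorithms = "character",
        algorithmSettings = "list",
        stratified = "logical",
        masterSeed = "integer"
    )
)

setValidity("GridConfig", function(object) {
    msg <- character()
    nonTotal <- setdiff(object@nsLevels, "total")
    if (anyNA(suppressWarnings(as.integer(nonTotal))))
        msg <- c(msg, "nsLevels must be integers or the sentinel 'total'")
    if (any(object@srLevels <= 0 | object@srLevels >= 100))
        msg <- c(msg, "srLevels must lie in (0, 100)")
    if (object@balanceReps < 1L || object@sampleReps < 1L || object@splitReps < 1L)
        msg <- c(msg, "repetition counts must be >= 1")
    if (object@cvFolds < 2L)
        msg <- c(msg, "cvFolds must be >= 2")
    if (!all(object@algorithms %in% mcbenchAlgorithms()))
        msg <- c(msg, paste0("algorithms must be among: ",
                             paste(mcbenchAlgorithms(), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Long-format results of a benchmarking grid
#'
#' One row per (model, validation type): the factor levels identifying the
#' model (`ML`, `SR`, `NS`, repetition indices), the validation flag
#' (`Split`: `"CV"` for pooled out-of-fold predictions, `"test"` for the
#' held-out split), and the 25 performance parameters.
#'
#' @slot results data.frame in the long format described above.
#' @slot config the \linkS4class{GridConfig} that produced it.
#' @slot provenance list with the config hash and master seed.
#' @slot failures data.frame describing failed cells (possibly empty).
#' @slot normalized logical; TRUE after [normalizeEuclidean()].
#' @seealso [runGrid()], [resultsTable()], [meltResults()]
#' @export
setClass("BenchmarkResults",
    representation(
        results = "data.frame",
        config = "GridConfig",
        provenance = "list",
        failures = "data.frame",
        normalized = "logical"
    )
)

#' Result of a Sum of Ranking Differences analysis
#'
#' @slot srdRaw named numeric, raw SRD per column (integer- or half-valued
#'   under fractional ranking).
#' @slot srdPercent named numeric, SRD as percent of the theoretical maximum.
#' @slot nObjects integer, number of ranked objects (rows).
#' @slot nullPercentiles numeric, the 5% / 50% / 95% points of the CRRN
#'   (random-ranking) null distribution on the percent scale.
#' @slot nullDistribution data.frame of the null (srd, probability), possibly
#'   empirical.
#' @slot cvValues numeric fold x column matrix of cross-validated SRD% values
#'   (empty if CV was not requested).
#' @seealso [srdAnalysis()], [computeSRD()], [crrnNull()]
#' @export
setClass("SRDResult",
    representation(
        srdRaw = "numeric",
        srdPercent = "numeric",
        nObjects = "integer",
        nullPercentiles = "numeric",
        nullDistribution = "data.frame",
        cvValues = "matrix"
    )
)

setValidity("SRDResult", function(object) {
    msg <- character()
    mx <- maxSRD(object@nObjects)
    if (any(object@srdRaw < 0 | object@srdRaw > mx))
        msg <- c(msg, "srdRaw must lie in [0, maxSRD(n)]")
    if (any(abs(object@srdPercent - 100 * object@srdRaw / mx) > 1e-9))
        msg <- c(msg, "srdPercent must equal 100 * srdRaw / maxSRD(n)")
    if (length(msg)) msg else TRUE
})
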