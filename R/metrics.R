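#' Canonical names of the 25 performance parameters
#'
#' The battery covers early-recognition metrics (robust initial enhancement
#' RIE and its min-max-scaled form BEDROC at exponential weights alpha = 20
#' and 160.9; enrichment factor and ROC enrichment at 1% and 5%), ranking
#' summaries (AUAC, AUC, average precision), and confusion-matrix parameters
#' (rates, predictive values, informedness/markedness, likelihood ratios,
#' correlation and agreement coefficients, accuracies, Jaccard and F1).
#'
#' @return Character vector of the 25 canonical metric names, in battery
#'   order.
#' @export
metricNames <- function() {
    c("RIE20", "RIE1609", "BEDROC20", "BEDROC1609", "EF1", "EF5",
      "ROC_EF1", "ROC_EF5", "AUAC", "AUC", "AP", "TPR", "TNR", "PPV",
      "NPV", "BM", "MK", "LRp", "DOR", "MCC", "Cohen", "ACC", "BACC",
      "Jaccard", "F1")
}

#' Construct a MetricConfig
#'
#' @param alphas RIE/BEDROC exponential weights (default `c(20, 160.9)`).
#' @param fractions enrichment fractions (default `c(0.01, 0.05)`).
#' @param averaging only `"macro"` (one-vs-rest) is implemented.
#' @param epsilon denominator clip; `NA` (default) means 1/(2N), which keeps
#'   likelihood-ratio-type metrics finite when a cell of the confusion
#'   matrix is empty.
#' @param tiePolicy only `"fractional"` (mid-rank) is implemented.
#' @return A \linkS4class{MetricConfig}.
#' @export
MetricConfig <- function(alphas = c(20, 160.9), fractions = c(0.01, 0.05),
                         averaging = "macro", epsilon = NA_real_,
                         tiePolicy = "fractional") {
    new("MetricConfig", alphas = as.numeric(alphas),
        fractions = as.numeric(fractions), averaging = averaging,
        epsilon = as.numeric(epsilon), tiePolicy = tiePolicy)
}

#' Construct a PredictionSet
#'
#' @param trueLabels observed class labels.
#' @param predictedLabels predicted class labels.
#' @param classScores numeric N x K matrix of per-class scores with columns
#'   named by class; rows need not sum to one.
#' @param classLevels optional explicit class set; defaults to the union of
#'   levels seen in `trueLabels` and the score columns.
#' @return A \linkS4class{PredictionSet}.
#' @export
PredictionSet <- function(trueLabels, predictedLabels, classScores,
                          classLevels = NULL) {
    classScores <- as.matrix(classScores)
    if (is.null(classLevels))
        classLevels <- union(levels(factor(trueLabels)), colnames(classScores))
    if (is.null(colnames(classScores))) {
        if (ncol(classScores) != length(classLevels))
            stop("classScores needs one named column per class")
        colnames(classScores) <- classLevels
    }
    bad <- setdiff(unique(as.character(predictedLabels)), classLevels)
    if (length(bad))
        stop("predicted label(s) outside the declared class set: ",
             paste(bad, collapse = ", "))
    new("PredictionSet",
        trueLabels = factor(trueLabels, levels = classLevels),
        predictedLabels = factor(predictedLabels, levels = classLevels),
        classScores = classScores[, classLevels, drop = FALSE])
}

setMethod("show", "PredictionSet", function(object) {
    cat("PredictionSet:", length(object@trueLabels), "samples,",
        nlevels(object@trueLabels), "classes (",
        paste(levels(object@trueLabels), collapse = ", "), ")\n")
    cat("accuracy:", format(mean(object@trueLabels == object@predictedLabels),
                            digits = 3), "\n")
})

#' Multiclass and one-vs-rest confusion counts
#'
#' @param pred a \linkS4class{PredictionSet}.
#' @return A list with `matrix`, the K x K confusion matrix (rows = true,
#'   columns = predicted), and `perClass`, a data.frame of one-vs-rest
#'   TP/FP/FN/TN counts per class.  For every class TP + FP + FN + TN = N.
#' @export
confusionCounts <- function(pred) {
    stopifnot(is(pred, "PredictionSet"))
    tl <- pred@trueLabels
    pl <- pred@predictedLabels
    cm <- table(true = tl, predicted = pl)
    cm <- unclass(cm)
    tp <- diag(cm)
    fn <- rowSums(cm) - tp
    fp <- colSums(cm) - tp
    tn <- sum(cm) - tp - fn - fp
    list(matrix = cm,
         perClass = data.frame(class = rownames(cm), TP = as.numeric(tp),
                               FP = as.numeric(fp), FN = as.numeric(fn),
                               TN = as.numeric(tn), row.names = NULL))
}

clipDenom <- function(x, eps) pmax(x, eps)

#' Confusion-matrix performance parameters
#'
#' Computes the 14 confusion-matrix members of the battery.  `ACC`
#' (trace/N) and `Cohen` (Cohen's kappa, `(p_o - p_e) / (1 - p_e)`) are
#' computed on the full K x K matrix; every other parameter is computed
#' one-vs-rest per class and macro-averaged over the classes present in the
#' true labels.  Denominators of the bounded ratios are clipped at `epsilon`
#' (default 1/(2N)) before division; the unbounded LRp and DOR use the
#' Haldane-Anscombe zero-cell correction (0.5 added to every cell of the
#' one-vs-rest table when any cell is empty), which keeps them finite
#' without tying their ceiling to the evaluation-set size.
#'
#' @param counts output of [confusionCounts()].
#' @param config a \linkS4class{MetricConfig}.
#' @return Named numeric vector: TPR, TNR, PPV, NPV, BM, MK, LRp, DOR, MCC,
#'   Cohen, ACC, BACC, Jaccard, F1.
#' @export
confusionMetrics <- function(counts, config = MetricConfig()) {
    methods::validObject(config)
    cm <- counts$matrix
    pc <- counts$perClass
    N <- sum(cm)
    if (N < 1L) stop("empty prediction set")
    eps <- if (is.na(config@epsilon)) 1 / (2 * N) else config@epsilon

    present <- rowSums(cm) > 0
    if (!all(present))
        message("class(es) absent from true labels excluded from macro average: ",
                paste(rownames(cm)[!present], collapse = ", "))
    pc <- pc[present, , drop = FALSE]

    TP <- pc$TP; FP <- pc$FP; FN <- pc$FN; TN <- pc$TN
    TPR <- TP / clipDenom(TP + FN, eps)
    TNR <- TN / clipDenom(TN + FP, eps)
    PPV <- TP / clipDenom(TP + FP, eps)
    NPV <- TN / clipDenom(TN + FN, eps)
    F1 <- 2 * PPV * TPR / clipDenom(PPV + TPR, eps)
    Jac <- TP / clipDenom(TP + FP + FN, eps)
    BM <- TPR + TNR - 1
    MK <- PPV + NPV - 1
    BACC <- (TPR + TNR) / 2
    MCC <- (TP * TN - FP * FN) /
        clipDenom(sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)), eps)
    # LRp/DOR are unbounded; a zero cell is handled by the Haldane-Anscombe
    # correction (0.5 added to every cell) so the ceiling does not scale
    # with the evaluation-set size
    hal <- (TP == 0) | (FP == 0) | (FN == 0) | (TN == 0)
    TPh <- TP + 0.5 * hal; FPh <- FP + 0.5 * hal
    FNh <- FN + 0.5 * hal; TNh <- TN + 0.5 * hal
    TPRh <- TPh / (TPh + FNh)
    TNRh <- TNh / (TNh + FPh)
    LRp <- TPRh / (1 - TNRh)
    DOR <- (TPh * TNh) / (FPh * FNh)

    po <- sum(diag(cm)) / N
    pe <- sum(rowSums(cm) * colSums(cm)) / N^2
    cohen <- if (abs(1 - pe) < .Machine$double.eps^0.5) 0 else (po - pe) / (1 - pe)

    c(TPR = mean(TPR), TNR = mean(TNR), PPV = mean(PPV), NPV = mean(NPV),
      BM = mean(BM), MK = mean(MK), LRp = mean(LRp), DOR = mean(DOR),
      MCC = mean(MCC), Cohen = cohen, ACC = po, BACC = mean(BACC),
      Jaccard = mean(Jac), F1 = mean(F1))
}

# One-vs-rest ranking metrics for a single class given scores and an
# active indicator; N total samples, n actives, m inactives (both >= 1).
rankingMetricsOneClass <- function(scores, active, config) {
    N <- length(scores)
    n <- sum(active)
    m <- N - n
    aScores <- scores[active]

    # ascending fractional ranks by score -> Mann-Whitney AUC with half
    # credit for ties
    raAsc <- rank(scores, ties.method = "average")
    auc <- (sum(raAsc[active]) - n * (n + 1) / 2) / (n * m)

    # descending fractional relative ranks of the actives
    rDesc <- rank(-scores, ties.method = "average")
    xi <- rDesc[active] / N
    auac <- mean(1 - xi) + 1 / (2 * N)

    # average precision over a descending sort (stable within ties)
    ord <- order(scores, decreasing = TRUE)
    hits <- cumsum(active[ord])
    ap <- mean((hits / seq_len(N))[active[ord]])

    rieDenom <- function(alpha) (n / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
    rie <- vapply(config@alphas, function(alpha) {
        sum(exp(-alpha * xi)) / rieDenom(alpha)
    }, numeric(1))
    bedroc <- vapply(seq_along(config@alphas), function(j) {
        alpha <- config@alphas[j]
        best <- sum(exp(-alpha * seq_len(n) / N)) / rieDenom(alpha)
        worst <- sum(exp(-alpha * seq.int(N - n + 1, N) / N)) / rieDenom(alpha)
        (rie[j] - worst) / (best - worst)
    }, numeric(1))

    ef <- vapply(config@fractions, function(chi) {
        k <- ceiling(chi * N)
        (hits[k] / k) / (n / N)
    }, numeric(1))

    # empirical ROC: one point per distinct score (ties grouped), linear
    # interpolation -> diagonal segments across tied blocks
    byScore <- rev(split(seq_len(N), scores)) # descending score groups
    tpCum <- cumsum(vapply(byScore, function(i) sum(active[i]), numeric(1)))
    fpCum <- cumsum(vapply(byScore, function(i) sum(!active[i]), numeric(1)))
    fpr <- c(0, fpCum / m)
    tpr <- c(0, tpCum / n)
    rocEf <- vapply(config@fractions, function(chi) {
        stats::approx(fpr, tpr, xout = chi, ties = max)$y
    }, numeric(1))

    c(RIE = rie, BEDROC = bedroc, EF = ef, ROC_EF = rocEf,
      AUAC = auac, AUC = auc, AP = ap)
}

#' Ranking (early-recognition) performance parameters
#'
#' For each class c the samples are ranked by the class-c score column,
#' treating class c as "active" one-vs-rest, and the eleven ranking metrics
#' are computed: AUC (pairwise concordance probability, ties counted half),
#' AUAC under the continuous-rank convention, average precision, RIE and
#' BEDROC at both configured alphas, enrichment factor and ROC enrichment
#' at both configured fractions.  Tied scores receive fractional (mid)
#' ranks.  Results are macro-averaged over classes; a class with zero
#' actives or zero inactives is skipped with a message.
#'
#' @param pred a \linkS4class{PredictionSet}.
#' @param config a \linkS4class{MetricConfig}.
#' @return Named numeric vector: RIE20, RIE1609, BEDROC20, BEDROC1609, EF1,
#'   EF5, ROC_EF1, ROC_EF5, AUAC, AUC, AP (names follow the configured
#'   alphas/fractions only in value, not in spelling).
#' @export
rankingMetrics <- function(pred, config = MetricConfig()) {
    stopifnot(is(pred, "PredictionSet"))
    methods::validObject(config)
    tl <- pred@trueLabels
    N <- length(tl)
    lev <- levels(tl)
    usable <- vapply(lev, function(cl) {
        n <- sum(tl == cl); n >= 1 && n < N
    }, logical(1))
    if (!any(usable))
        stop("no class has both actives and inactives")
    if (!all(usable))
        message("class(es) without both actives and inactives skipped: ",
                paste(lev[!usable], collapse = ", "))
    per <- vapply(lev[usable], function(cl) {
        rankingMetricsOneClass(pred@classScores[, cl], tl == cl, config)
    }, numeric(11))
    avg <- rowMeans(per)
    stats::setNames(avg, c("RIE20", "RIE1609", "BEDROC20", "BEDROC1609",
                           "EF1", "EF5", "ROC_EF1", "ROC_EF5",
                           "AUAC", "AUC", "AP"))
}

#' The full 25-parameter performance battery
#'
#' Union of [rankingMetrics()] and [confusionMetrics()], in the canonical
#' order of [metricNames()].  Deterministic given its inputs.
#'
#' @param pred a \linkS4class{PredictionSet}.
#' @param config a \linkS4class{MetricConfig}.
#' @return Named numeric vector of length 25.
#' @examples
#' p <- PredictionSet(c("a", "a", "b", "b"), c("a", "b", "b", "b"),
#'                    cbind(a = c(.9, .4, .3, .2), b = c(.1, .6, .7, .8)))
#' metricBattery(p)
#' @export
metricBattery <- function(pred, config = MetricConfig()) {
    out <- c(rankingMetrics(pred, config),
             confusionMetrics(confusionCounts(pred), config))
    out[metricNames()]
}
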