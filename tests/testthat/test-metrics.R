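test_that("confusion counts tally correctly and conserve N", {
    # perfect 3-class prediction
    sc <- diag(3); colnames(sc) <- c("a", "b", "c")
    p <- PredictionSet(c("a", "b", "c"), c("a", "b", "c"), sc)
    cc <- confusionCounts(p)
    expect_equal(unname(diag(cc$matrix)), rep(1L, 3), ignore_attr = TRUE)
    expect_equal(cc$perClass$TP, rep(1, 3))
    expect_equal(cc$perClass$FP, rep(0, 3))
    expect_equal(cc$perClass$TN, rep(2, 3))

    # direct tally
    sc2 <- matrix(0.5, 4, 2, dimnames = list(NULL, c("a", "b")))
    p2 <- PredictionSet(c("a", "a", "b", "b"), c("a", "b", "b", "b"), sc2)
    cc2 <- confusionCounts(p2)
    a <- cc2$perClass[cc2$perClass$class == "a", ]
    expect_equal(c(a$TP, a$FN, a$FP, a$TN), c(1, 1, 0, 2))
    for (i in seq_len(nrow(cc2$perClass))) {
        expect_equal(sum(cc2$perClass[i, c("TP", "FP", "FN", "TN")]), 4)
    }
    expect_equal(sum(cc2$matrix), 4)
})

test_that("predictions outside the declared class set are rejected", {
    sc <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
    expect_error(PredictionSet(c("a", "b"), c("a", "z"), sc), "class set")
})

test_that("Cohen's kappa and chance-level symmetry behave as defined", {
    # binary counts TP=3, FN=1, FP=1, TN=3: p_o = .75, p_e = .5 -> kappa .5
    sc <- matrix(0.5, 8, 2, dimnames = list(NULL, c("n", "p")))
    p <- PredictionSet(rep(c("p", "n"), each = 4),
                       c("p", "p", "p", "n", "n", "n", "n", "p"), sc)
    cm <- confusionMetrics(confusionCounts(p))
    expect_equal(cm[["Cohen"]], 0.5)
    expect_equal(cm[["ACC"]], 0.75)
    expect_equal(cm[["MCC"]], 0.5)

    # identical confusion rows: agreement at chance, kappa = BM = 0
    truth <- rep(c("a", "b"), each = 4)
    pred <- rep(c("a", "a", "b", "b"), 2)
    sc2 <- matrix(0.5, 8, 2, dimnames = list(NULL, c("a", "b")))
    cm2 <- confusionMetrics(confusionCounts(PredictionSet(truth, pred, sc2)))
    expect_equal(cm2[["Cohen"]], 0)
    expect_equal(cm2[["BM"]], 0, tolerance = 1e-12)
})

test_that("perfect predictions reach the maxima of the bounded metrics", {
    lev <- c("a", "b", "c")
    truth <- rep(lev, each = 5)
    # perfect and tie-free: every active scores above every inactive
    jitter <- seq(0.01, 0.15, length.out = 15)
    sc <- vapply(lev, function(cl) as.numeric(truth == cl) + jitter,
                 numeric(15))
    p <- PredictionSet(truth, truth, sc)
    b <- metricBattery(p)
    for (m in c("ACC", "Cohen", "MCC", "BM", "MK", "F1", "Jaccard", "TPR",
                "TNR", "PPV", "NPV", "BACC", "AUC", "AP", "BEDROC20",
                "BEDROC1609")) {
        expect_equal(b[[m]], 1, tolerance = 1e-12, label = m)
    }
    expect_true(b[["LRp"]] > 1 && b[["DOR"]] > 1)
})

test_that("rank-formula AUC equals brute-force pairwise concordance", {
    set.seed(71)
    for (rep in 1:30) {
        n <- sample(5:50, 1)
        p <- randomPredictionSet(n, k = sample(2:4, 1),
                                 tieProb = rep %% 2)
        rm <- rankingMetrics(p)
        tl <- p@trueLabels
        perClass <- vapply(levels(tl), function(cl) {
            act <- tl == cl
            if (!any(act) || all(act)) return(NA_real_)
            bruteForceAUC(p@classScores[, cl], act)
        }, numeric(1))
        expect_equal(rm[["AUC"]], mean(perClass, na.rm = TRUE),
                     tolerance = 1e-12)
    }
})

test_that("worked ranking examples agree with direct evaluation", {
    # 4 active/inactive pairs, 3 concordant -> AUC = .75 (both classes by
    # complement symmetry)
    sc <- cbind(a = c(.9, .6, .7, .1), b = -c(.9, .6, .7, .1))
    p <- PredictionSet(c("a", "a", "b", "b"), c("a", "a", "b", "b"), sc)
    expect_equal(rankingMetrics(p)[["AUC"]], 0.75)

    # N=100, 10 actives, single top-ranked sample active -> class-a EF1 = 10
    s <- c(0.999, seq(0.5, 0.01, length.out = 99))
    lab <- c("a", rep("b", 90), rep("a", 9))
    p2 <- PredictionSet(lab, lab, cbind(a = s, b = -s))
    efA <- bruteForceEF(s, lab == "a", 0.01)
    expect_equal(efA, 10)
    efB <- bruteForceEF(-s, lab == "b", 0.01)
    expect_equal(rankingMetrics(p2)[["EF1"]], mean(c(efA, efB)))
})

test_that("random scores give chance-level AUC and unit enrichment", {
    set.seed(5)
    nShuffles <- 300
    act <- rep(c(TRUE, FALSE), c(20, 80))
    res <- t(vapply(seq_len(nShuffles), function(i) {
        s <- stats::runif(100)
        c(auc = bruteForceAUC(s, act), ef = bruteForceEF(s, act, 0.05))
    }, numeric(2)))
    # sanity of the oracle itself under the null
    expect_lt(abs(mean(res[, "auc"]) - 0.5),
              3 * stats::sd(res[, "auc"]) / sqrt(nShuffles))
    # implementation agrees with the oracle distribution
    imp <- t(vapply(seq_len(nShuffles), function(i) {
        s <- stats::runif(100)
        lab <- ifelse(act, "a", "b")
        p <- PredictionSet(lab, lab, cbind(a = s, b = stats::runif(100)))
        c(auc = rankingMetrics(p)[["AUC"]])
    }, numeric(1)))
    expect_lt(abs(mean(imp) - 0.5), 3 * stats::sd(imp) / sqrt(nShuffles))
})

test_that("metric vector bounds hold on randomized inputs", {
    set.seed(99)
    bounded01 <- c("AUC", "AUAC", "AP", "BEDROC20", "BEDROC1609", "ACC",
                   "BACC", "TPR", "TNR", "PPV", "NPV", "F1", "Jaccard")
    bounded11 <- c("MCC", "Cohen", "BM", "MK")
    nonneg <- c("EF1", "EF5", "ROC_EF1", "ROC_EF5", "RIE20", "RIE1609",
                "LRp", "DOR")
    for (rep in 1:25) {
        p <- randomPredictionSet(sample(10:60, 1), k = sample(2:5, 1),
                                 tieProb = rep %% 3 == 0)
        b <- suppressMessages(metricBattery(p))
        expect_true(all(is.finite(b)))
        expect_true(all(b[bounded01] >= 0 & b[bounded01] <= 1 + 1e-12))
        expect_true(all(b[bounded11] >= -1 & b[bounded11] <= 1 + 1e-12))
        expect_true(all(b[nonneg] >= 0))
    }
})

test_that("the battery returns exactly the 25 canonical parameters, deterministically", {
    set.seed(3)
    p <- randomPredictionSet(40, k = 3)
    b1 <- metricBattery(p)
    b2 <- metricBattery(p)
    expect_length(b1, 25)
    expect_identical(names(b1), metricNames())
    expect_identical(b1, b2)
})

test_that("macro averaging over identical per-class values is the identity", {
    # two-class complement-score setting: both one-vs-rest problems are the
    # same problem mirrored, so per-class values coincide and the macro
    # average must equal the per-class value
    set.seed(8)
    s <- stats::runif(30)
    lab <- rep(c("a", "b"), 15)
    p <- PredictionSet(lab, lab, cbind(a = s, b = -s))
    rm <- rankingMetrics(p)
    expect_equal(rm[["AUC"]], bruteForceAUC(s, lab == "a"))
})

test_that("degenerate one-vs-rest classes are skipped with a message", {
    sc <- cbind(a = c(.9, .8, .2), b = c(.1, .2, .8), c = c(0, 0, 0))
    p <- PredictionSet(factor(c("a", "a", "b"), levels = c("a", "b", "c")),
                       factor(c("a", "a", "b"), levels = c("a", "b", "c")),
                       sc, classLevels = c("a", "b", "c"))
    expect_message(rm <- rankingMetrics(p), "skipped")
    expect_true(is.finite(rm[["AUC"]]))
    expect_message(cm <- confusionMetrics(confusionCounts(p)),
                   "excluded from macro")
    expect_true(all(is.finite(cm)))
})

test_that("all-tied scores are handled by fractional ranking, not an error", {
    sc <- matrix(0.5, 10, 2, dimnames = list(NULL, c("a", "b")))
    lab <- rep(c("a", "b"), 5)
    p <- PredictionSet(lab, lab, sc)
    rm <- rankingMetrics(p)
    expect_equal(rm[["AUC"]], 0.5)
})
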