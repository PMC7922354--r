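test_that("balancing keeps exactly the minority-class count from every class", {
    x <- noiseDescriptorSet(c(10, 7, 7), seed = 4)
    b <- balanceDataset(x, seed = 1)
    expect_equal(as.vector(table(classLabels(b))), rep(7L, 3))
    expect_true(all(sampleIds(b) %in% sampleIds(x)))

    # already balanced input is a fixed point up to row identity
    b2 <- balanceDataset(b, seed = 9)
    expect_setequal(sampleIds(b2), sampleIds(b))

    # the imbalance profile of a three-class curation: 2319 -> 1734 rows
    big <- noiseDescriptorSet(c(700, 600, 578), d = 2, seed = 5)
    bb <- balanceDataset(big, seed = 2)
    expect_equal(as.vector(table(classLabels(bb))), rep(578L, 3))
    expect_equal(ncol(bb), 1734L)

    empty <- noiseDescriptorSet(c(5, 5), seed = 6)
    expect_error(balanceDataset(empty[, 1:5]), "at least 2")
})

test_that("subsampling is stratified with seeded remainder allocation", {
    x <- noiseDescriptorSet(c(40, 40, 40), seed = 7)
    expect_identical(subsampleDataset(x, "total"), x)

    s99 <- subsampleDataset(x, 99, seed = 3)
    expect_equal(as.vector(table(classLabels(s99))), rep(33L, 3))

    s100 <- subsampleDataset(x, 100, seed = 3)
    counts <- sort(as.vector(table(classLabels(s100))))
    expect_equal(counts, c(33L, 33L, 34L))
    # the class receiving the extra row is a seeded choice
    extras <- vapply(1:20, function(s) {
        cc <- table(classLabels(subsampleDataset(x, 100, seed = s)))
        names(which.max(cc))
    }, character(1))
    expect_gt(length(unique(extras)), 1)

    expect_error(subsampleDataset(x, 500), "exceeds")
    expect_true(all(sampleIds(s100) %in% sampleIds(x)))
})

test_that("splitting honors the ratio with largest-remainder class allocation", {
    x <- noiseDescriptorSet(c(25, 25, 25, 25), seed = 8)
    sp <- splitTrainTest(x, 80, seed = 1)
    expect_equal(ncol(sp$train), 80L)
    expect_equal(ncol(sp$test), 20L)

    sp50 <- splitTrainTest(x, 50, seed = 1)
    expect_equal(ncol(sp50$train), 50L)
    # 12.5 per class rounds to 12 or 13 by largest remainder
    cc <- as.vector(table(classLabels(sp50$train)))
    expect_true(all(cc %in% c(12L, 13L)))
    expect_equal(sum(cc), 50L)

    # partition: disjoint and exhaustive
    expect_length(intersect(sampleIds(sp$train), sampleIds(sp$test)), 0)
    expect_setequal(c(sampleIds(sp$train), sampleIds(sp$test)), sampleIds(x))

    tiny <- noiseDescriptorSet(c(4, 4), seed = 9)
    expect_error(splitTrainTest(tiny, 50, minPerClass = 5L), "degenerate")
})

smallTable <- zscoreStandardize(generateDataset(
    SyntheticSpec(nPerClass = c(40L, 36L, 34L), nDescriptors = 10L,
                  nInformative = 6L, latentDim = 4L, classSeparation = 4,
                  seed = 77L)))

test_that("the grid bookkeeping yields the documented model counts", {
    cfg <- GridConfig(nsLevels = c("30", "total"), srLevels = c(50, 70),
                      balanceReps = 2L, sampleReps = 2L, splitReps = 2L,
                      cvFolds = 3L, algorithms = "NB", masterSeed = 4L)
    res <- runGrid(smallTable, cfg)
    df <- resultsTable(res)
    expect_equal(nrow(res@failures), 0L)
    # non-total cell: 2*2*2 = 8 models -> 16 records per SR
    non <- df[df$NS == "30" & df$SR == 50, ]
    expect_equal(nrow(non), 16L)
    expect_equal(nrow(unique(non[, c("balance_rep", "sample_rep",
                                     "split_rep")])), 8L)
    # total collapses the sample loop: 2*1*2 = 4 models -> 8 records per SR
    tot <- df[df$NS == "total" & df$SR == 50, ]
    expect_equal(nrow(tot), 8L)
    expect_true(all(tot$sample_rep == 1L))
    # every model contributes exactly one CV and one test record
    expect_equal(sum(df$Split == "CV"), sum(df$Split == "test"))
    expect_true(all(metricNames() %in% colnames(df)))
})

test_that("grids are reproducible from the master seed", {
    cfg <- GridConfig(nsLevels = "40", srLevels = 60, balanceReps = 1L,
                      sampleReps = 2L, splitReps = 1L, cvFolds = 3L,
                      algorithms = c("NB", "PNN"), masterSeed = 11L)
    r1 <- runGrid(smallTable, cfg)
    r2 <- runGrid(smallTable, cfg)
    expect_equal(resultsTable(r1), resultsTable(r2))
    r3 <- runGrid(smallTable, GridConfig(nsLevels = "40", srLevels = 60,
                                         balanceReps = 1L, sampleReps = 2L,
                                         splitReps = 1L, cvFolds = 3L,
                                         algorithms = c("NB", "PNN"),
                                         masterSeed = 12L))
    expect_false(isTRUE(all.equal(resultsTable(r1), resultsTable(r3))))
})

test_that("Euclidean normalization produces unit-norm columns", {
    df <- data.frame(a = c(3, 4), b = c(1, 0))
    out <- normalizeEuclidean(df, columns = c("a", "b"))
    expect_equal(out$a, c(0.6, 0.8))
    expect_equal(out$b, c(1, 0))
    # idempotent on unit-norm input
    expect_equal(normalizeEuclidean(out, columns = c("a", "b")), out)

    zeros <- data.frame(a = c(0, 0), b = c(2, 1))
    expect_message(z <- normalizeEuclidean(zeros, columns = c("a", "b")),
                   "all zeros")
    expect_equal(z$a, c(0, 0))

    cfg <- GridConfig(nsLevels = "30", srLevels = 70, balanceReps = 1L,
                      sampleReps = 1L, splitReps = 2L, cvFolds = 3L,
                      algorithms = "NB", masterSeed = 2L)
    res <- normalizeEuclidean(runGrid(smallTable, cfg))
    norms <- vapply(metricNames(), function(m) {
        sqrt(sum(resultsTable(res)[[m]]^2))
    }, numeric(1))
    expect_true(all(abs(norms - 1) < 1e-12))
})

test_that("results CSV round-trips the long format", {
    cfg <- GridConfig(nsLevels = "30", srLevels = 70, balanceReps = 1L,
                      sampleReps = 1L, splitReps = 1L, cvFolds = 3L,
                      algorithms = "NB", masterSeed = 6L)
    res <- runGrid(smallTable, cfg)
    path <- withr::local_tempfile(fileext = ".csv")
    writeResultsCSV(res, path)
    back <- readResultsCSV(path)
    expect_equal(back$NS, resultsTable(res)$NS)
    expect_equal(back$AUC, resultsTable(res)$AUC, tolerance = 1e-12)
})
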