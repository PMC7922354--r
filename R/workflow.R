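#' Construct a GridConfig
#'
#' @param nsLevels dataset sizes: integers and/or the sentinel `"total"`.
#'   The study default is `c("100", "500", "1000", "total")`.
#' @param srLevels training-set percentages (default `c(50, 60, 70, 80)`).
#' @param balanceReps,sampleReps,splitReps repetition counts (default 5
#'   each, giving 125 models per cell; the subsampling loop collapses to a
#'   single iteration at `ns = "total"`, giving 25).
#' @param cvFolds stratified cross-validation folds (default 5).
#' @param algorithms algorithm names, see [mcbenchAlgorithms()].
#' @param algorithmSettings named list of per-algorithm setting overrides,
#'   passed through to [trainAndScore()].
#' @param stratified stratify subsampling/splitting by class (default TRUE).
#' @param masterSeed integer master seed.
#' @return A \linkS4class{GridConfig}.
#' @export
GridConfig <- function(nsLevels = c("100", "500", "1000", "total"),
                       srLevels = c(50, 60, 70, 80),
                       balanceReps = 5L, sampleReps = 5L, splitReps = 5L,
                       cvFolds = 5L, algorithms = mcbenchAlgorithms(),
                       algorithmSettings = list(), stratified = TRUE,
                       masterSeed = 1L) {
    new("GridConfig", nsLevels = as.character(nsLevels),
        srLevels = as.numeric(srLevels),
        balanceReps = as.integer(balanceReps),
        sampleReps = as.integer(sampleReps),
        splitReps = as.integer(splitReps),
        cvFolds = as.integer(cvFolds),
        algorithms = as.character(algorithms),
        algorithmSettings = algorithmSettings,
        stratified = isTRUE(stratified),
        masterSeed = as.integer(masterSeed))
}

setMethod("show", "GridConfig", function(object) {
    cat("GridConfig:", length(object@algorithms), "algorithm(s) x",
        length(object@nsLevels), "NS level(s) x",
        length(object@srLevels), "SR level(s)\n")
    cat("reps (balance x sample x split):", object@balanceReps, "x",
        object@sampleReps, "x", object@splitReps,
        "| CV folds:", object@cvFolds,
        "| master seed:", object@masterSeed, "\n")
})

#' Equal-balance undersampling
#'
#' Reduces every class to the size of the smallest class by drawing rows
#' uniformly without replacement; the minority class passes through intact.
#'
#' @param x a \linkS4class{DescriptorSet} with at least two nonempty
#'   classes.
#' @param seed integer.
#' @return A balanced \linkS4class{DescriptorSet}.
#' @export
balanceDataset <- function(x, seed = 1L) {
    lab <- classLabels(x)
    counts <- table(lab)
    if (length(counts) < 2L || any(counts == 0L))
        stop("balancing needs at least 2 nonempty classes")
    m <- min(counts)
    keep <- withSeed(seed, {
        unlist(lapply(levels(lab), function(cl) {
            idx <- which(lab == cl)
            if (length(idx) > m) sort(sample(idx, m)) else idx
        }), use.names = FALSE)
    })
    subsetSamples(x, sort(keep))
}

#' Subsample to a fixed dataset size
#'
#' Draws exactly `ns` rows, allocated as equally as possible across the
#' classes (remainder classes chosen by a seeded draw) when
#' `stratified = TRUE`, or uniformly otherwise.  The sentinel
#' `ns = "total"` returns the input unchanged.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @param ns target size (integer or `"total"`).
#' @param seed integer.
#' @param stratified logical.
#' @return A \linkS4class{DescriptorSet} with `ns` rows.
#' @export
subsampleDataset <- function(x, ns, seed = 1L, stratified = TRUE) {
    if (identical(as.character(ns), "total")) return(x)
    ns <- as.integer(ns)
    lab <- classLabels(x)
    N <- length(lab)
    if (ns > N) stop("ns (", ns, ") exceeds available rows (", N, ")")
    if (!stratified) {
        keep <- withSeed(childSeed(seed, 1L), sort(sample.int(N, ns)))
        return(subsetSamples(x, keep))
    }
    K <- nlevels(lab)
    alloc <- largestRemainder(ns, rep(1, K), childSeed(seed, 2L))
    counts <- tabulate(lab, K)
    if (any(alloc > counts))
        stop("class too small for stratified subsample of ", ns)
    keep <- withSeed(childSeed(seed, 3L), {
        unlist(lapply(seq_len(K), function(k) {
            sort(sample(which(lab == levels(lab)[k]), alloc[k]))
        }), use.names = FALSE)
    })
    subsetSamples(x, sort(keep))
}

#' Stratified train/test split
#'
#' Assigns `round(sr/100 * N)` rows to the training set.  Under
#' stratification the training rows are allocated across classes by the
#' largest-remainder rule (remainder ties broken by seed), so class
#' proportions are preserved as exactly as integer counts allow.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @param sr training percentage in (0, 100).
#' @param seed integer.
#' @param stratified logical.
#' @param minPerClass minimum training rows required per class (e.g. the CV
#'   fold count); violation raises a degenerate-split error.
#' @return List with `train` and `test` \linkS4class{DescriptorSet}s
#'   forming a disjoint partition of the input rows.
#' @export
splitTrainTest <- function(x, sr, seed = 1L, stratified = TRUE,
                           minPerClass = 1L) {
    stopifnot(sr > 0, sr < 100)
    lab <- classLabels(x)
    N <- length(lab)
    nTrain <- round(sr / 100 * N)
    if (stratified) {
        counts <- tabulate(lab, nlevels(lab))
        alloc <- largestRemainder(nTrain, counts, childSeed(seed, 4L))
        if (any(alloc < minPerClass) || any(counts - alloc < 1L))
            stop("degenerate split: sr = ", sr, ", class counts ",
                 paste(counts, collapse = "/"), " leave a class with fewer ",
                 "than ", minPerClass, " training or 1 test row(s)")
        trainIdx <- withSeed(childSeed(seed, 5L), {
            unlist(lapply(seq_len(nlevels(lab)), function(k) {
                sample(which(lab == levels(lab)[k]), alloc[k])
            }), use.names = FALSE)
        })
    } else {
        trainIdx <- withSeed(childSeed(seed, 5L), sample.int(N, nTrain))
    }
    trainIdx <- sort(trainIdx)
    list(train = subsetSamples(x, trainIdx),
         test = subsetSamples(x, setdiff(seq_len(N), trainIdx)))
}

# stratified fold assignment: within each class, a seeded permutation is
# dealt round-robin over folds
stratifiedFolds <- function(labels, folds, seed) {
    assign <- integer(length(labels))
    withSeed(seed, {
        for (cl in levels(labels)) {
            idx <- which(labels == cl)
            assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
    })
    assign
}

# pooled out-of-fold predictions for one model's training table
cvPredict <- function(algorithm, train, folds, seed, settings) {
    lab <- classLabels(train)
    fold <- stratifiedFolds(lab, folds, childSeed(seed, 11L))
    lev <- levels(lab)
    n <- length(lab)
    scores <- matrix(NA_real_, n, length(lev), dimnames = list(NULL, lev))
    predicted <- character(n)
    for (f in seq_len(folds)) {
        hold <- which(fold == f)
        p <- trainAndScore(algorithm, subsetSamples(train, -hold),
                           subsetSamples(train, hold),
                           seed = childSeed(seed, 12L, f),
                           settings = settings)
        scores[hold, ] <- p@classScores[, lev]
        predicted[hold] <- as.character(p@predictedLabels)
    }
    PredictionSet(lab, factor(predicted, levels = lev), scores,
                  classLevels = lev)
}

#' Run the factorial benchmarking grid
#'
#' Executes the nested experiment of the harness: for every balance
#' repetition the input is rebalanced, for every (dataset size, sample
#' repetition) a stratified subsample is drawn (the sample loop collapses
#' at `ns = "total"`), for every (split ratio, split repetition) a
#' stratified train/test split is made, and every algorithm is fitted once
#' per split.  Each model is scored twice with the 25-parameter battery:
#' on pooled out-of-fold predictions of a `cvFolds`-fold stratified CV of
#' its training part (`Split = "CV"`) and on the held-out test part
#' (`Split = "test"`).  With default repetitions this yields 125 models --
#' 250 records -- per (algorithm, non-total NS, SR) cell.  Every stage seed
#' derives deterministically from `masterSeed`.  A failing cell is recorded
#' in the `failures` slot and the grid continues.
#'
#' @param x a \linkS4class{DescriptorSet} (typically z-scored).
#' @param config a \linkS4class{GridConfig}.
#' @param metricConfig a \linkS4class{MetricConfig}.
#' @param verbose print one line per model group.
#' @return A \linkS4class{BenchmarkResults}.
#' @export
runGrid <- function(x, config = GridConfig(), metricConfig = MetricConfig(),
                    verbose = FALSE) {
    methods::validObject(config)
    master <- config@masterSeed
    rows <- list()
    fails <- list()
    ri <- 0L
    for (b in seq_len(config@balanceReps)) {
        balanced <- balanceDataset(x, seed = childSeed(master, 1L, b))
        for (nsIdx in seq_along(config@nsLevels)) {
            ns <- config@nsLevels[nsIdx]
            nSampleReps <- if (identical(ns, "total")) 1L else config@sampleReps
            for (s in seq_len(nSampleReps)) {
                sub <- tryCatch(
                    subsampleDataset(balanced, ns,
                                     seed = childSeed(master, 2L, b, nsIdx, s),
                                     stratified = config@stratified),
                    error = function(e) e)
                if (inherits(sub, "error")) {
                    fails[[length(fails) + 1L]] <- data.frame(
                        ML = NA, SR = NA, NS = ns, balance_rep = b,
                        sample_rep = s, split_rep = NA,
                        reason = conditionMessage(sub))
                    next
                }
                for (sr in config@srLevels) {
                    for (p in seq_len(config@splitReps)) {
                        seedSp <- childSeed(master, 3L, b, nsIdx, s,
                                            round(sr), p)
                        sp <- tryCatch(
                            splitTrainTest(sub, sr, seed = seedSp,
                                           stratified = config@stratified,
                                           minPerClass = config@cvFolds),
                            error = function(e) e)
                        if (inherits(sp, "error")) {
                            fails[[length(fails) + 1L]] <- data.frame(
                                ML = NA, SR = sr, NS = ns, balance_rep = b,
                                sample_rep = s, split_rep = p,
                                reason = conditionMessage(sp))
                            next
                        }
                        for (alg in config@algorithms) {
                            st <- config@algorithmSettings[[alg]]
                            if (is.null(st)) st <- list()
                            seedM <- childSeed(master, 4L, b, nsIdx, s,
                                               round(sr), p,
                                               match(alg, mcbenchAlgorithms()))
                            rec <- tryCatch({
                                pcv <- cvPredict(alg, sp$train,
                                                 config@cvFolds, seedM, st)
                                pte <- trainAndScore(alg, sp$train, sp$test,
                                                     seed = childSeed(seedM, 13L),
                                                     settings = st)
                                rbind(
                                    data.frame(ML = alg, SR = sr, NS = ns,
                                               balance_rep = b, sample_rep = s,
                                               split_rep = p, Split = "CV",
                                               t(metricBattery(pcv, metricConfig))),
                                    data.frame(ML = alg, SR = sr, NS = ns,
                                               balance_rep = b, sample_rep = s,
                                               split_rep = p, Split = "test",
                                               t(metricBattery(pte, metricConfig))))
                            }, error = function(e) e)
                            if (inherits(rec, "error")) {
                                fails[[length(fails) + 1L]] <- data.frame(
                                    ML = alg, SR = sr, NS = ns,
                                    balance_rep = b, sample_rep = s,
                                    split_rep = p,
                                    reason = conditionMessage(rec))
                            } else {
                                ri <- ri + 1L
                                rows[[ri]] <- rec
                            }
                        }
                    }
                    if (verbose)
                        message(sprintf("balance %d | NS %s rep %d | SR %g: done",
                                        b, ns, s, sr))
                }
            }
        }
    }
    res <- if (ri > 0L) do.call(rbind, rows) else
        stop("every cell of the grid failed")
    rownames(res) <- NULL
    failDf <- if (length(fails)) do.call(rbind, fails) else
        data.frame(ML = character(), SR = numeric(), NS = character(),
                   balance_rep = integer(), sample_rep = integer(),
                   split_rep = integer(), reason = character())
    new("BenchmarkResults", results = res, config = config,
        provenance = list(masterSeed = master,
                          configHash = sum(utf8ToInt(paste(
                              utils::capture.output(show(config)),
                              collapse = ""))),
                          timestamp = format(Sys.time(), "%Y-%m-%d")),
        failures = failDf, normalized = FALSE)
}

#' @rdname resultsTable
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' Access the long-format results of a benchmark run
#'
#' @param x a \linkS4class{BenchmarkResults}.
#' @return data.frame with columns ML, SR, NS, balance_rep, sample_rep,
#'   split_rep, Split, then the 25 metric columns.
#' @export
setMethod("resultsTable", "BenchmarkResults", function(x) x@results)

setMethod("show", "BenchmarkResults", function(object) {
    r <- object@results
    cat("BenchmarkResults:", nrow(r), "records (",
        nrow(r[r$Split == "CV", ]), "CV /", nrow(r[r$Split == "test", ]),
        "test ) |", nrow(object@failures), "failed cell(s)\n")
    cat("ML:", paste(unique(r$ML), collapse = ", "),
        "| NS:", paste(unique(r$NS), collapse = ", "),
        "| SR:", paste(unique(r$SR), collapse = ", "), "\n")
    if (object@normalized) cat("metric columns Euclidean-normalized\n")
})

#' Euclidean column normalization of the metric columns
#'
#' Divides each of the 25 metric columns by its Euclidean norm over the
#' rows analyzed together, so that metrics of very different scales (e.g.
#' DOR vs AUC) become comparable before ANOVA and SRD.  All-zero columns
#' are left as zeros with a message.
#'
#' @param x a \linkS4class{BenchmarkResults}, or a data.frame/matrix whose
#'   numeric columns are to be normalized (e.g. several merged result
#'   tables, which the joint-normalization convention requires to be
#'   normalized together).
#' @param columns columns to normalize; defaults to [metricNames()] when
#'   present, otherwise all numeric columns.
#' @return Same class as `x`, with unit-Euclidean-norm columns.
#' @export
normalizeEuclidean <- function(x, columns = NULL) {
    if (is(x, "BenchmarkResults")) {
        x@results <- normalizeEuclidean(x@results, columns = columns)
        x@normalized <- TRUE
        return(x)
    }
    df <- as.data.frame(x)
    if (is.null(columns)) {
        columns <- intersect(metricNames(), colnames(df))
        if (!length(columns))
            columns <- colnames(df)[vapply(df, is.numeric, logical(1))]
    }
    for (cn in columns) {
        nrm <- sqrt(sum(df[[cn]]^2))
        if (nrm == 0) {
            message("column '", cn, "' is all zeros; left unnormalized")
        } else {
            df[[cn]] <- df[[cn]] / nrm
        }
    }
    if (is.matrix(x)) as.matrix(df) else df
}

#' Write / read benchmark results as CSV
#'
#' @param x a \linkS4class{BenchmarkResults} or its results data.frame.
#' @param path file path.
#' @return `writeResultsCSV()` returns `path` invisibly;
#'   `readResultsCSV()` the results data.frame.
#' @export
writeResultsCSV <- function(x, path) {
    df <- if (is(x, "BenchmarkResults")) resultsTable(x) else x
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeResultsCSV
#' @export
readResultsCSV <- function(path) {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = c(NS = "character"))
}
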