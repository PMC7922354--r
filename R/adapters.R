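#' Supported classifier families
#'
#' @return Character vector of algorithm names accepted by
#'   [trainAndScore()] and [GridConfig()].
#' @export
mcbenchAlgorithms <- function() c("XGBoost", "NB", "SVM", "NN", "PNN")

defaultSettings <- function(name) {
    switch(name,
        XGBoost = list(nrounds = 50, max_depth = 4, eta = 0.3,
                       subsample = 1, colsample_bytree = 1, nthread = 1),
        NB = list(laplace = 0),
        SVM = list(kernel = "radial", cost = 1),
        NN = list(size = 5, decay = 0.1, maxit = 150),
        PNN = list(bandwidth = NA_real_),  # NA -> median-distance default
        stop("unknown algorithm: ", name))
}

#' Train a classifier and score an evaluation set
#'
#' Uniform contract over the five algorithm families of the benchmark:
#' gradient-boosted trees (`"XGBoost"`, via \pkg{xgboost} with softprob
#' output), Gaussian naive Bayes (`"NB"`, via \pkg{e1071}), RBF-kernel
#' support vector machine with probability scores (`"SVM"`, via
#' \pkg{e1071}), a single-hidden-layer backpropagation perceptron (`"NN"`,
#' via \pkg{nnet}), and a Parzen/Gaussian-kernel probabilistic neural
#' network (`"PNN"`, implemented here: the class score is the log of the
#' mean Gaussian kernel density of that class's training points at the
#' query, with a shared bandwidth defaulting to the median pairwise
#' training distance divided by sqrt(K)).  All algorithms run at fixed
#' default settings -- this harness deliberately performs no feature
#' selection or hyperparameter optimization, so that factor effects are
#' compared on an equal footing.
#'
#' @param algorithm one of [mcbenchAlgorithms()].
#' @param train,eval \linkS4class{DescriptorSet}s sharing descriptor
#'   columns; `train` must contain at least two classes.
#' @param seed integer; the fit is deterministic given it.
#' @param settings named list of overrides merged over the defaults.
#' @return A \linkS4class{PredictionSet} for the rows of `eval`, with the
#'   predicted label equal to the argmax of the score row.
#' @examples
#' x <- generateDataset(SyntheticSpec(nPerClass = 40L, classSeparation = 6))
#' sp <- splitTrainTest(zscoreStandardize(x), sr = 70, seed = 1)
#' p <- trainAndScore("NB", sp$train, sp$test, seed = 1)
#' mean(p@trueLabels == p@predictedLabels)
#' @export
trainAndScore <- function(algorithm, train, eval, seed = 1L,
                          settings = list()) {
    algorithm <- match.arg(algorithm, mcbenchAlgorithms())
    cfg <- utils::modifyList(defaultSettings(algorithm), settings)
    xtr <- descriptorMatrix(train)
    xev <- descriptorMatrix(eval)
    if (!identical(colnames(xtr), colnames(xev)))
        stop("train and eval descriptor columns differ")
    ytr <- classLabels(train)
    if (nlevels(ytr) < 2L)
        stop("training set must contain at least two classes")
    lev <- levels(ytr)

    scores <- withSeed(childSeed(seed, match(algorithm, mcbenchAlgorithms())),
        switch(algorithm,
            XGBoost = fitXGBoost(xtr, ytr, xev, cfg),
            NB = fitNB(xtr, ytr, xev, cfg),
            SVM = fitSVM(xtr, ytr, xev, cfg),
            NN = fitNN(xtr, ytr, xev, cfg),
            PNN = fitPNN(xtr, ytr, xev, cfg)))
    colnames(scores) <- lev
    scores[!is.finite(scores)] <- min(scores[is.finite(scores)], 0)
    predicted <- lev[max.col(scores, ties.method = "first")]
    yev <- factor(classLabels(eval), levels = lev)
    PredictionSet(yev, factor(predicted, levels = lev), scores,
                  classLevels = lev)
}

fitXGBoost <- function(xtr, ytr, xev, cfg) {
    K <- nlevels(ytr)
    dtr <- xgboost::xgb.DMatrix(xtr, label = as.integer(ytr) - 1L)
    params <- c(list(objective = "multi:softprob", num_class = K,
                     eval_metric = "mlogloss"),
                cfg[setdiff(names(cfg), "nrounds")])
    fit <- xgboost::xgb.train(params = params, data = dtr,
                              nrounds = cfg$nrounds, verbose = 0)
    pr <- stats::predict(fit, xgboost::xgb.DMatrix(xev))
    if (is.matrix(pr)) pr else matrix(pr, ncol = K, byrow = TRUE)
}

fitNB <- function(xtr, ytr, xev, cfg) {
    fit <- e1071::naiveBayes(xtr, ytr, laplace = cfg$laplace)
    # log-space posterior: raw products of ~2000 densities underflow
    prior <- fit$apriori / sum(fit$apriori)
    lp <- vapply(seq_along(fit$tables), function(j) {
        tab <- fit$tables[[j]]          # K x 2: mean, sd per class
        sdv <- pmax(tab[, 2], 1e-3)
        vapply(seq_len(nrow(tab)), function(k) {
            stats::dnorm(xev[, j], tab[k, 1], sdv[k], log = TRUE)
        }, numeric(nrow(xev)))
    }, matrix(0, nrow(xev), nrow(fit$tables[[1]])))
    rowSums(lp, dims = 2) + rep(log(prior), each = nrow(xev))
}

fitSVM <- function(xtr, ytr, xev, cfg) {
    fit <- e1071::svm(xtr, ytr, kernel = cfg$kernel, cost = cfg$cost,
                      probability = TRUE)
    pr <- attr(stats::predict(fit, xev, probability = TRUE), "probabilities")
    pr[, levels(ytr), drop = FALSE]
}

fitNN <- function(xtr, ytr, xev, cfg) {
    ymat <- nnet::class.ind(ytr)
    fit <- nnet::nnet(xtr, ymat, size = cfg$size, decay = cfg$decay,
                      maxit = cfg$maxit, softmax = TRUE, trace = FALSE,
                      MaxNWts = 1e5)
    pr <- stats::predict(fit, xev)
    pr[, levels(ytr), drop = FALSE]
}

fitPNN <- function(xtr, ytr, xev, cfg) {
    h <- cfg$bandwidth
    if (is.na(h)) {
        n <- nrow(xtr)
        idx <- if (n > 200) sample.int(n, 200) else seq_len(n)
        h <- stats::median(stats::dist(xtr[idx, , drop = FALSE])) /
            sqrt(nlevels(ytr))
    }
    if (h <= 0) h <- 1e-6
    # squared distances eval x train
    d2 <- outer(rowSums(xev^2), rowSums(xtr^2), "+") - 2 * xev %*% t(xtr)
    d2[d2 < 0] <- 0
    lk <- -d2 / (2 * h^2)
    vapply(levels(ytr), function(cl) {
        cols <- which(ytr == cl)
        apply(lk[, cols, drop = FALSE], 1, logSumExp) - log(length(cols))
    }, numeric(nrow(xev)))
}
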