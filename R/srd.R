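#' Theoretical maximum of the Sum of Ranking Differences
#'
#' The largest footrule distance between two rankings of `n` objects,
#' attained by the reversal permutation: `n^2/2` for even `n` and
#' `(n^2 - 1)/2` for odd `n`.  Used to express SRD on the percent scale.
#'
#' @param n number of ranked objects (>= 2).
#' @return The maximum SRD value.
#' @export
maxSRD <- function(n) {
    stopifnot(n >= 2)
    ifelse(n %% 2 == 0, n^2 / 2, (n^2 - 1) / 2)
}

buildReference <- function(mat, reference) {
    if (is.numeric(reference)) {
        if (length(reference) != nrow(mat))
            stop("explicit reference must have one value per row")
        return(reference)
    }
    switch(match.arg(reference, c("rowmax", "rowmin", "rowmean")),
           rowmax = apply(mat, 1, max),
           rowmin = apply(mat, 1, min),
           rowmean = rowMeans(mat))
}

#' Sum of Ranking Differences
#'
#' Every column of the input matrix and the reference vector are rank
#' transformed (ascending, fractional ranks on ties); the SRD of a column
#' is the sum over rows of the absolute differences between its ranks and
#' the reference ranks.  A column whose ranking agrees with the reference
#' scores 0; larger values mean greater disagreement.  In this package's
#' headline use the rows are the 25 performance parameters, the columns the
#' train/test split-ratio settings, and the reference the row maximum -- an
#' ideal setting that maximizes every performance parameter.
#'
#' @param mat numeric matrix, objects in rows (n >= 2), systems in columns.
#' @param reference `"rowmax"` (default), `"rowmin"`, `"rowmean"`, or an
#'   explicit numeric vector of length `nrow(mat)`.
#' @return Named numeric vector of raw SRD values, one per column
#'   (integer- or half-valued).
#' @examples
#' m <- cbind(ideal = 1:4, reversed = 4:1)
#' computeSRD(m, reference = "rowmax")
#' @export
computeSRD <- function(mat, reference = "rowmax") {
    mat <- as.matrix(mat)
    if (nrow(mat) < 2L) stop("SRD needs at least 2 rows")
    if (!all(is.finite(mat))) stop("SRD input must be finite")
    refRank <- rank(buildReference(mat, reference), ties.method = "average")
    out <- apply(mat, 2, function(col) {
        sum(abs(rank(col, ties.method = "average") - refRank))
    })
    if (is.null(names(out)))
        names(out) <- sprintf("col_%d", seq_len(ncol(mat)))
    out
}

# Exact distribution of the footrule distance between the identity and a
# uniformly random permutation of n items, by dynamic programming over the
# set of already-used ranks (positions filled in order).
exactFootruleDistribution <- function(n) {
    mx <- maxSRD(n)
    nStates <- bitwShiftL(1L, n)
    counts <- vector("list", nStates)
    counts[[1L]] <- c(1, numeric(mx))        # counts[value + 1]
    popcount <- function(m) sum(bitwAnd(bitwShiftR(m, 0:(n - 1L)), 1L))
    pops <- vapply(0:(nStates - 1L), popcount, numeric(1))
    for (mask in 0:(nStates - 2L)) {
        cm <- counts[[mask + 1L]]
        if (is.null(cm)) next
        pos <- pops[mask + 1L] + 1L          # next position to fill
        for (r in seq_len(n)) {
            bit <- bitwShiftL(1L, r - 1L)
            if (bitwAnd(mask, bit) != 0L) next
            d <- abs(r - pos)
            nm <- bitwOr(mask, bit) + 1L
            shifted <- c(numeric(d), cm[seq_len(mx + 1L - d)])
            counts[[nm]] <- if (is.null(counts[[nm]])) shifted
                            else counts[[nm]] + shifted
        }
    }
    total <- counts[[nStates]]
    vals <- which(total > 0) - 1L
    data.frame(srd = vals, probability = total[vals + 1L] / factorial(n))
}

#' CRRN null distribution of SRD under random ranking
#'
#' Comparison of Ranks by Random Numbers: the distribution of the SRD
#' between a fixed (tie-free) reference ranking and a uniformly random
#' permutation.  An observed column SRD below the 5% point of this
#' distribution ranks significantly better than random.  The exact
#' distribution is computed by dynamic programming for `n <= 10`; beyond
#' that a Monte Carlo sample is drawn.
#'
#' @param n number of ranked objects.
#' @param method `"auto"` (exact for `n <= 10`, else Monte Carlo),
#'   `"exact"`, or `"montecarlo"`.
#' @param draws Monte Carlo sample size (default 1e5).
#' @param seed integer, used only for Monte Carlo.
#' @return List with `distribution` (data.frame of `srd` and
#'   `probability`), `percentiles` (raw-scale 5%/50%/95% points),
#'   `percentilesPercent` (same on the percent scale), `mean`, and
#'   `method`.
#' @examples
#' crrnNull(3, method = "exact")$distribution
#' @export
crrnNull <- function(n, method = c("auto", "exact", "montecarlo"),
                     draws = 1e5, seed = 1L) {
    method <- match.arg(method)
    stopifnot(n >= 2)
    if (method == "auto")
        method <- if (n <= 10) "exact" else "montecarlo"
    if (method == "exact") {
        if (n > 10)
            stop("exact CRRN enumeration is limited to n <= 10; ",
                 "use method = 'montecarlo'")
        dist <- exactFootruleDistribution(n)
    } else {
        draws <- as.integer(draws)
        srd <- withSeed(seed, {
            perms <- matrix(0L, n, draws)
            for (j in seq_len(draws)) perms[, j] <- sample.int(n)
            colSums(abs(perms - seq_len(n)))
        })
        tab <- table(srd)
        dist <- data.frame(srd = as.numeric(names(tab)),
                           probability = as.numeric(tab) / draws)
    }
    cdf <- cumsum(dist$probability)
    q <- function(p) dist$srd[which(cdf >= p - 1e-12)[1]]
    pct <- c("5%" = q(0.05), "50%" = q(0.5), "95%" = q(0.95))
    list(distribution = dist,
         percentiles = pct,
         percentilesPercent = 100 * pct / maxSRD(n),
         mean = sum(dist$srd * dist$probability),
         method = method)
}

#' Cross-validated SRD
#'
#' The rows (objects) are partitioned into `folds` groups by a seeded
#' draw; for each fold the SRD of every column is recomputed on the rows
#' with that fold left out and rescaled to percent of the reduced-n
#' theoretical maximum.  The fold-level values quantify the stability of
#' the column ordering and feed a one-way ANOVA ([onewayAnova()]).
#'
#' @param mat numeric matrix as in [computeSRD()]; `nrow(mat) >= folds`.
#' @param folds number of folds (5 to 10 in the intended use).
#' @param seed integer.
#' @param reference as in [computeSRD()].
#' @return Numeric folds x columns matrix of SRD% values.
#' @export
srdCrossValidate <- function(mat, folds = 5L, seed = 1L,
                             reference = "rowmax") {
    mat <- as.matrix(mat)
    n <- nrow(mat)
    folds <- as.integer(folds)
    if (folds > n) stop("more folds than rows")
    if (folds < 2L) stop("at least 2 folds required")
    assign <- withSeed(childSeed(seed, 21L),
                       sample(rep_len(seq_len(folds), n)))
    ref <- if (is.numeric(reference)) reference else NULL
    out <- t(vapply(seq_len(folds), function(f) {
        keep <- assign != f
        sub <- mat[keep, , drop = FALSE]
        refSub <- if (is.null(ref)) reference else ref[keep]
        100 * computeSRD(sub, refSub) / maxSRD(nrow(sub))
    }, numeric(ncol(mat))))
    rownames(out) <- sprintf("fold_%d", seq_len(folds))
    out
}

#' Full SRD analysis with randomization and cross-validation
#'
#' Convenience wrapper producing a complete \linkS4class{SRDResult}:
#' per-column raw and percent SRD values via [computeSRD()], the CRRN
#' random-ranking percentiles via [crrnNull()], and fold-level
#' cross-validated SRD% via [srdCrossValidate()].
#'
#' @inheritParams computeSRD
#' @inheritParams srdCrossValidate
#' @param draws Monte Carlo draws for the null when `nrow(mat) > 10`.
#' @return An \linkS4class{SRDResult}.
#' @examples
#' m <- cbind(a = c(5, 4, 9, 2, 8), b = c(1, 2, 3, 4, 5))
#' srdAnalysis(m, folds = 3)
#' @export
srdAnalysis <- function(mat, reference = "rowmax", folds = 5L, seed = 1L,
                        draws = 1e5) {
    mat <- as.matrix(mat)
    raw <- computeSRD(mat, reference)
    n <- nrow(mat)
    null <- crrnNull(n, draws = draws, seed = childSeed(seed, 22L))
    cv <- srdCrossValidate(mat, folds = folds, seed = seed,
                           reference = reference)
    new("SRDResult",
        srdRaw = raw,
        srdPercent = 100 * raw / maxSRD(n),
        nObjects = as.integer(n),
        nullPercentiles = null$percentilesPercent,
        nullDistribution = null$distribution,
        cvValues = cv)
}

setMethod("show", "SRDResult", function(object) {
    cat("SRDResult over", object@nObjects, "objects x",
        length(object@srdRaw), "systems\n")
    print(round(rbind(`SRD raw` = object@srdRaw,
                      `SRD %` = object@srdPercent), 2))
    cat("CRRN random-ranking percentiles (SRD %): 5% =",
        round(object@nullPercentiles[1], 1), "| median =",
        round(object@nullPercentiles[2], 1), "| 95% =",
        round(object@nullPercentiles[3], 1), "\n")
    below <- names(object@srdRaw)[object@srdPercent < object@nullPercentiles[1]]
    if (length(below))
        cat("better than random ranking (below 5% point):",
            paste(below, collapse = ", "), "\n")
    if (nrow(object@cvValues))
        cat("cross-validated over", nrow(object@cvValues), "folds\n")
})
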