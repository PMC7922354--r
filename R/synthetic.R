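#' Construct a SyntheticSpec
#'
#' Defaults emulate the statistical shape of curated multiclass QSAR
#' descriptor tables: a few hundred to a few thousand samples, many
#' z-scored and partially collinear descriptors, and class-conditional
#' signal confined to a low-dimensional latent subspace so that held-out
#' performance grows with sample size rather than saturating immediately.
#'
#' @param nClasses number of classes K (>= 2).
#' @param nPerClass per-class sample counts; a scalar is recycled to K.
#'   The default is mildly imbalanced so that class balancing has work to do.
#' @param nDescriptors number of descriptor columns D.
#' @param nInformative number of columns carrying class signal.
#' @param classSeparation distance between latent class means, in latent
#'   noise SD units.  0 means no signal; around 3 gives the intermediate
#'   difficulty where performance depends visibly on sample size; 8 and
#'   above is near-separable.
#' @param latentDim dimension of the latent signal space.
#' @param descriptorNoiseSd additive per-column noise SD.
#' @param correlationStrength descriptor mixing strength in \[0, 1).
#' @param seed master seed.
#' @return A \linkS4class{SyntheticSpec}.
#' @seealso [generateDataset()]
#' @export
SyntheticSpec <- function(nClasses = 3L,
                          nPerClass = c(150L, 130L, 120L),
                          nDescriptors = 50L,
                          nInformative = 40L,
                          classSeparation = 3.2,
                          latentDim = 15L,
                          descriptorNoiseSd = 1,
                          correlationStrength = 0.5,
                          seed = 1L) {
    if (length(nPerClass) == 1L)
        nPerClass <- rep(nPerClass, nClasses)
    new("SyntheticSpec",
        nClasses = as.integer(nClasses),
        nPerClass = as.integer(nPerClass),
        nDescriptors = as.integer(nDescriptors),
        nInformative = as.integer(nInformative),
        classSeparation = as.numeric(classSeparation),
        latentDim = as.integer(latentDim),
        descriptorNoiseSd = as.numeric(descriptorNoiseSd),
        correlationStrength = as.numeric(correlationStrength),
        seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec: K =", object@nClasses,
        "| N =", sum(object@nPerClass),
        "| D =", object@nDescriptors,
        sprintf("(%d informative)", object@nInformative), "\n")
    cat("separation =", object@classSeparation,
        "| latentDim =", object@latentDim,
        "| noise SD =", object@descriptorNoiseSd,
        "| correlation =", object@correlationStrength,
        "| seed =", object@seed, "\n")
})

#' Generate a synthetic multiclass descriptor dataset
#'
#' Samples of class k are drawn in a `latentDim`-dimensional latent space as
#' Gaussians around class means placed `classSeparation` apart along
#' orthonormal directions.  The latent coordinates are embedded linearly
#' into the first `nInformative` descriptor columns, independent Gaussian
#' noise of SD `descriptorNoiseSd` is added, the remaining columns are pure
#' standard-normal noise, and finally all columns are mixed as
#' `X ((1 - rho) I + rho Q)` with `Q` a random orthogonal matrix and `rho`
#' the correlation strength, which spreads signal across collinear columns.
#' The result is deterministic given the spec seed.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return A \linkS4class{DescriptorSet} with `sum(nPerClass)` rows.
#' @examples
#' x <- generateDataset(SyntheticSpec(seed = 7))
#' x
#' @export
generateDataset <- function(spec) {
    methods::validObject(spec)
    K <- spec@nClasses
    N <- sum(spec@nPerClass)
    D <- spec@nDescriptors
    L <- spec@latentDim

    labels <- factor(rep(sprintf("class_%d", seq_len(K)), spec@nPerClass))

    # class means: orthonormal-ish latent directions scaled so pairwise
    # distances equal classSeparation (exact when L >= K)
    mu <- withSeed(childSeed(spec@seed, 1L), {
        G <- matrix(stats::rnorm(L * K), L, K)
        V <- qr.Q(qr(G))[, seq_len(min(L, K)), drop = FALSE]
        if (ncol(V) < K)   # L < K: reuse (normalized) random directions
            V <- cbind(V, G[, seq_len(K - ncol(V)), drop = FALSE] /
                          sqrt(colSums(G[, seq_len(K - ncol(V)), drop = FALSE]^2)))
        V * spec@classSeparation / sqrt(2)
    })

    Z <- withSeed(childSeed(spec@seed, 2L), {
        matrix(stats::rnorm(N * L), N, L) + t(mu)[as.integer(labels), , drop = FALSE]
    })

    W <- withSeed(childSeed(spec@seed, 3L), {
        matrix(stats::rnorm(L * spec@nInformative), L, spec@nInformative) / sqrt(L)
    })

    X <- withSeed(childSeed(spec@seed, 4L), {
        info <- Z %*% W +
            spec@descriptorNoiseSd * matrix(stats::rnorm(N * spec@nInformative),
                                            N, spec@nInformative)
        noise <- if (D > spec@nInformative)
            matrix(stats::rnorm(N * (D - spec@nInformative)),
                   N, D - spec@nInformative)
        else NULL
        cbind(info, noise)
    })

    rho <- spec@correlationStrength
    if (rho > 0) {
        Q <- withSeed(childSeed(spec@seed, 5L), {
            qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
        })
        X <- X %*% ((1 - rho) * diag(D) + rho * Q)
    }

    perm <- withSeed(childSeed(spec@seed, 6L), sample.int(N))
    DescriptorSet(X[perm, , drop = FALSE], labels = labels[perm],
                  metadata = list(generator = "mcbench synthetic",
                                  seed = spec@seed))
}

#' Standardize descriptor columns to z-scores
#'
#' Each descriptor column is centered and scaled to unit standard deviation
#' using the sample-SD (n - 1 denominator) convention, which is recorded in
#' the object metadata.  Near-constant columns (SD below `dropThreshold`
#' after centering) are dropped with a message when `drop = TRUE`, and raise
#' an error otherwise, since they cannot be scaled.
#'
#' @param x a \linkS4class{DescriptorSet}.
#' @param dropThreshold SD below which a column counts as near-constant.
#' @param drop drop near-constant columns (`TRUE`, default) or fail on them.
#' @return A standardized \linkS4class{DescriptorSet}; every retained column
#'   has mean 0 and sample SD 1 to within 1e-10.
#' @export
zscoreStandardize <- function(x, dropThreshold = 1e-8, drop = TRUE) {
    mat <- descriptorMatrix(x)
    if (nrow(mat) < 2L)
        stop("z-scoring needs at least two samples")
    mu <- colMeans(mat)
    sdv <- apply(mat, 2, stats::sd)
    bad <- sdv < dropThreshold
    if (any(bad)) {
        if (!drop)
            stop("near-constant descriptor column(s): ",
                 paste(colnames(mat)[bad], collapse = ", "))
        message("dropping ", sum(bad), " near-constant descriptor column(s): ",
                paste(colnames(mat)[bad], collapse = ", "))
        mat <- mat[, !bad, drop = FALSE]
        mu <- mu[!bad]
        sdv <- sdv[!bad]
    }
    if (ncol(mat) == 0L)
        stop("no descriptor columns left after dropping near-constant ones")
    mat <- sweep(sweep(mat, 2, mu), 2, sdv, "/")
    md <- S4Vectors::metadata(x)
    md$standardization <- "sample SD (n-1)"
    DescriptorSet(mat, labels = classLabels(x), sampleIds = sampleIds(x),
                  descriptorNames = colnames(mat), metadata = md)
}
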