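# Independent oracles used across the suite.  These deliberately use the
# slowest, most literal formulation of each quantity.

# AUC as explicit pairwise concordance (ties count one half)
bruteForceAUC <- function(scores, active) {
    a <- scores[active]
    i <- scores[!active]
    pairs <- outer(a, i, function(x, y) (x > y) + 0.5 * (x == y))
    mean(pairs)
}

# all permutations of 1..n (n small)
allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- allPermutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(k) {
        cbind(k, sub + (sub >= k))
    }))
}

# footrule distance of a permutation from the identity
footrule <- function(perm) sum(abs(perm - seq_along(perm)))

# enrichment factor by direct count, no ranking shortcuts
bruteForceEF <- function(scores, active, chi) {
    N <- length(scores)
    k <- ceiling(chi * N)
    top <- order(scores, decreasing = TRUE)[seq_len(k)]
    (sum(active[top]) / k) / (sum(active) / N)
}

# a small random PredictionSet with optional score ties
randomPredictionSet <- function(n, k = 3, tieProb = 0) {
    lev <- letters[seq_len(k)]
    truth <- factor(sample(lev, n, replace = TRUE), levels = lev)
    while (nlevels(droplevels(truth)) < 2) {
        truth <- factor(sample(lev, n, replace = TRUE), levels = lev)
    }
    sc <- matrix(stats::runif(n * k), n, k, dimnames = list(NULL, lev))
    if (tieProb > 0) {
        sc <- round(sc, 1)  # heavy ties
    }
    pred <- lev[max.col(sc, ties.method = "first")]
    PredictionSet(truth, factor(pred, levels = lev), sc, classLevels = lev)
}

# tiny labeled descriptor table without any signal
noiseDescriptorSet <- function(counts, d = 4, seed = 1) {
    n <- sum(counts)
    withr::with_seed(seed, {
        DescriptorSet(matrix(stats::rnorm(n * d), n, d),
                      labels = rep(sprintf("c%d", seq_along(counts)), counts))
    })
}
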