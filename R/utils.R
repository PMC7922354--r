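# Internal helpers: deterministic seed derivation and small numerics.

# Derive a child seed from a master seed and a stage path (integers).
# Counter-based mixing with a multiplicative hash modulo the Mersenne prime
# 2^31 - 1; exact in double arithmetic and always a valid R integer seed.
childSeed <- function(master, ...) {
    p <- 2147483647
    idx <- c(...)
    h <- (as.numeric(master) %% p)
    for (k in seq_along(idx)) {
        h <- (h * 48271 + as.numeric(idx[k]) + 1) %% p
        # second pass breaks linearity across stage positions
        h <- (h * 69621 + k) %% p
    }
    as.integer(h)
}

withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

# log(sum(exp(x))) without overflow; returns -Inf only for empty input
logSumExp <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
}

# largest-remainder allocation of `total` items proportionally to `weights`,
# with ties among remainders broken by a seeded shuffle
largestRemainder <- function(total, weights, seed) {
    target <- total * weights / sum(weights)
    base <- floor(target)
    rem <- target - base
    left <- total - sum(base)
    if (left > 0) {
        ord <- withSeed(seed, order(rem, sample.int(length(rem)),
                                    decreasing = TRUE))
        base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
    }
    as.integer(base)
}
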