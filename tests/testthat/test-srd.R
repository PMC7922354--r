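test_that("maxSRD matches brute-force enumeration over all permutations", {
    for (n in 2:7) {
        perms <- allPermutations(n)
        fr <- apply(perms, 1, footrule)
        expect_equal(maxSRD(n), max(fr), label = paste("n =", n))
    }
    expect_equal(maxSRD(25), 312)
    # the reversal permutation attains the bound
    expect_equal(footrule(25:1), 312)
})

test_that("computeSRD agrees with the direct footrule on permutation columns", {
    set.seed(12)
    for (n in 3:7) {
        perms <- allPermutations(n)
        pick <- perms[sample(nrow(perms), min(10, nrow(perms))), ,
                      drop = FALSE]
        mat <- t(pick) + 0  # columns are permutations of 1..n
        srd <- computeSRD(mat, reference = seq_len(n))
        expect_equal(unname(srd), apply(pick, 1, footrule),
                     label = paste("n =", n))
    }
})

test_that("worked SRD examples evaluate as derived", {
    # identical to the reference
    expect_equal(unname(computeSRD(cbind(x = c(2, 5, 9)),
                                   reference = c(1, 4, 7))), 0)
    # full reversal at n = 4 attains the brute-force maximum 8
    expect_equal(unname(computeSRD(cbind(x = 4:1), reference = 1:4)), 8)
    # constant column: fractional ranks (2,2,2) against (1,2,3)
    expect_equal(unname(computeSRD(cbind(x = c(5, 5, 5)),
                                   reference = 1:3)), 2)
    # row-maximum reference policy
    m <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
    expect_equal(unname(computeSRD(m, "rowmax")),
                 unname(computeSRD(m, reference = c(3, 2, 3))))
})

test_that("SRD is invariant under strictly monotone column transforms", {
    set.seed(21)
    for (rep in 1:10) {
        m <- matrix(stats::rnorm(8 * 3), 8, 3)
        expect_equal(computeSRD(exp(m), "rowmax"),
                     computeSRD(m, "rowmax"))
        expect_equal(unname(computeSRD(m^3, reference = m[, 1]^3)),
                     unname(computeSRD(m, reference = m[, 1])))
    }
})

test_that("SRD never exceeds the theoretical maximum and hits 0 on the reference", {
    set.seed(31)
    for (rep in 1:20) {
        n <- sample(3:12, 1)
        m <- matrix(stats::rnorm(n * 4), n, 4)
        srd <- computeSRD(cbind(m, ref = m[, 2]), reference = m[, 2])
        expect_true(all(srd <= maxSRD(n) + 1e-12))
        expect_equal(unname(srd["ref"]), 0)
    }
})

test_that("exact CRRN distributions match enumeration", {
    d2 <- crrnNull(2, method = "exact")$distribution
    expect_equal(d2$srd, c(0, 2))
    expect_equal(d2$probability, c(0.5, 0.5))

    d3 <- crrnNull(3, method = "exact")
    expect_equal(d3$distribution$srd, c(0, 2, 4))
    expect_equal(d3$distribution$probability, c(1, 2, 3) / 6)
    expect_equal(d3$mean, 8 / 3)

    # general n: the DP must reproduce the full factorial enumeration
    for (n in 4:7) {
        fr <- apply(allPermutations(n), 1, footrule)
        tab <- table(fr) / factorial(n)
        dn <- crrnNull(n, method = "exact")$distribution
        expect_equal(dn$srd, as.numeric(names(tab)))
        expect_equal(dn$probability, as.numeric(tab), label = paste("n =", n))
        expect_equal(sum(dn$probability), 1)
    }

    expect_error(crrnNull(12, method = "exact"), "n <= 10")
})

test_that("Monte Carlo CRRN converges to the exact distribution", {
    ex <- crrnNull(6, method = "exact")$distribution
    mc <- crrnNull(6, method = "montecarlo", draws = 2e4,
                   seed = 7)$distribution
    merged <- merge(ex, mc, by = "srd", all = TRUE)
    merged[is.na(merged)] <- 0
    tv <- sum(abs(merged$probability.x - merged$probability.y)) / 2
    expect_lt(tv, 0.03)
})

test_that("cross-validated SRD preserves structure across folds", {
    # all columns equal to the reference: every fold SRD = 0
    m <- cbind(a = 1:10, b = (1:10) * 2)
    cv <- srdCrossValidate(m, folds = 5, seed = 1, reference = "rowmax")
    expect_equal(dim(cv), c(5L, 2L))
    expect_true(all(cv == 0))

    # leave-out sets have n - n/folds rows: fold SRD is on the reduced scale
    m2 <- matrix(stats::rnorm(25 * 4), 25, 4)
    cv2 <- srdCrossValidate(m2, folds = 5, seed = 2)
    expect_true(all(cv2 >= 0 & cv2 <= 100))

    # a fully reversed column dominates an identical-to-reference column
    # in every fold
    n <- 6
    m3 <- cbind(good = 1:n, bad = n:1)
    cv3 <- srdCrossValidate(m3, folds = 3, seed = 3, reference = 1:n)
    expect_true(all(cv3[, "bad"] > cv3[, "good"]))

    expect_error(srdCrossValidate(m3, folds = 10), "more folds")
})

test_that("srdAnalysis assembles a consistent SRDResult", {
    set.seed(41)
    m <- matrix(stats::runif(25 * 4), 25, 4,
                dimnames = list(NULL, c("50", "60", "70", "80")))
    m[, "80"] <- m[, "80"] + 2   # dominant column, identical to row max
    res <- srdAnalysis(m, folds = 5, seed = 5, draws = 2e4)
    expect_equal(unname(res@srdRaw["80"]), 0)
    expect_equal(res@srdPercent, 100 * res@srdRaw / maxSRD(25))
    expect_equal(sum(res@nullDistribution$probability), 1, tolerance = 1e-9)
    # random rankings sit far above a dominant column
    expect_lt(res@srdPercent["80"], res@nullPercentiles[1])
})
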