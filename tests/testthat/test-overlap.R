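## small merged table builder with direct control over beta/se
mergedTable <- function(beta1, se1, beta2, se2, pos = NULL) {
    n <- length(beta1)
    if (is.null(pos)) pos <- seq_len(n) * 10000L
    data.frame(SNP = sprintf("s%d", seq_len(n)), CHR = "1", BP = pos,
               A1 = "A", A2 = "G", BETA1 = beta1, SE1 = se1, P1 = NA,
               BETA2 = beta2, SE2 = se2, P2 = NA, flipped = FALSE,
               stringsAsFactors = FALSE)
}

test_that("starred pruning metrics follow their defining formulas", {
    rule <- decisionRule(0.99, 1)           # theta = 99
    ## SNP1 weak/weak, SNP2 strong/strong (dual), SNP3 strong/weak
    m <- mergedTable(beta1 = c(0.02, 0.30, 0.30), se1 = 0.05,
                     beta2 = c(0.02, 0.30, 0.01), se2 = 0.05)
    mt <- computeOverlapMetrics(m, rule = rule, alpha = 1e-3)
    M <- attr(mt, "M")
    expect_equal(M, max(mt$log10Abf1, mt$log10Abf2))
    expect_identical(mt$dualAbf, c(FALSE, TRUE, FALSE))
    ## indicator off: abf* = max of the two ABFs
    expect_equal(mt$log10AbfStar[1], pmax(mt$log10Abf1, mt$log10Abf2)[1])
    expect_equal(mt$log10AbfStar[3], pmax(mt$log10Abf1, mt$log10Abf2)[3])
    ## indicator on: abf* = max + M on the natural scale
    expect_equal(10^mt$log10AbfStar[2],
                 10^pmax(mt$log10Abf1[2], mt$log10Abf2[2]) + 10^M,
                 tolerance = 1e-10)
    ## P*: dual-significant SNPs drop below zero by exactly 1
    expect_equal(mt$pStar[2], pmin(mt$p1, mt$p2)[2] - 1)
    expect_equal(mt$pStar[1], pmin(mt$p1, mt$p2)[1])
    expect_true(all(mt$pStar > -1 & mt$pStar <= 1))
    ## forced numeric example: p1 = 1e-5 below alpha in both -> p* ~ -0.99999
    z <- qnorm(c(1e-5, 1e-4) / 2)
    m2 <- mergedTable(beta1 = -z[1] * 0.05, se1 = 0.05,
                      beta2 = -z[2] * 0.05, se2 = 0.05)
    mt2 <- computeOverlapMetrics(m2, rule = rule, alpha = 1e-3)
    expect_equal(mt2$pStar, 1e-5 - 1, tolerance = 1e-6)
    expect_error(computeOverlapMetrics(m[0, ], rule = rule), "empty")
})

test_that("dual-threshold SNPs outrank every single-trait signal under ABF*", {
    rule <- decisionRule(0.99, 5)
    set.seed(21)
    m <- mergedTable(beta1 = rnorm(40, 0, 0.15), se1 = 0.05,
                     beta2 = rnorm(40, 0, 0.15), se2 = 0.05)
    mt <- computeOverlapMetrics(m, rule = rule, alpha = 1e-3)
    if (any(mt$dualAbf) && any(!mt$dualAbf))
        expect_gt(min(mt$log10AbfStar[mt$dualAbf]),
                  max(mt$log10AbfStar[!mt$dualAbf]))
})

test_that("greedy clumping: window, threshold, and brute-force agreement", {
    ## three linked SNPs within 100 kb: only the best survives
    ld3 <- data.frame(snpA = c("s1", "s1", "s2"), snpB = c("s2", "s3", "s3"),
                      r2 = 0.9)
    keep <- clumpSnps(c("s1", "s2", "s3"), rep("1", 3),
                      c(1e5, 1.5e5, 2e5), metric = c(2, 5, 1), ld = ld3)
    expect_identical(keep, "s2")
    ## same r2 but 600 kb apart: both retained
    ld2 <- data.frame(snpA = "s1", snpB = "s2", r2 = 0.9)
    keep2 <- clumpSnps(c("s1", "s2"), c("1", "1"), c(1e5, 7e5),
                       metric = c(1, 2), ld = ld2)
    expect_setequal(keep2, c("s1", "s2"))
    ## window inclusive at exactly windowBp; r2 strictly > threshold prunes
    keep3 <- clumpSnps(c("a", "b"), c("1", "1"), c(1L, 500001L),
                       metric = c(2, 1),
                       ld = data.frame(snpA = "a", snpB = "b", r2 = 0.5))
    expect_identical(keep3, "a")
    keep4 <- clumpSnps(c("a", "b"), c("1", "1"), c(1L, 1000L),
                       metric = c(2, 1),
                       ld = data.frame(snpA = "a", snpB = "b", r2 = 0.1))
    expect_setequal(keep4, c("a", "b"))   # r2 == threshold does not prune
    expect_error(clumpSnps("a", "1", NA, 1, ld2), "position")

    ## 50-SNP fixtures against the brute-force oracle
    for (seed in 1:5) {
        set.seed(seed)
        n <- 50
        snp <- sprintf("v%02d", 1:n)
        pos <- sort(sample.int(3e6, n))
        metric <- rnorm(n)
        pairs <- t(combn(n, 2))
        sel <- runif(nrow(pairs)) < 0.15
        ld <- data.frame(snpA = snp[pairs[sel, 1]], snpB = snp[pairs[sel, 2]],
                         r2 = runif(sum(sel)))
        got <- clumpSnps(snp, rep("1", n), pos, metric, ld)
        want <- bruteClump(snp, pos, metric, ld, 500000, 0.1)
        expect_identical(got, want)
        ## retained set is approximately independent
        for (i in seq_len(nrow(ld))) {
            a <- ld$snpA[i]; b <- ld$snpB[i]
            if (a %in% got && b %in% got && ld$r2[i] > 0.1)
                expect_gt(abs(pos[snp == a] - pos[snp == b]), 500000)
        }
    }
})

test_that("contingency counts classify on per-trait statistics only", {
    rule <- decisionRule(0.99, 1)
    ## (high,high) (high,low) (low,high) (low,low) by construction
    m <- mergedTable(beta1 = c(0.30, 0.30, 0.01, 0.01), se1 = 0.05,
                     beta2 = c(0.30, 0.01, 0.30, 0.01), se2 = 0.05)
    mt <- computeOverlapMetrics(m, rule = rule, alpha = 1e-3)
    cc <- buildContingency(mt, rule)
    expect_identical(cc, c(n11 = 1L, n10 = 1L, n01 = 1L, n00 = 1L))
    expect_identical(sum(cc), nrow(mt))
    ccP <- buildContingency(mt, rule, mode = "pvalue", alpha = 1e-3)
    expect_identical(ccP, c(n11 = 1L, n10 = 1L, n01 = 1L, n00 = 1L))
    ## all null
    m0 <- mergedTable(beta1 = rep(0.01, 5), se1 = 0.05,
                      beta2 = rep(0.01, 5), se2 = 0.05)
    cc0 <- buildContingency(computeOverlapMetrics(m0, rule = rule), rule)
    expect_identical(cc0[["n00"]], 5L)
    expect_identical(sum(cc0), 5L)
})

test_that("McNemar mid-P matches exhaustive enumeration and its invariants", {
    expect_equal(mcnemarMidP(1, 1), 1)
    expect_equal(mcnemarMidP(0, 5), 1 / 32)
    expect_equal(mcnemarMidP(0, 0), 1)
    ## full enumeration for every pair with n <= 20
    for (n10 in 0:20) for (n01 in 0:(20 - n10)) {
        expect_equal(mcnemarMidP(n10, n01), enumMidP(n10, n01),
                     tolerance = 1e-12)
    }
    ## symmetry and dominance by the exact conditional two-sided P, n <= 50
    for (n in c(1:10, 25, 50)) {
        for (k in 0:floor(n / 2)) {
            mid <- mcnemarMidP(k, n - k)
            expect_identical(mid, mcnemarMidP(n - k, k))
            exact2 <- 2 * pbinom(k, n, 0.5)
            expect_lte(mid, min(exact2, 1) + 1e-12)
        }
    }
    expect_gt(mcnemarMidP(0, 500), 0)   # clipped away from zero
})

test_that("signal ranking orders by min-ABF and max-P with stable ties", {
    rule <- decisionRule(0.99, 1)
    m <- mergedTable(beta1 = c(0.25, 0.20, 0.20), se1 = 0.05,
                     beta2 = c(0.30, 0.22, 0.22), se2 = 0.05)
    mt <- computeOverlapMetrics(m, rule = rule, alpha = 1e-3)
    rk <- rankSignals(mt)
    expect_identical(rk$SNP[rk$abfRank == 1], "s1")
    ## s2 and s3 tie on the statistics: position breaks the tie
    expect_lt(rk$abfRank[rk$SNP == "s2"], rk$abfRank[rk$SNP == "s3"])
    expect_equal(sort(rk$abfRank), 1:3)
    expect_equal(sort(rk$pRank), 1:3)
    one <- rankSignals(mt[1, ])
    expect_identical(one$abfRank, 1L)
    expect_identical(one$pRank, 1L)
})

test_that("full pipeline: recovery of planted signals and degenerate modes", {
    fx <- generateFixture(nBlocks = 8, blockSize = 7, nOverlapSignals = 5,
                          signalOr = 1.3, seed = 11)
    res <- runOverlap(fx$study1, fx$study2, fx$ld,
                      rule = decisionRule(0.99, 20), alpha = 1e-3)
    blockOf <- function(ids) sub("_.*", "", ids)
    hits <- blockOf(fx$truth$SNP) %in% blockOf(overlapSignals(res)$SNP[
        overlapSignals(res)$minLog10Abf > log10(4.95)])
    expect_gte(sum(hits), 4)
    expect_identical(sum(overlapCounts(res)$abf),
                     length(retainedSnps(res)$abf))
    ## every retained pair respects the LD contract
    for (m in names(retainedSnps(res))) {
        kept <- retainedSnps(res)[[m]]
        pos <- fx$study1$BP[match(kept, fx$study1$SNP)]
        for (i in seq_len(nrow(fx$ld))) {
            if (fx$ld$snpA[i] %in% kept && fx$ld$snpB[i] %in% kept &&
                fx$ld$r2[i] > 0.1) {
                pa <- pos[kept == fx$ld$snpA[i]]
                pb <- pos[kept == fx$ld$snpB[i]]
                expect_gt(abs(pa - pb), 500000)
            }
        }
    }
    ## alpha = 1 makes every SNP significant in P mode: n11 = total
    resAll <- runOverlap(fx$study1, fx$study2, fx$ld,
                         rule = decisionRule(0.99, 20), alpha = 1 - 1e-12,
                         mode = "pvalue")
    ccAll <- overlapCounts(resAll)$pvalue
    expect_identical(ccAll[["n11"]], sum(ccAll))
    ## swapping the traits transposes the discordant counts, same mid-P
    res12 <- runOverlap(fx$study1, fx$study2, fx$ld,
                        rule = decisionRule(0.99, 10), alpha = 1e-2)
    res21 <- runOverlap(fx$study2, fx$study1, fx$ld,
                        rule = decisionRule(0.99, 10), alpha = 1e-2)
    cc12 <- overlapCounts(res12)$abf; cc21 <- overlapCounts(res21)$abf
    expect_identical(cc12[["n10"]], cc21[["n01"]])
    expect_identical(cc12[["n01"]], cc21[["n10"]])
    expect_equal(overlapMidP(res12)[["abf"]], overlapMidP(res21)[["abf"]])
})
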