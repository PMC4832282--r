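## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths.

## Normal density ratio N(beta; 0, V+W) / N(beta; 0, V): the marginal
## likelihood ratio the approximate Bayes factor equals.
densityRatioAbf <- function(beta, V, W) {
    dnorm(beta, 0, sqrt(V + W)) / dnorm(beta, 0, sqrt(V))
}

## Brute-force greedy clumping over an explicit pairwise r2 matrix.
bruteClump <- function(snp, pos, metric, ld, windowBp, r2Threshold,
                       decreasing = TRUE) {
    lookupR2 <- function(a, b) {
        if (a == b) return(1)
        hit <- (ld$snpA == a & ld$snpB == b) | (ld$snpA == b & ld$snpB == a)
        if (any(hit)) ld$r2[which(hit)[1]] else 0
    }
    ord <- order(if (decreasing) -metric else metric, pos, snp)
    snp <- snp[ord]; pos <- pos[ord]
    kept <- character(0)
    while (length(snp)) {
        idx <- snp[1]; ipos <- pos[1]
        kept <- c(kept, idx)
        prune <- vapply(seq_along(snp), function(j) {
            abs(pos[j] - ipos) <= windowBp && lookupR2(idx, snp[j]) > r2Threshold
        }, logical(1))
        prune[1] <- TRUE
        snp <- snp[!prune]; pos <- pos[!prune]
    }
    kept
}

## Exhaustive-enumeration McNemar mid-P: sum the Binomial(n, 1/2) pmf term
## by term via choose(), no distribution functions.
enumMidP <- function(n10, n01) {
    n <- n10 + n01
    if (n == 0) return(1)
    k <- min(n10, n01)
    pmf <- choose(n, 0:n) / 2^n
    min(2 * sum(pmf[1:(k + 1)]) - pmf[k + 1], 1)
}
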