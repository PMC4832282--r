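#' Per-SNP two-trait overlap metrics
#'
#' From a merged two-study table (see [mergeStudies()]) computes, per SNP,
#' the per-trait ABFs and Wald P-values plus the two pruning metrics:
#' \deqn{ABF^* = \max(ABF_1, ABF_2) + M \cdot I\{ABF_1 > \theta
#'   \;and\; ABF_2 > \theta\},}
#' where `M` is the maximum ABF observed at any SNP for either trait over
#' the full merged set (computed once, before any pruning), and
#' \deqn{P^* = \min(P_1, P_2) - 1 \cdot I\{P_1 < \alpha \;and\;
#'   P_2 < \alpha\}.}
#' The boost terms force SNPs passing the threshold in both traits to
#' outrank every single-trait signal during LD clumping. ABFs are handled on
#' the log10 scale so large Wald statistics cannot overflow; `abfStar` is
#' reported as `log10AbfStar` via a stable log-sum.
#'
#' @param merged data.frame from [mergeStudies()].
#' @param prior an [AbfPrior-class].
#' @param rule a [DecisionRule-class] (`theta` for the ABF indicator).
#' @param alpha P-value threshold for the `P*` indicator; defaults to the
#'   rule's `alpha`.
#' @return the input with columns `log10Abf1`, `log10Abf2`, `p1`, `p2`,
#'   `log10AbfStar`, `pStar`, `dualAbf`, `dualP` appended; attribute `"M"`
#'   holds the global max log10 ABF.
#' @export
computeOverlapMetrics <- function(merged, prior = abfPrior(),
                                  rule = decisionRule(), alpha = NULL) {
    if (nrow(merged) == 0L) stop("empty merged input")
    if (is.null(alpha)) alpha <- rule@alpha
    labf1 <- computeAbf(merged$BETA1, merged$SE1^2, prior, log10 = TRUE)
    labf2 <- computeAbf(merged$BETA2, merged$SE2^2, prior, log10 = TRUE)
    p1 <- 2 * stats::pnorm(-abs(merged$BETA1) / merged$SE1)
    p2 <- 2 * stats::pnorm(-abs(merged$BETA2) / merged$SE2)
    M <- max(labf1, labf2)
    lth <- log(rule@theta) / log(10)
    dualAbf <- labf1 > lth & labf2 > lth
    mx <- pmax(labf1, labf2)
    ## log10(10^mx + 10^M) computed stably; indicator off keeps plain max
    labfStar <- ifelse(dualAbf, M + log1p(10^(mx - M)) / log(10), mx)
    dualP <- if (is.na(alpha)) rep(FALSE, length(p1)) else
        p1 < alpha & p2 < alpha
    out <- merged
    out$log10Abf1 <- labf1
    out$log10Abf2 <- labf2
    out$p1 <- p1
    out$p2 <- p2
    out$log10AbfStar <- labfStar
    out$pStar <- pmin(p1, p2) - as.numeric(dualP)
    out$dualAbf <- dualAbf
    out$dualP <- dualP
    attr(out, "M") <- M
    out
}

#' Greedy LD clumping to an approximately independent SNP set
#'
#' Index-SNP-driven clumping: the best remaining SNP by the supplied metric
#' becomes an index, and every SNP within `windowBp` of it (inclusive) on
#' the same chromosome with `r2 > r2Threshold` is pruned out; this repeats
#' until the list is exhausted. Pairs missing from the LD table are treated
#' as unlinked. Ties in the metric are broken by position, then id, for
#' run-to-run determinism.
#'
#' @param snp,chr,pos SNP ids, chromosomes, 1-based bp positions.
#' @param metric values ordering the SNPs (best first under `decreasing`).
#' @param ld data.frame `snpA snpB r2` (see [readLdTable()]).
#' @param windowBp clumping window, inclusive at exactly `windowBp`.
#' @param r2Threshold prune when `r2` strictly exceeds this.
#' @param decreasing `TRUE` to treat large metric values as best (ABF*),
#'   `FALSE` for small-is-best (P*).
#' @return character vector of retained SNP ids.
#' @export
clumpSnps <- function(snp, chr, pos, metric, ld, windowBp = 500000,
                      r2Threshold = 0.1, decreasing = TRUE) {
    if (any(is.na(pos))) stop("SNP(s) missing position")
    n <- length(snp)
    stopifnot(length(chr) == n, length(pos) == n, length(metric) == n)
    ## symmetric r2 lookup keyed "a|b"
    r2map <- new.env(hash = TRUE, parent = emptyenv())
    if (nrow(ld)) {
        for (i in seq_len(nrow(ld))) {
            assign(paste(ld$snpA[i], ld$snpB[i], sep = "\r"), ld$r2[i], r2map)
            assign(paste(ld$snpB[i], ld$snpA[i], sep = "\r"), ld$r2[i], r2map)
        }
    }
    ord <- order(if (decreasing) -metric else metric, pos, snp)
    alive <- rep(TRUE, n)
    retained <- character(0)
    for (i in ord) {
        if (!alive[i]) next
        retained <- c(retained, snp[i])
        alive[i] <- FALSE
        cand <- which(alive & chr == chr[i] & abs(pos - pos[i]) <= windowBp)
        for (j in cand) {
            key <- paste(snp[i], snp[j], sep = "\r")
            r2 <- if (snp[i] == snp[j]) 1
                  else if (exists(key, r2map, inherits = FALSE))
                      get(key, r2map) else 0
            if (r2 > r2Threshold) alive[j] <- FALSE
        }
    }
    retained
}

#' Matched-pair contingency counts of high/low evidence
#'
#' Classifies each (pruned) SNP by the individual per-trait statistics —
#' never the starred pruning metrics — into the 2x2 matched-pair table:
#' `n11` both traits high-evidence, `n10`/`n01` discordant, `n00` neither.
#'
#' @param metrics data.frame from [computeOverlapMetrics()], usually
#'   restricted to the LD-pruned SNP set.
#' @param rule a [DecisionRule-class].
#' @param mode `"abf"` (threshold `theta` on the ABFs) or `"pvalue"`
#'   (threshold `alpha` on the P-values).
#' @param alpha overrides the rule's `alpha` in P-value mode.
#' @return named integer vector `n11, n10, n01, n00`.
#' @export
buildContingency <- function(metrics, rule, mode = c("abf", "pvalue"),
                             alpha = NULL) {
    mode <- match.arg(mode)
    if (mode == "abf") {
        h1 <- classifyEvidence(metrics$log10Abf1, rule, "abf", log10 = TRUE)
        h2 <- classifyEvidence(metrics$log10Abf2, rule, "abf", log10 = TRUE)
    } else {
        r <- if (is.null(alpha)) rule else
            decisionRule(rule@pi0, rule@rCost, alpha = alpha)
        h1 <- classifyEvidence(metrics$p1, r, "pvalue")
        h2 <- classifyEvidence(metrics$p2, r, "pvalue")
    }
    c(n11 = sum(h1 & h2), n10 = sum(h1 & !h2), n01 = sum(!h1 & h2),
      n00 = sum(!h1 & !h2))
}

#' McNemar mid-P test on discordant counts
#'
#' Two-sided mid-P value for equality of the discordant probabilities:
#' `2 * sum_{x=0}^{k} f(x | n) - f(k | n)` with `k = min(n10, n01)`,
#' `n = n10 + n01` and `f` the Binomial(n, 1/2) pmf — i.e. twice the exact
#' conditional one-sided P-value minus the boundary mass. The result is
#' clipped to (0, 1]; `n = 0` (no discordance, hence no evidence) returns 1.
#'
#' @param n10,n01 discordant counts (non-negative integers).
#' @return numeric(1) mid-P value in (0, 1].
#' @examples
#' mcnemarMidP(1, 1)   # 1
#' mcnemarMidP(0, 5)   # 1/32
#' @export
mcnemarMidP <- function(n10, n01) {
    stopifnot(n10 >= 0, n01 >= 0)
    n <- n10 + n01
    if (n == 0) return(1)
    k <- min(n10, n01)
    p <- 2 * stats::pbinom(k, n, 0.5) - stats::dbinom(k, n, 0.5)
    min(max(p, .Machine$double.xmin), 1)
}

#' Rank the pruned overlap signals
#'
#' Bayesian ranking orders SNPs by decreasing minimum per-trait ABF;
#' frequentist ranking by increasing maximum per-trait P-value. Both ranks
#' are reported per SNP, together with the min-ABF (log10) and max-P
#' summaries. Ties break by position then id.
#'
#' @param metrics pruned data.frame from [computeOverlapMetrics()].
#' @return data.frame sorted by `abfRank` with columns `SNP CHR BP abfRank
#'   pRank minLog10Abf maxP` plus the per-trait statistics.
#' @export
rankSignals <- function(metrics) {
    minLabf <- pmin(metrics$log10Abf1, metrics$log10Abf2)
    maxP <- pmax(metrics$p1, metrics$p2)
    oA <- order(-minLabf, metrics$BP, metrics$SNP)
    oP <- order(maxP, metrics$BP, metrics$SNP)
    abfRank <- pRank <- integer(nrow(metrics))
    abfRank[oA] <- seq_len(nrow(metrics))
    pRank[oP] <- seq_len(nrow(metrics))
    out <- data.frame(SNP = metrics$SNP, CHR = metrics$CHR, BP = metrics$BP,
                      abfRank = abfRank, pRank = pRank,
                      minLog10Abf = minLabf, maxP = maxP,
                      log10Abf1 = metrics$log10Abf1,
                      log10Abf2 = metrics$log10Abf2,
                      p1 = metrics$p1, p2 = metrics$p2,
                      stringsAsFactors = FALSE)
    out[order(out$abfRank), ]
}

## Re-clump the union of per-mode retained SNPs on the LD table, keeping the
## larger-ABF member of any linked pair, to reconcile the separately pruned
## ABF- and P-mode signal lists into one approximately independent set.
.reconcileUnion <- function(metrics, retainedList, ld, windowBp, r2Threshold) {
    ids <- unique(unlist(retainedList))
    sub <- metrics[match(ids, metrics$SNP), ]
    keep <- clumpSnps(sub$SNP, sub$CHR, sub$BP,
                      pmax(sub$log10Abf1, sub$log10Abf2), ld,
                      windowBp, r2Threshold, decreasing = TRUE)
    sub[match(keep, sub$SNP), ]
}

#' Run the full two-trait overlap analysis
#'
#' Executes the pipeline: merge the studies, compute per-trait ABFs and
#' P-values plus the `ABF*`/`P*` pruning metrics, LD-clump separately per
#' mode (by decreasing `ABF*`, by increasing `P*`), build the matched-pair
#' contingency table from the individual per-trait statistics on each pruned
#' set, test overlap enrichment with the McNemar mid-P test, and rank the
#' reconciled signal list.
#'
#' @param study1,study2 canonical summary data.frames ([readSummaryStats()]).
#' @param ld LD table data.frame ([readLdTable()]).
#' @param prior an [AbfPrior-class].
#' @param rule a [DecisionRule-class].
#' @param alpha P-value threshold for the frequentist mode (defaults to the
#'   rule's `alpha`; required when a P-value mode is run).
#' @param mode `"abf"`, `"pvalue"`, or `"both"`.
#' @param windowBp,r2Threshold clumping parameters (500 kb, 0.1).
#' @param dropAmbiguous passed to [mergeStudies()].
#' @return An [OverlapAnalysis-class].
#' @export
runOverlap <- function(study1, study2, ld, prior = abfPrior(),
                       rule = decisionRule(), alpha = NULL, mode = "both",
                       windowBp = 500000, r2Threshold = 0.1,
                       dropAmbiguous = FALSE) {
    mode <- match.arg(mode, c("abf", "pvalue", "both"))
    modes <- if (mode == "both") c("abf", "pvalue") else mode
    if (is.null(alpha)) alpha <- rule@alpha
    if ("pvalue" %in% modes && is.na(alpha))
        stop("P-value mode requires 'alpha'")
    merged <- mergeStudies(study1, study2, dropAmbiguous = dropAmbiguous)
    metrics <- computeOverlapMetrics(merged, prior, rule, alpha)
    ruleA <- decisionRule(rule@pi0, rule@rCost,
                          alpha = if (is.na(alpha)) NA_real_ else alpha)

    retained <- list(); counts <- list(); midP <- numeric(0)
    for (m in modes) {
        keep <- if (m == "abf")
            clumpSnps(metrics$SNP, metrics$CHR, metrics$BP,
                      metrics$log10AbfStar, ld, windowBp, r2Threshold,
                      decreasing = TRUE)
        else
            clumpSnps(metrics$SNP, metrics$CHR, metrics$BP, metrics$pStar,
                      ld, windowBp, r2Threshold, decreasing = FALSE)
        pruned <- metrics[match(keep, metrics$SNP), ]
        cc <- buildContingency(pruned, ruleA, mode = m)
        retained[[m]] <- keep
        counts[[m]] <- cc
        midP[m] <- mcnemarMidP(cc["n10"], cc["n01"])
    }
    signals <- rankSignals(.reconcileUnion(metrics, retained, ld, windowBp,
                                           r2Threshold))
    new("OverlapAnalysis", metrics = metrics, M = attr(metrics, "M"),
        retained = retained, counts = counts, midP = midP,
        signals = signals, rule = ruleA, prior = prior,
        params = list(windowBp = windowBp, r2Threshold = r2Threshold,
                      mode = mode))
}

#' @describeIn runOverlap accessor: ranked signal table
#' @param x an [OverlapAnalysis-class]
#' @export
overlapSignals <- function(x) x@signals

#' @describeIn runOverlap accessor: contingency counts per mode
#' @export
overlapCounts <- function(x) x@counts

#' @describeIn runOverlap accessor: McNemar mid-P per mode
#' @export
overlapMidP <- function(x) x@midP

#' @describeIn runOverlap accessor: retained SNP ids per mode
#' @export
retainedSnps <- function(x) x@retained
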