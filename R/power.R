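#' Simulate a shared causal SNP across two case-control studies
#'
#' Each replicate draws, independently for the two studies, case and control
#' effect-allele counts at one causal SNP: the control frequency is the
#' population `maf` and the case frequency follows the allelic odds ratio
#' mapping [caseFrequency()]. Per study, the log odds ratio, Woolf variance,
#' log10 ABF and two-sided Wald P-value are returned — the same association
#' statistic as the null-calibration engine. The same replicate index
#' carries both studies' draws, so joint detection is evaluated per
#' replicate.
#'
#' @param n1Cases,n1Controls,n2Cases,n2Controls study sizes.
#' @param maf causal effect-allele frequency in controls.
#' @param or1,or2 per-trait allelic odds ratios.
#' @param nReps number of replicates.
#' @param prior an [AbfPrior-class].
#' @param statistic `"woolf"` or `"logistic"` (see
#'   [simulateNullSummary()]).
#' @param seed optional integer seed.
#' @return data.frame `log10Abf1 p1 log10Abf2 p2`.
#' @export
simulateCausalPair <- function(n1Cases, n1Controls = n1Cases, n2Cases,
                               n2Controls = n2Cases, maf = 0.1, or1 = 1.1,
                               or2 = 1.1, nReps = 1e5, prior = abfPrior(),
                               statistic = "woolf", seed = NULL) {
    stopifnot(or1 > 0, or2 > 0, maf > 0, maf < 1, nReps >= 1)
    if (!is.null(seed)) set.seed(seed)
    w1 <- .simulateStudy(n1Cases, n1Controls, nReps,
                         caseFrequency(maf, or1), maf, statistic)
    w2 <- .simulateStudy(n2Cases, n2Controls, nReps,
                         caseFrequency(maf, or2), maf, statistic)
    data.frame(log10Abf1 = computeAbf(w1$beta, w1$V, prior, log10 = TRUE),
               p1 = w1$pvalue,
               log10Abf2 = computeAbf(w2$beta, w2$V, prior, log10 = TRUE),
               p2 = w2$pvalue)
}

#' Overlap-detection power: Bayesian versus calibrated P-value rules
#'
#' A replicate is detected by the ABF rule when both studies' ABFs exceed
#' `theta`, and by a P-value rule at level `alpha` when both Wald P-values
#' fall below it. Powers are reported for the ABF rule and for the
#' calibrated upper (`alphaU`, the PFP at the smaller study's case count)
#' and lower (`alphaL`, at the larger study's) thresholds, together with the
#' conditional proportions over the ABF-or-alphaU union: the fraction of
#' detected signals found only by ABFs and only by P-values.
#'
#' @param sim data.frame from [simulateCausalPair()].
#' @param rule a [DecisionRule-class].
#' @param alphaL,alphaU calibrated P-value thresholds (see
#'   [calibrateAlphaBounds()]).
#' @return one-row data.frame: `powerAbf`, `powerAlphaL`, `powerAlphaU`,
#'   union/only counts, and `condPropAbfOnly`, `condPropPOnly` (proportions
#'   of the ABF-or-alphaU union).
#' @export
estimateOverlapPower <- function(sim, rule, alphaL, alphaU) {
    lth <- log(rule@theta) / log(10)
    abfDet <- sim$log10Abf1 > lth & sim$log10Abf2 > lth
    pDetU <- sim$p1 < alphaU & sim$p2 < alphaU
    pDetL <- sim$p1 < alphaL & sim$p2 < alphaL
    union <- abfDet | pDetU
    nUnion <- sum(union)
    abfOnly <- sum(abfDet & !pDetU)
    pOnly <- sum(pDetU & !abfDet)
    data.frame(powerAbf = mean(abfDet), powerAlphaL = mean(pDetL),
               powerAlphaU = mean(pDetU), nReps = nrow(sim),
               detectedUnion = nUnion, detectedAbfOnly = abfOnly,
               detectedPOnly = pOnly,
               detectedBoth = nUnion - abfOnly - pOnly,
               condPropAbfOnly = if (nUnion) abfOnly / nUnion else NA_real_,
               condPropPOnly = if (nUnion) pOnly / nUnion else NA_real_)
}

#' Power comparison over a grid of scenarios
#'
#' Convenience wrapper running [simulateCausalPair()] and
#' [estimateOverlapPower()] per scenario row. When `alphaL`/`alphaU` are
#' absent from a scenario they are calibrated on the fly from null
#' simulations at the two case counts via [calibrateAlphaBounds()].
#'
#' @param scenarios data.frame with columns `n1Cases n2Cases maf or1 or2`
#'   and optionally `n1Controls n2Controls alphaL alphaU`.
#' @param rule a [DecisionRule-class].
#' @param nReps replicates per scenario.
#' @param prior an [AbfPrior-class].
#' @param nNullSnps null SNPs per calibration simulation (when needed).
#' @param seed integer seed; per-scenario streams are derived from it.
#' @return the scenario table with power and conditional-proportion columns
#'   appended.
#' @export
powerGrid <- function(scenarios, rule = decisionRule(0.99, 2), nReps = 1e5,
                      prior = abfPrior(), nNullSnps = 1e6, seed = 1) {
    seeds <- deriveSeeds(seed, nrow(scenarios))
    rows <- lapply(seq_len(nrow(scenarios)), function(i) {
        sc <- scenarios[i, ]
        n1co <- if ("n1Controls" %in% names(sc)) sc$n1Controls else sc$n1Cases
        n2co <- if ("n2Controls" %in% names(sc)) sc$n2Controls else sc$n2Cases
        if (all(c("alphaL", "alphaU") %in% names(sc)) &&
            is.finite(sc$alphaL) && is.finite(sc$alphaU)) {
            aL <- sc$alphaL; aU <- sc$alphaU
        } else {
            ab <- calibrateAlphaBounds(rule, min(sc$n1Cases, sc$n2Cases),
                                       max(sc$n1Cases, sc$n2Cases),
                                       nSnps = nNullSnps, prior = prior,
                                       seed = seeds[i])
            aL <- ab$alphaL; aU <- ab$alphaU
        }
        sim <- simulateCausalPair(sc$n1Cases, n1co, sc$n2Cases, n2co,
                                  maf = sc$maf, or1 = sc$or1, or2 = sc$or2,
                                  nReps = nReps, prior = prior,
                                  seed = seeds[i] + 1L)
        cbind(sc[c("n1Cases", "n2Cases", "maf", "or1", "or2")],
              alphaL = aL, alphaU = aU,
              estimateOverlapPower(sim, rule, aL, aU))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
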