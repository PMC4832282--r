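#' Log odds ratio and Woolf variance from allele counts
#'
#' Given effect-allele counts `a` in cases and `b` in controls (out of
#' `2 * nCases` and `2 * nControls` chromosomes), returns the 2x2
#' allele-table log odds ratio and its Woolf variance
#' `1/a + 1/(2 nCases - a) + 1/b + 1/(2 nControls - b)`. SNPs with an empty
#' or full cell receive the Haldane-Anscombe continuity correction (0.5 added
#' to all four cells of the affected SNP only).
#'
#' @param a,b effect-allele counts in cases and controls.
#' @param nCases,nControls numbers of cases and controls (individuals).
#' @return list with numeric vectors `beta` and `V`.
#' @export
waldFromAlleleCounts <- function(a, b, nCases, nControls) {
    a2 <- 2 * nCases - a
    b2 <- 2 * nControls - b
    zero <- a == 0 | a2 == 0 | b == 0 | b2 == 0
    if (any(zero)) {
        a <- a + 0.5 * zero; a2 <- a2 + 0.5 * zero
        b <- b + 0.5 * zero; b2 <- b2 + 0.5 * zero
    }
    list(beta = log(a / a2) - log(b / b2), V = 1 / a + 1 / a2 + 1 / b + 1 / b2)
}

## Additive logistic regression Wald statistic on the 2x3 genotype table,
## vectorized Newton-Raphson across SNPs. Used behind statistic = "logistic"
## as a fidelity check of the fast allele-count default.
.logisticWald <- function(ca0, ca1, ca2, co0, co1, co2, iter = 8L) {
    n0 <- ca0 + co0; n1 <- ca1 + co1; n2 <- ca2 + co2
    nca <- ca0 + ca1 + ca2; nco <- co0 + co1 + co2
    b0 <- log(pmax(nca, 0.5) / pmax(nco, 0.5))
    b1 <- numeric(length(ca0))
    for (i in seq_len(iter)) {
        e0 <- stats::plogis(b0); e1 <- stats::plogis(b0 + b1)
        e2 <- stats::plogis(b0 + 2 * b1)
        U1 <- (ca0 - n0 * e0) + (ca1 - n1 * e1) + (ca2 - n2 * e2)
        U2 <- (ca1 - n1 * e1) + 2 * (ca2 - n2 * e2)
        w0 <- n0 * e0 * (1 - e0); w1 <- n1 * e1 * (1 - e1)
        w2 <- n2 * e2 * (1 - e2)
        I11 <- w0 + w1 + w2; I12 <- w1 + 2 * w2; I22 <- w1 + 4 * w2
        det <- pmax(I11 * I22 - I12^2, .Machine$double.eps)
        b0 <- b0 + (I22 * U1 - I12 * U2) / det
        b1 <- b1 + (-I12 * U1 + I11 * U2) / det
    }
    e0 <- stats::plogis(b0); e1 <- stats::plogis(b0 + b1)
    e2 <- stats::plogis(b0 + 2 * b1)
    w0 <- n0 * e0 * (1 - e0); w1 <- n1 * e1 * (1 - e1); w2 <- n2 * e2 * (1 - e2)
    I11 <- w0 + w1 + w2; I12 <- w1 + 2 * w2; I22 <- w1 + 4 * w2
    list(beta = b1, V = I11 / pmax(I11 * I22 - I12^2, .Machine$double.eps))
}

## One study's summary statistics for nSnps independent SNPs with given case
## and control effect-allele frequencies (vectors or scalars).
.simulateStudy <- function(nCases, nControls, nSnps, fCase, fControl,
                           statistic = c("woolf", "logistic")) {
    statistic <- match.arg(statistic)
    fCase <- rep_len(fCase, nSnps); fControl <- rep_len(fControl, nSnps)
    if (statistic == "woolf") {
        w <- waldFromAlleleCounts(stats::rbinom(nSnps, 2 * nCases, fCase),
                                  stats::rbinom(nSnps, 2 * nControls, fControl),
                                  nCases, nControls)
    } else {
        gdraw <- function(n, f) {
            p0 <- (1 - f)^2; p1 <- 2 * f * (1 - f)
            g0 <- stats::rbinom(nSnps, n, p0)
            g1 <- stats::rbinom(nSnps, n - g0, p1 / (1 - p0))
            list(g0 = g0, g1 = g1, g2 = n - g0 - g1)
        }
        ca <- gdraw(nCases, fCase); co <- gdraw(nControls, fControl)
        w <- .logisticWald(ca$g0, ca$g1, ca$g2, co$g0, co$g1, co$g2)
    }
    w$pvalue <- 2 * stats::pnorm(-abs(w$beta) / sqrt(w$V))
    w
}

#' Simulate null case-control GWAS summary statistics
#'
#' Per SNP: the effect-allele frequency is drawn uniformly over `mafRange`
#' (shared by cases and controls under the null), allele counts are drawn
#' binomially, and the allele-table log odds ratio with Woolf variance and
#' its two-sided Wald P-value are returned. `statistic = "logistic"` instead
#' draws Hardy-Weinberg genotype tables and fits an additive logistic
#' regression per SNP (slower; for fidelity checks).
#'
#' @param nCases,nControls study sizes (individuals).
#' @param nSnps number of independent null SNPs.
#' @param mafRange frequency range, default `c(0.05, 0.5)`.
#' @param statistic `"woolf"` (allele-count log-OR, default) or
#'   `"logistic"`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (the caller must have seeded it).
#' @return data.frame with columns `beta`, `V`, `pvalue`.
#' @export
simulateNullSummary <- function(nCases, nControls = nCases, nSnps,
                                mafRange = c(0.05, 0.5),
                                statistic = c("woolf", "logistic"),
                                seed = NULL) {
    stopifnot(nCases >= 2, nControls >= 2, nSnps >= 1,
              mafRange[1] > 0, mafRange[1] <= mafRange[2], mafRange[2] < 1)
    if (!is.null(seed)) set.seed(seed)
    f <- stats::runif(nSnps, mafRange[1], mafRange[2])
    w <- .simulateStudy(nCases, nControls, nSnps, f, f, statistic)
    data.frame(beta = w$beta, V = w$V, pvalue = w$pvalue)
}

#' Estimate the Bayesian proportion of false positives (PFP)
#'
#' The PFP for a decision rule is the fraction of simulated null SNPs whose
#' ABF exceeds `theta = PO/R`. ABFs are computed once from the simulation
#' output and reused across all supplied rules.
#'
#' @param sim output of [simulateNullSummary()] (columns `beta`, `V`).
#' @param rules a [DecisionRule-class] or list of them.
#' @param prior an [AbfPrior-class].
#' @return data.frame with one row per rule: `pi0`, `rCost`, `log10Theta`,
#'   `pfp`, `nExceed`, `nSnps`, `mcSe` (binomial standard error), and
#'   `noExceedance` flagging rules too strict for the simulation size.
#' @export
estimatePfp <- function(sim, rules, prior = abfPrior()) {
    if (is(rules, "DecisionRule")) rules <- list(rules)
    labf <- computeAbf(sim$beta, sim$V, prior, log10 = TRUE)
    n <- length(labf)
    out <- do.call(rbind, lapply(rules, function(r) {
        nExceed <- sum(labf > log(r@theta) / log(10))
        pfp <- nExceed / n
        data.frame(pi0 = r@pi0, rCost = r@rCost,
                   log10Theta = log10Theta(r, digits = NULL),
                   pfp = pfp, nExceed = nExceed, nSnps = n,
                   mcSe = sqrt(pfp * (1 - pfp) / n),
                   noExceedance = nExceed == 0L)
    }))
    rownames(out) <- NULL
    out
}

#' Semi-analytic proportion of false positives
#'
#' An independent oracle for [estimatePfp()] that avoids simulation: inverts
#' `ABF > theta` into a chi-square(1) tail condition on the Wald statistic,
#' `Z^2 > c(V) = (2 (V + W) / W) * (log(theta) + 0.5 log((V + W) / V))`,
#' with `V(f)` the expected Woolf variance at effect-allele frequency `f`,
#' and integrates the tail probability over `f ~ Uniform(mafRange)`. A
#' degenerate `mafRange` (equal endpoints) evaluates at the point mass.
#'
#' @param nCases,nControls study sizes.
#' @param rule a [DecisionRule-class].
#' @param prior an [AbfPrior-class].
#' @param mafRange frequency range (or a single repeated value).
#' @return numeric(1), the PFP.
#' @export
semiAnalyticPfp <- function(nCases, nControls = nCases, rule,
                            prior = abfPrior(), mafRange = c(0.05, 0.5)) {
    W <- prior@W
    tail1 <- function(f) {
        V <- (1 / (2 * nCases) + 1 / (2 * nControls)) / (f * (1 - f))
        crit <- (2 * (V + W) / W) * (log(rule@theta) + 0.5 * log((V + W) / V))
        ifelse(crit <= 0, 1, stats::pchisq(pmax(crit, 0), df = 1,
                                           lower.tail = FALSE))
    }
    if (mafRange[1] == mafRange[2]) return(tail1(mafRange[1]))
    stats::integrate(tail1, mafRange[1], mafRange[2],
                     rel.tol = 1e-9)$value / diff(mafRange)
}

#' Calibrate matching P-value thresholds for two study sizes
#'
#' For an overlap analysis of a smaller study (`n1Cases`) and a larger study
#' (`n2Cases`), the upper threshold `alphaU` is the PFP of the Bayesian rule
#' at the smaller study's case count and the lower threshold `alphaL` the
#' PFP at the larger study's; `alphaL <= alphaU` up to Monte-Carlo noise.
#'
#' @param rule a [DecisionRule-class].
#' @param n1Cases,n2Cases case counts, `n1Cases <= n2Cases`; controls are
#'   matched 1:1.
#' @param nSnps null SNPs per simulation.
#' @param prior an [AbfPrior-class].
#' @param seed integer seed (two per-size streams are derived from it).
#' @param statistic passed to [simulateNullSummary()].
#' @return list with `alphaL`, `alphaU` and the two PFP estimate rows.
#' @export
calibrateAlphaBounds <- function(rule, n1Cases, n2Cases, nSnps = 1e6,
                                 prior = abfPrior(), seed = 1,
                                 statistic = "woolf") {
    stopifnot(n1Cases <= n2Cases)
    seeds <- deriveSeeds(seed, 2)
    simU <- simulateNullSummary(n1Cases, n1Cases, nSnps, statistic = statistic,
                                seed = seeds[1])
    estU <- estimatePfp(simU, rule, prior)
    if (n1Cases == n2Cases) {
        estL <- estU
    } else {
        simL <- simulateNullSummary(n2Cases, n2Cases, nSnps,
                                    statistic = statistic, seed = seeds[2])
        estL <- estimatePfp(simL, rule, prior)
    }
    list(alphaL = estL$pfp, alphaU = estU$pfp, upper = estU, lower = estL)
}

#' PFP calibration table over a grid of sample sizes and cost ratios
#'
#' Runs one null simulation per case count (all rules share it, so the
#' comparison across rules is exact) and tabulates the PFP per (N, rule).
#' The default grid of N and R values matches the conventional reporting
#' layout: rows N, columns R.
#'
#' @param nCasesGrid integer vector of case counts (1:1 controls unless
#'   `controlRatio` is changed).
#' @param rCost numeric vector of cost ratios.
#' @param pi0 prior probability of no association.
#' @param nSnps null SNPs per sample size.
#' @param prior an [AbfPrior-class].
#' @param controlRatio controls per case.
#' @param seed integer seed; per-N streams are derived from it.
#' @param statistic passed to [simulateNullSummary()].
#' @return data.frame: `nCases`, `pi0`, `rCost`, `log10Theta`, `pfp`,
#'   `nExceed`, `nSnps`, `mcSe`, `noExceedance`.
#' @export
pfpCalibrationTable <- function(nCasesGrid = c(2000, 3000, 4000, 5000, 8000,
                                               10000, 20000, 30000, 50000,
                                               100000),
                                rCost = c(1, 2, 4, 5, 10, 12, 15, 20),
                                pi0 = 0.99, nSnps = 5e6, prior = abfPrior(),
                                controlRatio = 1, seed = 1,
                                statistic = "woolf") {
    rules <- lapply(rCost, function(r) decisionRule(pi0, r))
    seeds <- deriveSeeds(seed, length(nCasesGrid))
    out <- do.call(rbind, lapply(seq_along(nCasesGrid), function(i) {
        n <- nCasesGrid[i]
        sim <- simulateNullSummary(n, round(n * controlRatio), nSnps,
                                   statistic = statistic, seed = seeds[i])
        est <- estimatePfp(sim, rules, prior)
        cbind(nCases = n, est)
    }))
    rownames(out) <- NULL
    out
}

#' Fit the -log10(PFP) extrapolation regression
#'
#' Ordinary least squares of `-log10(PFP)` on `log10(N)` and `log10(N)^2`
#' over the simulated grid; when the linear coefficient is not significant
#' at the 5% level it is removed and the model refitted. Non-positive PFP
#' values are excluded with a warning.
#'
#' @param nCases case counts of the grid (>= 4 usable points).
#' @param pfp PFP estimates at those counts.
#' @param rule the [DecisionRule-class] the grid was computed for.
#' @return A [CalibrationCurve-class].
#' @export
fitPfpCurve <- function(nCases, pfp, rule = decisionRule()) {
    keep <- is.finite(pfp) & pfp > 0
    if (any(!keep))
        warning(sum(!keep), " grid point(s) with non-positive PFP excluded")
    nCases <- nCases[keep]; pfp <- pfp[keep]
    if (length(unique(nCases)) < 4L)
        stop("need at least 4 distinct sample sizes to fit the curve")
    d <- data.frame(y = -log10(pfp), x = log10(nCases))
    fit <- stats::lm(y ~ x + I(x^2), data = d)
    pLinear <- summary(fit)$coefficients["x", "Pr(>|t|)"]
    dropped <- is.na(pLinear) || pLinear >= 0.05
    if (dropped) fit <- stats::lm(y ~ I(x^2), data = d)
    cf <- stats::coef(fit)
    coefs <- c("(Intercept)" = unname(cf["(Intercept)"]),
               log10N = if (dropped) 0 else unname(cf["x"]),
               log10N2 = unname(cf["I(x^2)"]))
    new("CalibrationCurve", coefficients = coefs,
        linearDropped = isTRUE(dropped),
        grid = data.frame(nCases = nCases, pfp = pfp), rule = rule)
}

#' Predict the PFP at a new sample size from a calibration curve
#'
#' @param curve a [CalibrationCurve-class].
#' @param nCases case count(s) to predict at.
#' @return numeric vector of predicted PFP values (`10^-fitted`).
#' @export
predictPfp <- function(curve, nCases) {
    cf <- curve@coefficients
    x <- log10(nCases)
    unname(10^-(cf["(Intercept)"] + cf["log10N"] * x + cf["log10N2"] * x^2))
}
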