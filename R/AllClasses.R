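#' @import methods
NULL

#' Effect-size prior for approximate Bayes factors
#'
#' An `AbfPrior` holds the variance `W` of the Normal(0, W) prior on the log
#' odds ratio. `W` may be given directly or derived from an upper odds ratio
#' `orUpper` such that `P(OR > orUpper) = tailProb/2` under the prior
#' (two-sided tail probability `tailProb`), i.e.
#' `W = (log(orUpper) / qnorm(1 - tailProb/2))^2`.
#'
#' @slot W numeric(1), prior variance of the log odds ratio.
#' @slot orUpper numeric(1), the upper odds ratio the prior was derived from,
#'   or `NA` if `W` was supplied directly.
#' @slot tailProb numeric(1), two-sided prior tail probability, or `NA`.
#' @export
setClass("AbfPrior",
    representation(W = "numeric", orUpper = "numeric", tailProb = "numeric"),
    prototype(W = 0.04, orUpper = NA_real_, tailProb = NA_real_))

setValidity("AbfPrior", function(object) {
    if (length(object@W) != 1L || !is.finite(object@W) || object@W <= 0)
        return("W must be a single positive number")
    TRUE
})

#' Bayesian / frequentist decision rule
#'
#' A `DecisionRule` bundles the prior probability of no association `pi0`, the
#' error-cost ratio `rCost` (type II cost / type I cost; values above 1 are
#' "discovery mode"), the implied Bayes-factor threshold
#' `theta = (pi0 / (1 - pi0)) / rCost`, and optionally a frequentist P-value
#' threshold `alpha`. A SNP is called high-evidence when `ABF > theta`
#' (strictly) in ABF mode, or `P < alpha` (strictly) in P-value mode.
#'
#' @slot pi0 numeric(1) in (0, 1).
#' @slot rCost numeric(1) > 0.
#' @slot theta numeric(1), the ABF threshold `PO/R`.
#' @slot alpha numeric(1) in (0, 1), or `NA` when no frequentist counterpart
#'   is attached.
#' @export
setClass("DecisionRule",
    representation(pi0 = "numeric", rCost = "numeric", theta = "numeric",
                   alpha = "numeric"),
    prototype(pi0 = 0.99, rCost = 1, theta = 99, alpha = NA_real_))

setValidity("DecisionRule", function(object) {
    msg <- character()
    if (!is.finite(object@pi0) || object@pi0 <= 0 || object@pi0 >= 1)
        msg <- c(msg, "pi0 must be in (0, 1)")
    if (!is.finite(object@rCost) || object@rCost <= 0)
        msg <- c(msg, "rCost must be positive")
    if (length(msg)) msg else {
        expected <- (object@pi0 / (1 - object@pi0)) / object@rCost
        if (!isTRUE(all.equal(object@theta, expected, tolerance = 1e-8)))
            "theta must equal (pi0/(1-pi0))/rCost" else TRUE
    }
})

#' Calibration curve for extrapolating the proportion of false positives
#'
#' Holds the ordinary-least-squares fit of `-log10(PFP)` on `log10(N)` and
#' `log10(N)^2` over a grid of simulated case counts, for one decision rule.
#' When the linear term is not significant at the 5% level it is dropped and
#' the model refitted (`linearDropped`).
#'
#' @slot coefficients named numeric: `(Intercept)`, `log10N`, `log10N2`
#'   (`log10N` is 0 when dropped).
#' @slot linearDropped logical(1).
#' @slot grid data.frame with columns `nCases` and `pfp` used for the fit.
#' @slot rule the [DecisionRule-class] the curve was fitted for.
#' @export
setClass("CalibrationCurve",
    representation(coefficients = "numeric", linearDropped = "logical",
                   grid = "data.frame", rule = "DecisionRule"))

setValidity("CalibrationCurve", function(object) {
    if (!all(c("(Intercept)", "log10N", "log10N2") %in%
             names(object@coefficients)))
        return("coefficients must be named (Intercept), log10N, log10N2")
    if (nrow(object@grid) < 4L)
        return("calibration grid needs at least 4 sample sizes")
    TRUE
})

#' Result container for a two-trait overlap analysis
#'
#' Produced by [runOverlap()]. Holds the merged per-SNP metrics, the global
#' maximum ABF `M` used by the ABF* pruning metric, the per-mode retained
#' (LD-pruned) SNP sets, matched-pair contingency counts, McNemar mid-P
#' values, and the ranked signal table.
#'
#' @slot metrics data.frame of per-SNP statistics for the full merged set.
#' @slot M numeric(1), maximum log10 ABF over both traits and all SNPs.
#' @slot retained named list of character vectors of retained SNP ids, one
#'   per mode run (`"abf"`, `"pvalue"`).
#' @slot counts named list of integer vectors `(n11, n10, n01, n00)` per mode.
#' @slot midP named numeric of mid-P values per mode.
#' @slot signals data.frame, the reconciled ranked signal table.
#' @slot rule the [DecisionRule-class] used.
#' @slot prior the [AbfPrior-class] used.
#' @slot params list of pruning parameters (window, r2 threshold, mode).
#' @export
setClass("OverlapAnalysis",
    representation(metrics = "data.frame", M = "numeric", retained = "list",
                   counts = "list", midP = "numeric", signals = "data.frame",
                   rule = "DecisionRule", prior = "AbfPrior", params = "list"))

#' @describeIn AbfPrior-class compact display
#' @param object an `AbfPrior`
#' @export
setMethod("show", "AbfPrior", function(object) {
    cat("AbfPrior: W =", format(object@W, digits = 4))
    if (!is.na(object@orUpper))
        cat(" (OR_U =", object@orUpper, ", two-sided tail =",
            object@tailProb, ")")
    cat("\n")
})

#' @describeIn DecisionRule-class compact display
#' @param object a `DecisionRule`
#' @export
setMethod("show", "DecisionRule", function(object) {
    cat(sprintf("DecisionRule: pi0 = %s, R = %s, theta = %.4g (log10 = %.3f)",
                format(object@pi0), format(object@rCost), object@theta,
                log10(object@theta)))
    if (!is.na(object@alpha)) cat(sprintf(", alpha = %.3g", object@alpha))
    cat("\n")
})

#' @describeIn CalibrationCurve-class compact display
#' @param object a `CalibrationCurve`
#' @export
setMethod("show", "CalibrationCurve", function(object) {
    cf <- object@coefficients
    cat("CalibrationCurve: -log10(PFP) =",
        sprintf("%.4f %+.4f log10(N) %+.4f log10(N)^2",
                cf["(Intercept)"], cf["log10N"], cf["log10N2"]), "\n")
    cat("  fitted over", nrow(object@grid), "sample sizes;",
        if (object@linearDropped) "linear term dropped (P >= 0.05)"
        else "linear term retained", "\n")
})

#' @describeIn OverlapAnalysis-class compact display
#' @param object an `OverlapAnalysis`
#' @export
setMethod("show", "OverlapAnalysis", function(object) {
    cat("OverlapAnalysis of", nrow(object@metrics), "merged SNPs\n")
    show(object@rule)
    for (m in names(object@retained)) {
        cc <- object@counts[[m]]
        cat(sprintf("  [%s] retained %d SNPs; n11=%d n10=%d n01=%d n00=%d; mid-P = %.3g\n",
                    m, length(object@retained[[m]]), cc["n11"], cc["n10"],
                    cc["n01"], cc["n00"], object@midP[[m]]))
    }
})
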