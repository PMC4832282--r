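#' Construct an effect-size prior
#'
#' Either supply the prior variance `W` of the log odds ratio directly, or
#' derive it from an upper odds ratio via [priorVariance()]. The default,
#' `W = 0.04 = 0.2^2`, corresponds to a two-sided prior probability of 0.05
#' that the odds ratio exceeds 1.48.
#'
#' @param W prior variance of the log odds ratio; ignored when `orUpper` is
#'   given.
#' @param orUpper upper odds ratio `OR_U` (> 1).
#' @param tailProb two-sided prior probability that `OR > OR_U`.
#' @return An [AbfPrior-class] object.
#' @examples
#' abfPrior()                      # W = 0.04
#' abfPrior(orUpper = 2, tailProb = 0.05)
#' @export
abfPrior <- function(W = 0.04, orUpper = NULL, tailProb = 0.05) {
    if (!is.null(orUpper)) {
        W <- priorVariance(orUpper, tailProb)
        new("AbfPrior", W = W, orUpper = as.numeric(orUpper),
            tailProb = as.numeric(tailProb))
    } else {
        new("AbfPrior", W = as.numeric(W))
    }
}

#' Prior variance of the log odds ratio from an upper odds ratio
#'
#' Computes `W = (log(orUpper) / qnorm(1 - tailProb/2))^2`, the variance of a
#' Normal(0, W) prior on the log odds ratio under which the two-sided prior
#' probability that `OR > orUpper` equals `tailProb`. The conventional default
#' `W = 0.2^2` arises from `orUpper = 1.48`, `tailProb = 0.05`.
#'
#' @param orUpper upper odds ratio, must exceed 1.
#' @param tailProb two-sided tail probability in (0, 1).
#' @return numeric(1), the prior variance.
#' @examples
#' priorVariance(1.48, 0.05)  # ~ 0.04
#' @export
priorVariance <- function(orUpper, tailProb = 0.05) {
    if (!is.numeric(orUpper) || orUpper <= 1)
        stop("'orUpper' must exceed 1: the prior must allow positive effects")
    if (tailProb <= 0 || tailProb >= 1)
        stop("'tailProb' must be in (0, 1)")
    (log(orUpper) / stats::qnorm(1 - tailProb / 2))^2
}

#' Approximate Bayes factor from an effect estimate and its variance
#'
#' Computes the summary-statistic approximate Bayes factor
#' \deqn{ABF = \sqrt{V/(V+W)} \exp\{ (W/(V+W)) Z^2 / 2 \},}
#' where `Z = beta/sqrt(V)`, `V` is the variance of the effect estimate and
#' `W` the prior variance of the effect. Large values are evidence against
#' the null hypothesis of no association. Because `Z^2` can be very large in
#' well-powered studies the computation is carried out on the log10 scale;
#' set `log10 = TRUE` to avoid overflow entirely.
#'
#' @param beta effect estimate(s) (log odds ratio), numeric vector.
#' @param V variance(s) of `beta` (squared standard error), recycled.
#' @param prior an [AbfPrior-class], or a plain numeric `W`.
#' @param log10 return log10(ABF) instead of ABF.
#' @return numeric vector of (log10) approximate Bayes factors.
#' @examples
#' computeAbf(log(1.1), 0.05^2)          # W = 0.04 default
#' computeAbf(0, V = 0.04)               # Z = 0, V = W: sqrt(1/2)
#' @export
computeAbf <- function(beta, V, prior = abfPrior(), log10 = FALSE) {
    W <- if (is(prior, "AbfPrior")) prior@W else as.numeric(prior)
    if (length(W) != 1L || is.na(W) || W < 0)
        stop("prior variance W must be a single non-negative number")
    if (any(!is.finite(V)) || any(V <= 0))
        stop("V must be positive and finite")
    z2 <- beta^2 / V
    labf <- 0.5 * (log(V) - log(V + W)) / log(10) +
        (W / (V + W)) * z2 / (2 * log(10))
    if (log10) labf else 10^labf
}

#' Construct a Bayesian decision rule
#'
#' Builds the threshold `theta = PO/R` with `PO = pi0/(1 - pi0)` the prior
#' odds of no association and `R = rCost` the ratio of type II to type I
#' error costs. A SNP is declared associated when `ABF > theta`. An optional
#' calibrated P-value threshold `alpha` may be attached for the frequentist
#' arm of an analysis.
#'
#' @param pi0 prior probability of no association, in (0, 1).
#' @param rCost error cost ratio `R` (> 0); `R > 1` is "discovery mode".
#' @param alpha optional P-value threshold in (0, 1).
#' @return A [DecisionRule-class].
#' @examples
#' decisionRule(0.99, 1)    # theta = 99, log10 = 1.996
#' decisionRule(0.99, 20)   # theta = 4.95, log10 = 0.695
#' @export
decisionRule <- function(pi0 = 0.99, rCost = 1, alpha = NA_real_) {
    if (!is.na(alpha) && (alpha <= 0 || alpha >= 1))
        stop("'alpha' must be in (0, 1)")
    theta <- (pi0 / (1 - pi0)) / rCost
    new("DecisionRule", pi0 = as.numeric(pi0), rCost = as.numeric(rCost),
        theta = theta, alpha = as.numeric(alpha))
}

#' @rdname decisionRule
#' @param rule a [DecisionRule-class]
#' @export
theta <- function(rule) rule@theta

#' @rdname decisionRule
#' @details `log10Theta()` reports the threshold on the log10 scale, rounded
#'   to three decimals as conventionally tabulated.
#' @param digits decimals for rounding; `NULL` for no rounding.
#' @export
log10Theta <- function(rule, digits = 3) {
    lt <- log10(rule@theta)
    if (is.null(digits)) lt else round(lt, digits)
}

#' @rdname decisionRule
#' @export
alphaLevel <- function(rule) rule@alpha

#' Classify evidence against a decision rule
#'
#' In ABF mode a value is high-evidence iff `ABF > theta` (strictly); in
#' P-value mode iff `P < alpha` (strictly). Boundary values are classified
#' low-evidence.
#'
#' @param x numeric vector of ABFs (or log10 ABFs with `log10 = TRUE`) or
#'   P-values, depending on `mode`.
#' @param rule a [DecisionRule-class]; P-value mode requires its `alpha`.
#' @param mode `"abf"` or `"pvalue"`.
#' @param log10 in ABF mode, interpret `x` as log10(ABF).
#' @return logical vector: `TRUE` for high evidence.
#' @examples
#' r <- decisionRule(0.99, 1, alpha = 1e-3)
#' classifyEvidence(c(99, 100), r)                  # FALSE TRUE (strict)
#' classifyEvidence(c(1e-4, 1e-3), r, mode = "pvalue")
#' @export
classifyEvidence <- function(x, rule, mode = c("abf", "pvalue"),
                             log10 = FALSE) {
    mode <- match.arg(mode)
    if (mode == "abf") {
        if (log10) x > log(rule@theta) / log(10) else x > rule@theta
    } else {
        if (is.na(rule@alpha))
            stop("P-value mode requires a rule with 'alpha' set")
        x < rule@alpha
    }
}
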