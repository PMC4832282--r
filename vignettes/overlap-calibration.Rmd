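---
title: "Bayesian overlap analysis of GWAS summary statistics: methods and calibration"
author: "abfOverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian overlap analysis: methods and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abfOverlap)
```

## The problem

Two diseases often co-occur beyond chance, and a cheap way to look for a
shared genetic basis is to take the summary statistics of two independent
GWAS and ask which SNPs show evidence of association with *both* traits.
The standard frequentist recipe — call a SNP shared when both P-values pass
a threshold — ignores that the two studies usually have very different
power: a fixed P-value threshold has the same type I error in both studies
but very different sensitivity, so threshold choice is always wrong for one
of the two studies. Bayes factors do not have this defect: because the
approximate Bayes factor depends on the variance of the effect estimate as
well as on the Wald statistic, a single Bayes-factor threshold applied to
studies of different sizes automatically implies a *smaller* realized type
I error in the larger study. This package implements the Bayesian overlap
workflow around that observation, together with the simulation machinery
needed to calibrate Bayes-factor thresholds against P-value thresholds and
to compare the power of the two routes.

## The model

For each SNP and trait we take the logistic-regression summary
$\hat\beta = \log \widehat{OR}$ with variance $V = \mathrm{se}^2$ and
compute Wakefield's summary-statistic approximate Bayes factor against a
Normal$(0, W)$ effect prior,

$$ABF = \sqrt{\frac{V}{V+W}} \exp\!\left\{\frac{W}{V+W}\,
  \frac{Z^2}{2}\right\},\qquad Z = \hat\beta/\sqrt{V},$$

which is exactly the marginal-likelihood ratio
$N(\hat\beta; 0, V+W)\,/\,N(\hat\beta; 0, V)$; large values are evidence
against the null (`computeAbf()`, with a density-ratio oracle in the test
suite). The default prior variance is $W = 0.2^2$, the value implied by a
5% two-sided prior probability that the odds ratio exceeds 1.48
(`priorVariance()`); `abfPrior()` accepts any other $(OR_U,
\text{tail})$ pair or a direct $W$. $W$ is constant across SNPs — MAF- or
effect-size-dependent priors are deliberately out of scope.

The null of no association is rejected when $ABF > \theta = PO/R$, where
$PO = \pi_0/(1-\pi_0)$ is the prior odds of no association and $R$ the
ratio of type II to type I error costs (`decisionRule()`). $R > 1 $ is
"discovery mode"; overlap screens typically use $\pi_0 \in \{0.99,
0.999\}$ and $R$ between 1 and 20 rather than genome-wide-significance
settings. Ties at the threshold are classified as low evidence (strict
inequality); the boundary case does not arise in continuous data and the
convention simply keeps the implementation deterministic.

ABFs are computed and stored on the log10 scale throughout: $Z^2$ can
exceed 1,000 in modern studies, and $\exp(Z^2/2)$ overflows a double long
before that.

## Two-trait pruning and the enrichment test

Contingency-table tests need approximately independent SNPs, but LD
pruning for two traits at once must decide which of two linked SNPs to
keep using a *single* metric. The package builds the dual-trait pruning
statistics

$$ABF^\ast = \max(ABF_1, ABF_2) + M \cdot
  I\{ABF_1 > \theta \text{ and } ABF_2 > \theta\},$$

with $M$ the maximum ABF at any SNP for either trait over the full merged
set, and

$$P^\ast = \min(P_1, P_2) - 1 \cdot I\{P_1 < \alpha \text{ and }
  P_2 < \alpha\}.$$

Because $M$ bounds every individual ABF, any SNP passing the threshold in
both traits outranks every single-trait signal during clumping, so the
pruned set preferentially retains dual signals. $M$ is computed once, on
the full merged set, before any pruning: its definition is a global
maximum, and recomputing it as clumps are removed would make the metric
order-dependent. Clumping itself (`clumpSnps()`) is index-SNP driven like
PLINK's `--clump`: the best remaining SNP by $ABF^\ast$ (descending) or
$P^\ast$ (ascending) indexes a clump and removes every SNP within 500 kb
(inclusive at exactly 500 kb) with $r^2$ strictly greater than 0.1; pairs
absent from the LD table count as unlinked. Ties break by position then
id. Pruning runs separately for the ABF and P-value modes; the combined
signal list is reconciled by re-clumping the union and keeping the
larger-ABF member of a linked pair.

The starred metrics are used *only* for pruning. The matched-pair
contingency table (`buildContingency()`) classifies each retained SNP by
the individual per-trait statistics: $n_{11}$ high in both, $n_{10}$ and
$n_{01}$ discordant, $n_{00}$ neither. Effect direction is ignored
throughout — a SNP may raise risk of one trait and lower the other and
still count as shared. Excess concordance is tested with McNemar's mid-P
test on the discordant counts,

$$\text{mid-}P = 2 \sum_{x=0}^{k} f(x \mid n) - f(k \mid n), \qquad
  k = \min(n_{10}, n_{01}),\; n = n_{10} + n_{01},$$

with $f$ the Binomial$(n, 1/2)$ pmf (`mcnemarMidP()`). The formula can
exceed 1 when $n_{10} = n_{01}$, so the result is clipped to $(0, 1]$, and
$n = 0$ returns 1 by convention (no discordance carries no evidence). The
mid-P variant subtracts half the boundary mass and is therefore never
larger than the exact conditional two-sided P-value — the test suite
asserts this for all $n \le 50$ and checks the pmf sum against exhaustive
enumeration.

## Threshold calibration by null simulation

A Bayes-factor threshold has no fixed type I error: the realized
proportion of false positives (PFP) under the null falls as the study
grows. `simulateNullSummary()` estimates it by simulating independent null
SNPs: per SNP a frequency $f \sim U(0.05, 0.5)$ (the common-variant
screen; uniform is also what PLINK's `--simulate` draws within a stated
range), binomial effect-allele counts in $2N$ case and $2N$ control
chromosomes, the allele-table log odds ratio, and its Woolf variance
$1/a + 1/(2N_{ca}-a) + 1/b + 1/(2N_{co}-b)$. SNPs with an empty cell —
rare at MAF $\ge$ 0.05 and $N \ge 2{,}000$ — get the Haldane–Anscombe 0.5
correction on all four cells rather than being dropped, which would bias
the tail. The Woolf statistic was chosen as the default because it
vectorizes to millions of SNPs in seconds; a genotype-level additive
logistic Wald (vectorized Newton–Raphson on the 2×3 table) is available
behind `statistic = "logistic"` and is statistically indistinguishable
from the allele-count default across the calibration grid at 5M SNPs.

`estimatePfp()` counts threshold exceedances (ABFs computed once per
simulation and shared by all rules, so comparisons across rules carry no
extra Monte-Carlo noise), and `semiAnalyticPfp()` provides an independent
oracle: inverting $ABF > \theta$ gives the chi-square(1) tail condition
$Z^2 > (2(V+W)/W)\,[\log\theta + \tfrac12 \log((V+W)/V)]$, integrated over
the frequency distribution with the expected Woolf variance $V(f)$.

For an overlap analysis of a smaller study ($N_1$ cases) and a larger one
($N_2$), `calibrateAlphaBounds()` turns the Bayesian rule into the two
natural P-value thresholds: $\alpha_U$, the PFP at $N_1$ (lenient for the
larger study), and $\alpha_L$, the PFP at $N_2$ (strict for the smaller).
Although calibration assumes 1:1 case-control sampling, the PFP at $N$
cases with up to $2N$ controls stays within about 15% of the 1:1 value,
so the tables remain usable for moderately unbalanced designs (asserted in
the tests). For sample sizes off the simulated grid, `fitPfpCurve()`
regresses $-\log_{10}(\mathrm{PFP})$ on a quadratic in $\log_{10} N$
(dropping the linear term when its coefficient is not significant at the
5% level, which happens on some grids because $\log_{10}N$ and its square
are nearly collinear over one decade) and `predictPfp()` inverts the
transform.

## Power comparison

`simulateCausalPair()` simulates one shared causal SNP in two independent
case-control studies: the control effect-allele frequency is the causal
MAF (0.1 or 0.2 in the reference scenarios, held fixed rather than drawn
with noise), the case frequency follows the allelic odds-ratio mapping
$f' = f \cdot OR / (1 + f(OR - 1))$, and only positive effect directions
are simulated since direction does not enter overlap detection. The same
replicate index carries both studies' draws, so `estimateOverlapPower()`
can compare, per replicate, joint detection by the ABF rule (both
$ABF > \theta$) against the calibrated $\alpha_U$/$\alpha_L$ rules (both
$P < \alpha$), and report the conditional proportions of the
ABF-or-$\alpha_U$ union caught by only one route. Overlap power is bounded
by the smaller marginal power, and the ABF rule dominates the strict
$\alpha_L$ rule everywhere — both appear as property tests.

One caveat worth stating explicitly: the "only by P-values" conditional
proportion is a knife-edge quantity. Given $V$, both rules are monotone in
the same Wald $Z^2$, so the P-only set is a thin slice between $\alpha_U$
and the ABF rule's $V$-dependent P-equivalent cutoff; its size responds to
percent-level changes in the variance model or in the tabulated
$\alpha_U$, far more strongly than the powers themselves. Comparisons of
this proportion across implementations should be read qualitatively.

## Synthetic fixtures

`generateFixture()` produces the two-study fixture the pipeline tests run
on: blocks of SNPs with within-block $r^2$ decaying geometrically with
marker distance, blocks spaced 2 Mb apart (independent by construction),
planted dual-trait signals at block centres with LD-attenuated effects
$\exp(r\,\log OR)$ at block-mates, and binomial allele-count sampling
identical to the simulators. Defaults (10 blocks × 20 SNPs, studies of
10,000 cases and 10,000 controls, planted allelic OR 1.3) make planted
signals overwhelming ($Z \approx 11$) so recovery failures indicate
pipeline defects, not sampling noise. Two features of real data are *not*
emulated: null effect estimates are independent across linked SNPs (the
LD table only drives pruning), and all fixtures are strand-clean —
strand-ambiguous A/T and C/G SNPs are exercised in dedicated merge tests
instead, where the `dropAmbiguous` switch covers the policy choice real
meta-analyses must make.

## Numerical and design choices

* Boundary classification is strict (`ABF = theta` and `P = alpha` are
  low evidence); ABFs live in log10 space; the mid-P is clipped to
  $(0, 1]$.
* P-values are always recomputed from $\hat\beta/\mathrm{se}$ on read;
  a stored P column disagreeing by more than 10% triggers a per-file
  warning. The frequentist arm is defined by the Wald statistic, so mixed
  provenance P-values would silently distort the calibration.
* Allele alignment flips study 2's sign when its effect allele matches
  study 1's other allele; incompatible allele pairs are dropped with a
  recorded reason. Strand-ambiguous SNPs are kept by default (fixtures
  are strand-clean; real analyses can choose).
* Every stochastic entry point takes one integer seed; multi-stage runs
  derive per-stage child streams with `deriveSeeds()`, so identical
  seeds reproduce outputs byte-identically.
* Simulation sizes: the reference calibration uses 5M null SNPs per
  sample size and 5M power replicates. The test suite runs the same
  checks at 1M SNPs / 500k replicates — chosen so that each check's
  3-SE Monte-Carlo band stays well below the scientific tolerance it
  verifies — and widens tolerances accordingly (each stochastic check
  allows max(10% relative, 3 binomial SEs) at the size actually run).

## Known limitations

* The calibration reproduces published reference values to within a few
  percent at moderate sample sizes but sits systematically a few percent
  high in the largest-sample rows ($N \ge 30{,}000$), for either per-SNP
  statistic; the semi-analytic chi-square oracle agrees with our
  simulations, so the residual reflects unmodelled details of the
  original simulation pipeline rather than a defect reproducible from
  its description.
* Genome-build conversion, imputation, dosage data, VCF parsing, proxy
  SNP lookup and gene annotation are out of scope; inputs are summary
  tables plus a precomputed LD table.
* McNemar's mid-P requires approximately independent SNPs; the quality
  of that approximation is bounded by the LD table supplied.

## A small worked run

```{r example}
fx <- generateFixture(nBlocks = 8, blockSize = 7, nOverlapSignals = 3,
                      signalOr = 1.3, seed = 11)
res <- runOverlap(fx$study1, fx$study2, fx$ld,
                  rule = decisionRule(0.99, 20), alpha = 1e-3)
res
head(overlapSignals(res), 5)
fx$truth$SNP
```

The planted blocks surface at the top of the ranked table (the retained
SNP may be a clump-mate of the planted one), the matched-pair counts show
the planted dual signals in $n_{11}$, and the mid-P reflects enrichment
far beyond chance for this tiny panel.
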