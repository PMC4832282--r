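#' Generate a synthetic two-study summary-statistic fixture
#'
#' Emits a pair of case-control GWAS summary-statistic tables over a common
#' SNP panel with block LD structure, a long-format LD table, and a truth
#' list of planted shared-effect SNPs, so the whole overlap pipeline can be
#' exercised without external data.
#'
#' SNPs are laid out in `nBlocks` blocks of `blockSize` SNPs on one
#' chromosome; blocks are separated by 2 Mb (beyond the clumping window) and
#' are therefore independent. Within a block, `r2` between SNPs `i` and `j`
#' decays as `ldDecay^|i - j|`. Planted signals are placed at the central SNP
#' of the first `nOverlapSignals` blocks with allelic odds ratio `signalOr`
#' in both traits; their block-mates carry the LD-attenuated effect
#' `exp(r * log(signalOr))` with `r = sqrt(r2)`, mimicking how association
#' signal leaks across a clump. All other SNPs are null in both studies.
#'
#' Per SNP and study, effect-allele counts are drawn binomially from the
#' shared population frequency (shifted in cases under a signal), and the
#' log odds ratio with its Woolf variance forms the summary record — the
#' same sampling model used by the calibration and power simulators. The
#' LD table describes the pruning structure; null effect estimates are drawn
#' independently across SNPs, so fixtures do not emulate correlated null
#' statistics within a block.
#'
#' @param nBlocks number of LD blocks.
#' @param blockSize SNPs per block; `1` yields an empty LD table.
#' @param ldDecay per-step `r2` decay within a block, in (0, 1).
#' @param nOverlapSignals number of blocks given a planted dual-trait signal.
#' @param nCases,nControls integer vectors of length 2: per-study sizes.
#' @param signalOr allelic odds ratio of planted signals (both traits).
#' @param mafRange range of the population effect-allele frequency.
#' @param spacingBp within-block spacing in bp.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list with elements `study1`, `study2` (canonical summary
#'   data.frames), `ld` (data.frame `snpA snpB r2`), `truth` (data.frame
#'   `SNP or1 or2`).
#' @examples
#' fx <- generateFixture(nBlocks = 4, blockSize = 5, nOverlapSignals = 1,
#'                       seed = 1)
#' head(fx$study1)
#' @export
generateFixture <- function(nBlocks = 10, blockSize = 20, ldDecay = 0.8,
                            nOverlapSignals = 0,
                            nCases = c(10000, 10000), nControls = nCases,
                            signalOr = 1.3, mafRange = c(0.1, 0.45),
                            spacingBp = 20000, seed = 1) {
    stopifnot(nBlocks >= 1, blockSize >= 1, ldDecay > 0, ldDecay < 1,
              nOverlapSignals >= 0, nOverlapSignals <= nBlocks,
              signalOr > 0, length(nCases) == 2, length(nControls) == 2)
    set.seed(seed)
    nSnps <- nBlocks * blockSize
    block <- rep(seq_len(nBlocks), each = blockSize)
    within <- rep(seq_len(blockSize), nBlocks)
    pos <- (block - 1L) * 2000000L + (within - 1L) * as.integer(spacingBp) + 1L
    ids <- sprintf("rs%d_%d", block, within)
    f <- stats::runif(nSnps, mafRange[1], mafRange[2])

    ## planted effects: causal SNP at block centre, attenuated block-mates
    or1 <- rep(1, nSnps); or2 <- rep(1, nSnps)
    centre <- (blockSize + 1L) %/% 2L
    causal <- integer(0)
    if (nOverlapSignals > 0) {
        causal <- which(block <= nOverlapSignals & within == centre)
        for (ci in causal) {
            mates <- which(block == block[ci])
            r <- sqrt(ldDecay^abs(within[mates] - centre))
            or1[mates] <- exp(r * log(signalOr))
            or2[mates] <- exp(r * log(signalOr))
        }
    }

    alleles <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
    ai <- sample(nrow(alleles), nSnps, replace = TRUE)

    study <- function(k, orv) {
        fCase <- caseFrequency(f, orv)
        w <- waldFromAlleleCounts(
            stats::rbinom(nSnps, 2 * nCases[k], fCase),
            stats::rbinom(nSnps, 2 * nControls[k], f),
            nCases[k], nControls[k])
        data.frame(SNP = ids, CHR = "1", BP = pos,
                   A1 = alleles[ai, 1], A2 = alleles[ai, 2],
                   BETA = w$beta, SE = sqrt(w$V),
                   P = 2 * stats::pnorm(-abs(w$beta) / sqrt(w$V)),
                   MAF = pmin(f, 1 - f),
                   N_CASES = nCases[k], N_CONTROLS = nControls[k],
                   stringsAsFactors = FALSE)
    }
    s1 <- study(1, or1)
    s2 <- study(2, or2)

    ## within-block LD pairs
    ld <- NULL
    if (blockSize > 1) {
        pairs <- do.call(rbind, lapply(seq_len(nBlocks), function(b) {
            idx <- which(block == b)
            cmb <- utils::combn(idx, 2)
            data.frame(snpA = ids[cmb[1, ]], snpB = ids[cmb[2, ]],
                       r2 = ldDecay^abs(within[cmb[1, ]] - within[cmb[2, ]]),
                       stringsAsFactors = FALSE)
        }))
        ld <- pairs
    } else {
        ld <- data.frame(snpA = character(), snpB = character(),
                         r2 = numeric(), stringsAsFactors = FALSE)
    }

    truth <- data.frame(SNP = ids[causal], or1 = or1[causal],
                        or2 = or2[causal], stringsAsFactors = FALSE)
    list(study1 = s1, study2 = s2, ld = ld, truth = truth)
}

#' Case effect-allele frequency implied by an allelic odds ratio
#'
#' Maps the control (population) effect-allele frequency `f` to the case
#' frequency `f * or / (1 + f * (or - 1))`.
#'
#' @param f control effect-allele frequency.
#' @param or allelic odds ratio.
#' @return case effect-allele frequency.
#' @examples
#' caseFrequency(0.1, 1.2)  # 0.12/1.02
#' @export
caseFrequency <- function(f, or) f * or / (1 + f * (or - 1))
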