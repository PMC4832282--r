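## Canonical summary-statistic dialect: tab-delimited with header
##   SNP CHR BP A1 A2 BETA SE P MAF N_CASES N_CONTROLS
## A1 is the effect allele. An OR column may stand in for BETA and is
## converted to the log scale on read.

.CANONICAL <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "P", "MAF",
                "N_CASES", "N_CONTROLS")
.MANDATORY <- c("SNP", "CHR", "BP", "A1", "A2", "SE")

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-delimited table with a header row, validates
#' each record, and returns a harmonized data.frame in the canonical dialect
#' (`SNP CHR BP A1 A2 BETA SE P MAF N_CASES N_CONTROLS`; `A1` = effect
#' allele). Foreign dialects are handled through `columnMap`, a named
#' character vector mapping canonical names to source column names; mapping
#' `OR` (or `BETA` onto an odds-ratio column via `orScale = TRUE`) converts
#' effects to the log odds ratio.
#'
#' P-values are always recomputed from the two-sided Wald statistic
#' `beta/SE`; when the file carries a P column disagreeing by more than 10%
#' relative, a warning reports the affected SNPs.
#'
#' Rows failing validation (non-positive SE, missing alleles, invalid MAF or
#' position) are dropped and collected, with reasons, in the `"rejected"`
#' attribute of the result.
#'
#' @param path file path.
#' @param columnMap named character vector, canonical name -> source column.
#'   Entries for absent optional columns may be omitted. Use the name `OR`
#'   to point at an odds-ratio effect column.
#' @param recomputeP recompute P from beta/SE (default TRUE; the stored P
#'   column, if any, is only used for the disagreement warning).
#' @return data.frame with attribute `"rejected"` (data.frame of `SNP`,
#'   `reason`).
#' @export
readSummaryStats <- function(path, columnMap = NULL, recomputeP = TRUE) {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    if (!is.null(columnMap)) {
        for (canon in names(columnMap)) {
            src <- columnMap[[canon]]
            if (!src %in% names(dt))
                stop("mapped column '", src, "' not found in ", path)
            names(dt)[names(dt) == src] <- canon
        }
    }
    if ("OR" %in% names(dt) && !"BETA" %in% names(dt)) {
        dt$BETA <- log(dt$OR)
        dt$OR <- NULL
    }
    missing <- setdiff(c(.MANDATORY, "BETA"), names(dt))
    if (length(missing))
        stop("mandatory column(s) missing: ", paste(missing, collapse = ", "))
    for (col in setdiff(.CANONICAL, names(dt))) dt[[col]] <- NA
    dt <- dt[.CANONICAL]
    dt$CHR <- as.character(dt$CHR)
    dt$A1 <- toupper(as.character(dt$A1))
    dt$A2 <- toupper(as.character(dt$A2))
    validateSummaryStats(dt, recomputeP = recomputeP)
}

#' @rdname readSummaryStats
#' @param x a data.frame already holding canonical columns (e.g. built
#'   programmatically); validated the same way as a file read.
#' @export
validateSummaryStats <- function(x, recomputeP = TRUE) {
    reason <- character(nrow(x))
    bad <- function(cond, why) ifelse(cond & reason == "", why, reason)
    reason <- bad(!is.finite(x$SE) | x$SE <= 0, "non-positive SE")
    reason <- bad(!is.finite(x$BETA), "missing effect estimate")
    reason <- bad(!is.finite(x$BP) | x$BP < 1, "invalid position")
    reason <- bad(is.na(x$A1) | is.na(x$A2) | x$A1 == "" | x$A2 == "" |
                  x$A1 == x$A2, "invalid alleles")
    reason <- bad(!is.na(x$MAF) & (x$MAF <= 0 | x$MAF > 0.5), "invalid MAF")
    rejected <- data.frame(SNP = x$SNP[reason != ""],
                           reason = reason[reason != ""],
                           stringsAsFactors = FALSE)
    out <- x[reason == "", , drop = FALSE]
    rownames(out) <- NULL
    if (recomputeP) {
        pWald <- 2 * stats::pnorm(-abs(out$BETA) / out$SE)
        stored <- suppressWarnings(as.numeric(out$P))
        disagree <- !is.na(stored) & stored > 0 &
            abs(stored - pWald) / pWald > 0.10
        if (any(disagree))
            warning(sum(disagree), " SNP(s) with stored P differing >10% ",
                    "from the Wald P (e.g. ",
                    paste(utils::head(out$SNP[disagree], 3), collapse = ", "),
                    "); Wald P used")
        out$P <- pWald
    }
    attr(out, "rejected") <- rejected
    out
}

#' Write a summary-statistics table in the canonical dialect
#'
#' @param x data.frame with canonical columns.
#' @param path output path (tab-delimited, with header).
#' @export
writeSummaryStats <- function(x, path) {
    data.table::fwrite(x[intersect(.CANONICAL, names(x))], path, sep = "\t",
                       quote = FALSE, na = "NA")
    invisible(path)
}

#' Read a long-format LD table
#'
#' Expects tab-delimited columns `SNP_A SNP_B R2` (compatible with PLINK
#' `--r2` inter-chromosomal long output after column selection). Lookups are
#' symmetric and `r2(a, a)` is treated as 1; pairs absent from the table are
#' treated as unlinked (`r2 = 0`).
#'
#' @param path file path.
#' @return data.frame `snpA`, `snpB`, `r2`.
#' @export
readLdTable <- function(path) {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    names(dt) <- toupper(names(dt))
    need <- c("SNP_A", "SNP_B", "R2")
    if (!all(need %in% names(dt)))
        stop("LD table must have columns SNP_A SNP_B R2")
    bad <- !is.finite(dt$R2) | dt$R2 < 0 | dt$R2 > 1
    if (any(bad)) stop("LD table contains r2 values outside [0, 1]")
    data.frame(snpA = as.character(dt$SNP_A), snpB = as.character(dt$SNP_B),
               r2 = dt$R2, stringsAsFactors = FALSE)
}

#' Merge two studies' summary statistics on shared SNPs
#'
#' Intersects the two tables on SNP id and aligns effect alleles: when study
#' 2's effect allele equals study 1's other allele (and vice versa), study
#' 2's effect sign is flipped and the pair flagged `flipped`. Pairs whose
#' allele sets do not match are dropped with reason `"allele mismatch"`.
#' Strand-ambiguous SNPs (A/T, C/G) are kept and aligned by allele label by
#' default; set `dropAmbiguous = TRUE` to exclude them.
#'
#' @param study1,study2 canonical summary-statistic data.frames (see
#'   [readSummaryStats()]).
#' @param dropAmbiguous drop strand-ambiguous (A/T, C/G) SNPs.
#' @return data.frame with one row per shared SNP: `SNP CHR BP A1 A2`,
#'   `BETA1 SE1 P1 BETA2 SE2 P2 flipped`; attribute `"dropped"` lists ids and
#'   reasons.
#' @export
mergeStudies <- function(study1, study2, dropAmbiguous = FALSE) {
    for (s in list(study1, study2))
        if (anyDuplicated(s$SNP))
            stop("duplicate SNP id within one study: ",
                 s$SNP[duplicated(s$SNP)][1])
    shared <- intersect(study1$SNP, study2$SNP)
    s1 <- study1[match(shared, study1$SNP), ]
    s2 <- study2[match(shared, study2$SNP), ]
    dropped <- data.frame(SNP = character(), reason = character(),
                          stringsAsFactors = FALSE)

    ambiguous <- function(a, b) (a == "A" & b == "T") | (a == "T" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
    if (dropAmbiguous) {
        amb <- ambiguous(s1$A1, s1$A2)
        dropped <- rbind(dropped, data.frame(SNP = shared[amb],
                                             reason = "strand-ambiguous"))
        s1 <- s1[!amb, ]; s2 <- s2[!amb, ]; shared <- shared[!amb]
    }
    aligned <- s1$A1 == s2$A1 & s1$A2 == s2$A2
    flippable <- s1$A1 == s2$A2 & s1$A2 == s2$A1
    mismatch <- !aligned & !flippable
    if (any(mismatch))
        dropped <- rbind(dropped, data.frame(SNP = shared[mismatch],
                                             reason = "allele mismatch"))
    keep <- !mismatch
    s1 <- s1[keep, ]; s2 <- s2[keep, ]
    flip <- flippable[keep]
    out <- data.frame(SNP = s1$SNP, CHR = s1$CHR, BP = s1$BP,
                      A1 = s1$A1, A2 = s1$A2,
                      BETA1 = s1$BETA, SE1 = s1$SE, P1 = s1$P,
                      BETA2 = ifelse(flip, -s2$BETA, s2$BETA),
                      SE2 = s2$SE, P2 = s2$P,
                      flipped = flip, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "dropped") <- dropped
    out
}
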