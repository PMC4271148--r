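#' Sensitivity and specificity against an orthogonal truth platform
#'
#' Direct-counting comparator for when per-site truth (typically genotyping
#' array calls) is available. Evaluation is restricted to truth positions:
#' sensitivity is the fraction of truth-variant sites at which the
#' sequencing pipeline also called a variant, specificity the fraction of
#' truth-non-variant sites at which it called none. Truth heterozygotes and
#' homozygous-alternate sites both count as "variant present" — the
#' comparison is dichotomized at the site level.
#'
#' @param calls a \linkS4class{CallSet}.
#' @param truth a non-empty \linkS4class{TruthTable}.
#' @param targets optional \linkS4class{GRanges}: truth sites outside the
#'   sequencing target are excluded before counting.
#' @return A list with \code{sensitivity} (NA when the truth has no variant
#'   sites), \code{specificity} (NA when it has no non-variant sites), and
#'   integer counts \code{TP}, \code{FN}, \code{TN}, \code{FP}. The counts
#'   satisfy TP + FN = number of truth-variant sites and TN + FP = number
#'   of truth-non-variant sites.
#' @examples
#' truth <- TruthTable("chr1", 1:10 * 100L, rep(c(TRUE, FALSE), c(4, 6)))
#' calls <- CallSet("chr1", c(100L, 200L, 300L, 500L), "s1")
#' truthMetrics(calls, truth)
#' @export
truthMetrics <- function(calls, truth, targets = NULL) {
    if (length(truth) == 0L)
        stop("'truth' contains no sites")
    truth <- .subsetToTargets(truth, targets)
    if (length(truth) == 0L)
        stop("no truth sites remain inside the target regions")
    called <- suppressWarnings(GenomicRanges::countOverlaps(
        granges(truth), granges(calls))) > 0L
    vp <- mcols(truth)$variantPresent
    TP <- sum(vp & called); FN <- sum(vp & !called)
    TN <- sum(!vp & !called); FP <- sum(!vp & called)
    list(sensitivity = if (TP + FN > 0L) TP / (TP + FN) else NA_real_,
         specificity = if (TN + FP > 0L) TN / (TN + FP) else NA_real_,
         TP = TP, FN = FN, TN = TN, FP = FP)
}
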