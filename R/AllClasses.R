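#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start width
#' @importFrom IRanges IRanges
NULL

#' FrequencyPanel: polymorphic sites with population allele frequencies
#'
#' A \code{FrequencyPanel} is a \linkS4class{GRanges} of width-1 positions
#' carrying three mandatory metadata columns: \code{ref} and \code{alt}
#' (allele strings) and \code{af}, the population alternate-allele frequency
#' in \eqn{[0, 1]}. It is the panel of sites with known frequencies against
#' which a call set is scored.
#'
#' Frequencies of exactly 0 or 1 are permitted: monomorphic panel sites and
#' positions added under the unreported-site convention (frequency
#' \eqn{10^{-8}}, see \code{\link{augmentUnreportedSites}}) are legitimate
#' inputs and contribute mostly specificity information.
#'
#' @seealso \code{\link{readFrequencyPanel}}, \code{\link{FrequencyPanel}}
#' @aliases FrequencyPanel-class
#' @exportClass FrequencyPanel
setClass("FrequencyPanel", contains = "GRanges")

setValidity("FrequencyPanel", function(object) {
    msg <- character()
    need <- c("ref", "alt", "af")
    missing <- setdiff(need, colnames(mcols(object)))
    if (length(missing))
        return(paste("missing metadata column(s):",
                     paste(missing, collapse = ", ")))
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all sites must have width 1")
        af <- mcols(object)$af
        if (anyNA(af) || any(af < 0) || any(af > 1))
            msg <- c(msg, "'af' must lie in [0, 1] with no NA")
        key <- paste(as.character(seqnames(object)), start(object),
                     mcols(object)$alt)
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated (chrom, pos, alt) entries")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a FrequencyPanel
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt character vectors of reference/alternate alleles.
#' @param af numeric vector of alternate-allele frequencies in \eqn{[0, 1]}.
#'
#' @return A \linkS4class{FrequencyPanel}, sorted by (chrom, pos).
#' @examples
#' FrequencyPanel(c("chr1", "chr2"), c(100L, 50L), c("A", "C"),
#'                c("G", "T"), c(0.2, 0.4))
#' @export
FrequencyPanel <- function(chrom, pos, ref, alt, af) {
    n <- length(pos)
    gr <- GRanges(rep_len(as.character(chrom), n),
                  IRanges(as.integer(pos), width = 1L),
                  ref = rep_len(as.character(ref), n),
                  alt = rep_len(as.character(alt), n),
                  af = rep_len(as.numeric(af), n))
    gr <- GenomicRanges::sort(gr)
    new("FrequencyPanel", gr)
}

#' CallSet: positions where a pipeline called a variant
#'
#' A \code{CallSet} holds, for one individual, the set of genomic positions
#' at which the sequencing pipeline reported a deviation from the reference.
#' A variant here is site-level: any non-reference call counts, regardless
#' of the specific alternate allele. Positions are unique width-1 ranges.
#'
#' @slot individualId single character label for the sample.
#' @seealso \code{\link{readCalls}}, \code{\link{CallSet}}
#' @aliases CallSet-class
#' @exportClass CallSet
setClass("CallSet", contains = "GRanges",
         representation(individualId = "character"),
         prototype(individualId = NA_character_))

setValidity("CallSet", function(object) {
    msg <- character()
    if (length(object@individualId) != 1L)
        msg <- c(msg, "'individualId' must be a single string")
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all called positions must have width 1")
        key <- paste(as.character(seqnames(object)), start(object))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated called positions")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a CallSet
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based called positions; duplicates are
#'   collapsed (set semantics).
#' @param individualId sample label.
#'
#' @return A \linkS4class{CallSet}.
#' @examples
#' CallSet(c("chr1", "chr1"), c(100L, 250L), "NA12878")
#' @export
CallSet <- function(chrom, pos, individualId = NA_character_) {
    chrom <- rep_len(as.character(chrom), length(pos))
    key <- !duplicated(paste(chrom, pos))
    gr <- GRanges(chrom[key], IRanges(as.integer(pos)[key], width = 1L))
    gr <- GenomicRanges::sort(gr)
    new("CallSet", gr, individualId = as.character(individualId))
}

#' TruthTable: orthogonal-platform variant presence/absence
#'
#' A \code{TruthTable} is a \linkS4class{GRanges} of width-1 positions with
#' a logical metadata column \code{variantPresent}: \code{TRUE} where the
#' truth platform (typically a genotyping array) observed any deviation from
#' the reference (heterozygous or homozygous alternate), \code{FALSE} where
#' it observed only the reference. The dichotomy is deliberate: truth
#' comparison is at the site level, not the genotype level.
#'
#' @seealso \code{\link{truthMetrics}}, \code{\link{readTruth}}
#' @aliases TruthTable-class
#' @exportClass TruthTable
setClass("TruthTable", contains = "GRanges")

setValidity("TruthTable", function(object) {
    if (!"variantPresent" %in% colnames(mcols(object)))
        return("missing metadata column 'variantPresent'")
    msg <- character()
    if (length(object)) {
        if (any(width(object) != 1L))
            msg <- c(msg, "all truth positions must have width 1")
        if (!is.logical(mcols(object)$variantPresent) ||
            anyNA(mcols(object)$variantPresent))
            msg <- c(msg, "'variantPresent' must be logical with no NA")
        key <- paste(as.character(seqnames(object)), start(object))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicated truth positions")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a TruthTable
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param variantPresent logical vector: variant observed by the truth
#'   platform at each position.
#'
#' @return A \linkS4class{TruthTable}.
#' @examples
#' TruthTable("chr1", c(10L, 20L), c(TRUE, FALSE))
#' @export
TruthTable <- function(chrom, pos, variantPresent) {
    n <- length(pos)
    gr <- GRanges(rep_len(as.character(chrom), n),
                  IRanges(as.integer(pos), width = 1L),
                  variantPresent = rep_len(as.logical(variantPresent), n))
    gr <- GenomicRanges::sort(gr)
    new("TruthTable", gr)
}

#' PerformanceEstimate: one maximum-likelihood (s, u) fit
#'
#' The result of maximizing the marginal detection likelihood over the
#' per-allele sensitivity \code{s} and specificity \code{u} for one set of
#' site observations.
#'
#' @slot sHat estimated per-allele sensitivity in \eqn{[0, 1]}.
#' @slot uHat estimated per-allele specificity in \eqn{[0, 1]}.
#' @slot nSites number of site observations used.
#' @slot logLik log-likelihood at the optimum.
#' @slot siteSetSeed integer seed of the site set the fit used
#'   (\code{NA} when the observations were supplied directly).
#' @seealso \code{\link{fitMLE}}, \code{\link{estimateIndividual}}
#' @aliases PerformanceEstimate-class
#' @exportClass PerformanceEstimate
setClass("PerformanceEstimate",
         representation(sHat = "numeric", uHat = "numeric",
                        nSites = "integer", logLik = "numeric",
                        siteSetSeed = "integer"),
         prototype(siteSetSeed = NA_integer_))

setValidity("PerformanceEstimate", function(object) {
    msg <- character()
    if (length(object@sHat) != 1L || object@sHat < 0 || object@sHat > 1)
        msg <- c(msg, "'sHat' must be a single value in [0, 1]")
    if (length(object@uHat) != 1L || object@uHat < 0 || object@uHat > 1)
        msg <- c(msg, "'uHat' must be a single value in [0, 1]")
    if (length(object@nSites) != 1L || object@nSites < 1L)
        msg <- c(msg, "'nSites' must be a single count >= 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' EstimateSummary: aggregated estimates across site sets
#'
#' Medians of the per-site-set maximum-likelihood estimates, together with
#' percentile-bootstrap confidence intervals for the mean and the full
#' per-set estimate table. Because the point estimate is a median while the
#' interval is a bootstrap interval for the mean, the interval is not
#' guaranteed to bracket the median (it almost always does in practice).
#'
#' @slot sMedian,uMedian across-set medians of the estimates.
#' @slot sCI,uCI numeric(2) percentile-bootstrap intervals for the mean.
#' @slot nReplicates number of site sets aggregated.
#' @slot estimates \code{data.frame} with one row per site set
#'   (columns \code{setSeed}, \code{nSites}, \code{sHat}, \code{uHat},
#'   \code{logLik}).
#' @seealso \code{\link{estimateIndividual}}
#' @aliases EstimateSummary-class
#' @exportClass EstimateSummary
setClass("EstimateSummary",
         representation(sMedian = "numeric", uMedian = "numeric",
                        sCI = "numeric", uCI = "numeric",
                        nReplicates = "integer", estimates = "data.frame"))

setValidity("EstimateSummary", function(object) {
    msg <- character()
    if (length(object@sCI) != 2L || length(object@uCI) != 2L)
        msg <- c(msg, "confidence intervals must have length 2")
    else if (object@sCI[1L] > object@sCI[2L] ||
             object@uCI[1L] > object@uCI[2L])
        msg <- c(msg, "interval low must not exceed high")
    if (object@nReplicates != nrow(object@estimates))
        msg <- c(msg, "'nReplicates' must match nrow(estimates)")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
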