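## Readers and writers for the exchange formats:
##   calls       : VCF 4.x or 2-column TSV (chrom, pos)
##   panel       : TSV with header `chrom pos ref alt af`
##   targets     : BED (0-based half-open)
##   truth       : TSV with header `chrom pos variant_present` (0/1), or a
##                 VCF with genotypes
## VCF/TSV positions are 1-based; a site at position p lies inside a BED
## interval [a, b) iff a < p <= b.

.subsetToTargets <- function(gr, targets) {
    if (is.null(targets)) return(gr)
    hits <- GenomicRanges::countOverlaps(gr, targets, ignore.strand = TRUE)
    gr[hits > 0L]
}

#' Read target regions from a BED file
#'
#' @param path path to a BED file (0-based half-open intervals).
#' @return A \linkS4class{GRanges} of the target intervals, reduced so that
#'   per-chromosome intervals are non-overlapping.
#' @export
readTargets <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::reduce(gr, ignore.strand = TRUE)
}

#' Read a call set from VCF or TSV
#'
#' A call is any record reporting a deviation from the reference. From a
#' VCF, records whose ALT is non-empty and whose FILTER is among
#' \code{keepFilters} are kept (multi-allelic records count as one called
#' site). From a 2-column TSV (\code{chrom}, \code{pos}, header optional),
#' every row counts. Duplicate positions collapse to one (set semantics).
#'
#' @param path path to a \code{.vcf} (uncompressed or gzipped) or
#'   \code{.tsv}/\code{.txt} file; the format is chosen by extension.
#' @param targets optional \linkS4class{GRanges} of target regions; calls
#'   outside them are dropped.
#' @param keepFilters FILTER values that count as emitted calls; the VCF
#'   missing value \code{"."} is always treated as unfiltered. Set to
#'   \code{NULL} to keep every record.
#' @param individualId sample label stored in the result; defaults to the
#'   file base name.
#' @return A \linkS4class{CallSet}.
#' @export
readCalls <- function(path, targets = NULL, keepFilters = c("PASS", "."),
                      individualId = NULL) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (is.null(individualId))
        individualId <- sub("\\.(vcf|tsv|txt)(\\.gz)?$", "",
                            basename(path), ignore.case = TRUE)
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    if (ext == "vcf") {
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- vcfR::getFIX(v)
        if (is.null(dim(fix)))
            fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
        if (nrow(fix) == 0L)
            return(CallSet(character(), integer(), individualId))
        alt <- fix[, "ALT"]
        filt <- fix[, "FILTER"]
        filt[is.na(filt)] <- "."
        keep <- !is.na(alt) & nzchar(alt) & alt != "."
        if (!is.null(keepFilters))
            keep <- keep & filt %in% keepFilters
        chrom <- fix[keep, "CHROM"]
        pos <- suppressWarnings(as.integer(fix[keep, "POS"]))
        if (anyNA(pos))
            stop("malformed VCF '", path, "': non-numeric POS at data line ",
                 which(is.na(pos))[1L])
    } else if (ext %in% c("tsv", "txt")) {
        d <- .readChromPosTable(path, minCols = 2L)
        chrom <- d[[1L]]
        pos <- d[[2L]]
    } else {
        stop("unknown call-set extension '", ext,
             "': expected .vcf, .tsv or .txt")
    }
    cs <- CallSet(chrom, pos, individualId)
    cs <- new("CallSet", .subsetToTargets(granges(cs), targets),
              individualId = individualId)
    cs
}

.readChromPosTable <- function(path, minCols) {
    d <- tryCatch(
        utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          comment.char = "#", blank.lines.skip = TRUE),
        error = function(e) stop("malformed TSV '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    if (ncol(d) < minCols)
        stop("TSV '", path, "' needs at least ", minCols, " columns")
    ## tolerate an optional header line
    if (is.na(suppressWarnings(as.integer(d[1L, 2L]))))
        d <- d[-1L, , drop = FALSE]
    pos <- suppressWarnings(as.integer(d[[2L]]))
    if (anyNA(pos))
        stop("malformed TSV '", path, "': non-numeric position at line ",
             which(is.na(pos))[1L])
    d[[2L]] <- pos
    d
}

#' Read and write a frequency panel
#'
#' The canonical exchange format for population allele frequencies is a
#' tab-separated file with header \code{chrom pos ref alt af}, positions
#' 1-based and \code{af} the population alternate-allele frequency. A
#' HapMap- or 1000 Genomes-style export reduces to this schema.
#'
#' @param path file path.
#' @param targets optional \linkS4class{GRanges}; panel sites outside the
#'   targets are dropped.
#' @return \code{readFrequencyPanel} returns a \linkS4class{FrequencyPanel}
#'   sorted by (chrom, pos); \code{writeFrequencyPanel} returns \code{path}
#'   invisibly.
#' @export
readFrequencyPanel <- function(path, targets = NULL) {
    d <- tryCatch(
        utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character"),
        error = function(e) stop("malformed panel '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    need <- c("chrom", "pos", "ref", "alt", "af")
    if (!all(need %in% names(d)))
        stop("panel '", path, "' must have header columns: ",
             paste(need, collapse = ", "))
    pos <- suppressWarnings(as.integer(d$pos))
    af <- suppressWarnings(as.numeric(d$af))
    if (anyNA(pos))
        stop("panel '", path, "': non-numeric pos at row ",
             which(is.na(pos))[1L])
    bad <- which(is.na(af) | af < 0 | af > 1)
    if (length(bad))
        stop("panel '", path, "': af outside [0, 1] at row ", bad[1L])
    key <- paste(d$chrom, pos, d$alt)
    if (anyDuplicated(key))
        stop("panel '", path, "': duplicated (chrom, pos, alt) at row ",
             which(duplicated(key))[1L])
    panel <- FrequencyPanel(d$chrom, pos, d$ref, d$alt, af)
    .subsetToTargets(panel, targets)
}

#' @rdname readFrequencyPanel
#' @param panel a \linkS4class{FrequencyPanel} to write.
#' @export
writeFrequencyPanel <- function(panel, path) {
    d <- data.frame(chrom = as.character(seqnames(panel)),
                    pos = start(panel),
                    ref = mcols(panel)$ref, alt = mcols(panel)$alt,
                    af = mcols(panel)$af)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Add unreported sites at an assumed rare frequency
#'
#' Positions at which no variant has ever been reported can still inform
#' the specificity estimate: the convention is to include them with an
#' assumed rare-allele frequency of \eqn{10^{-8}}, so that they contribute
#' essentially pure non-variant (specificity) information. This is how the
#' panel is extended for classes of variation, such as indels, that are
#' underrepresented in frequency databases.
#'
#' @param panel a \linkS4class{FrequencyPanel}.
#' @param chrom,pos vectors giving the extra positions; they must not
#'   collide with existing panel positions.
#' @param assumedFrequency frequency assigned to each added site.
#' @return The extended, re-sorted \linkS4class{FrequencyPanel}; added
#'   sites carry \code{ref = "N"}, \code{alt = "*"}.
#' @examples
#' p <- FrequencyPanel("chr1", 100L, "A", "G", 0.3)
#' augmentUnreportedSites(p, "chr1", c(200L, 300L))
#' @export
augmentUnreportedSites <- function(panel, chrom, pos,
                                   assumedFrequency = 1e-8) {
    .checkProb(assumedFrequency, "assumedFrequency")
    if (length(chrom) != length(pos))
        stop("'chrom' and 'pos' must have the same length")
    key <- paste(chrom, pos)
    existing <- paste(as.character(seqnames(panel)), start(panel))
    if (any(key %in% existing))
        stop("extra positions overlap existing panel sites: ",
             paste(utils::head(key[key %in% existing], 3L), collapse = ", "))
    extra <- FrequencyPanel(chrom, pos, ref = "N", alt = "*",
                            af = assumedFrequency)
    FrequencyPanel(
        c(as.character(seqnames(panel)), as.character(seqnames(extra))),
        c(start(panel), start(extra)),
        c(mcols(panel)$ref, mcols(extra)$ref),
        c(mcols(panel)$alt, mcols(extra)$alt),
        c(mcols(panel)$af, mcols(extra)$af))
}

#' Read and write a truth table
#'
#' The truth TSV has header \code{chrom pos variant_present} with 0/1 in
#' the last column. Alternatively a VCF with genotypes can serve as truth:
#' any genotype containing an alternate allele maps to
#' \code{variant_present = 1}, homozygous-reference genotypes to 0.
#'
#' @param path path to a \code{.tsv}/\code{.txt} truth table or a
#'   \code{.vcf} with a genotype (GT) field.
#' @param targets optional \linkS4class{GRanges}; truth positions outside
#'   are dropped.
#' @param sample for VCF input, which sample column to use (default: the
#'   first).
#' @return \code{readTruth} returns a \linkS4class{TruthTable};
#'   \code{writeTruth} returns \code{path} invisibly.
#' @export
readTruth <- function(path, targets = NULL, sample = 1L) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    if (ext == "vcf") {
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- vcfR::getFIX(v)
        gt <- vcfR::extract.gt(v, element = "GT")
        gtcol <- gt[, sample]
        present <- grepl("[1-9]", gtcol) & !is.na(gtcol)
        tt <- TruthTable(fix[, "CHROM"], as.integer(fix[, "POS"]), present)
    } else {
        d <- .readChromPosTable(path, minCols = 3L)
        vp <- suppressWarnings(as.integer(d[[3L]]))
        if (anyNA(vp) || any(!vp %in% c(0L, 1L)))
            stop("truth '", path, "': variant_present must be 0/1")
        tt <- TruthTable(d[[1L]], d[[2L]], vp == 1L)
    }
    new("TruthTable", .subsetToTargets(tt, targets))
}

#' @rdname readTruth
#' @param truth a \linkS4class{TruthTable} to write.
#' @export
writeTruth <- function(truth, path) {
    d <- data.frame(chrom = as.character(seqnames(truth)),
                    pos = start(truth),
                    variant_present = as.integer(mcols(truth)$variantPresent))
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
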