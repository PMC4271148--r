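## Workflow drivers behind the command-line interface
## (inst/scripts/callaccuracy.R). Each run* function is a thin, testable
## layer over the estimation/truth/simulation/design modules that reads the
## exchange formats and writes a versioned JSON report.

.REPORT_SCHEMA <- "callAccuracy-report/1"

.fileChecksums <- function(paths) {
    paths <- paths[!vapply(paths, is.null, logical(1L))]
    paths <- unlist(paths, use.names = TRUE)
    as.list(tools::md5sum(paths))
}

.summaryAsList <- function(summary) {
    list(s_median = sMedian(summary), u_median = uMedian(summary),
         s_ci = sCI(summary), u_ci = uCI(summary),
         n_site_sets = summary@nReplicates,
         per_set = perSetEstimates(summary))
}

#' Run the frequency-based estimation workflow
#'
#' End-to-end single- or multi-individual estimation: read the call set(s)
#' and frequency panel (optionally restricted to BED targets), estimate
#' \eqn{(s, u)} per individual over LD-thinned random site sets, and write
#' a JSON report with per-individual medians, per-set estimates, bootstrap
#' intervals, the seed, and input checksums. When a second
#' (\code{altFreqs}) panel is supplied — e.g. frequencies from a different
#' population — the estimation is repeated against it and both results are
#' reported side by side, the frequency-misspecification workflow.
#'
#' @param calls character vector of call-set paths (VCF or TSV), one per
#'   individual.
#' @param freqs path to the frequency-panel TSV.
#' @param targets optional path to a BED file of target regions.
#' @param altFreqs optional path to a second frequency panel.
#' @param nSets,minDistance,seed,nBoot see \code{\link{estimateIndividual}}.
#' @param unreportedFreq frequency assumed for called positions absent from
#'   the panel when \code{includeUnreported = TRUE}.
#' @param includeUnreported when \code{TRUE}, called positions not in the
#'   panel (inside the targets) are added at \code{unreportedFreq} — the
#'   convention used to assess variant classes, such as indels, that
#'   frequency databases underreport.
#' @param out optional path; when given, the report is written there as
#'   JSON.
#' @return The report, invisibly, as a nested list.
#' @export
runEstimate <- function(calls, freqs, targets = NULL, altFreqs = NULL,
                        nSets = 1000L, minDistance = 500000L,
                        nBoot = 2000L, seed = 1L, unreportedFreq = 1e-8,
                        includeUnreported = FALSE, out = NULL) {
    tgt <- if (is.null(targets)) NULL else readTargets(targets)
    panel <- readFrequencyPanel(freqs, targets = tgt)
    if (length(panel) == 0L)
        stop("no panel sites overlap the target regions", call. = FALSE)
    altPanel <- if (is.null(altFreqs))
        NULL else readFrequencyPanel(altFreqs, targets = tgt)
    individuals <- list()
    for (i in seq_along(calls)) {
        cs <- readCalls(calls[i], targets = tgt)
        p <- panel
        if (includeUnreported) {
            inPanel <- GenomicRanges::countOverlaps(
                granges(cs), granges(p)) > 0L
            extra <- cs[!inPanel]
            if (length(extra))
                p <- augmentUnreportedSites(
                    p, as.character(seqnames(extra)), start(extra),
                    assumedFrequency = unreportedFreq)
        }
        res <- list(individual = individualId(cs),
                    n_calls = length(cs),
                    n_panel_sites = length(p),
                    estimate = .summaryAsList(estimateIndividual(
                        cs, p, nSets = nSets, minDistance = minDistance,
                        seed = seed, nBoot = nBoot)))
        if (!is.null(altPanel))
            res$estimate_alt_freqs <- .summaryAsList(estimateIndividual(
                cs, altPanel, nSets = nSets, minDistance = minDistance,
                seed = seed, nBoot = nBoot))
        individuals[[length(individuals) + 1L]] <- res
    }
    sMeds <- vapply(individuals,
                    function(x) x$estimate$s_median, numeric(1L))
    uMeds <- vapply(individuals,
                    function(x) x$estimate$u_median, numeric(1L))
    cohort <- list(s_median = median(sMeds), u_median = median(uMeds))
    if (length(sMeds) >= 2L) {
        cohort$s_mean_ci <- bootstrapCI(sMeds, nBoot = nBoot,
                                        seed = .setSeed(seed, 0L))
        cohort$u_mean_ci <- bootstrapCI(uMeds, nBoot = nBoot,
                                        seed = .setSeed(seed, -1L))
    }
    report <- list(
        schema = .REPORT_SCHEMA,
        tool_version = as.character(utils::packageVersion("callAccuracy")),
        seed = seed,
        parameters = list(n_sets = nSets, min_distance = minDistance,
                          n_boot = nBoot,
                          unreported_frequency = unreportedFreq,
                          include_unreported = includeUnreported),
        inputs = .fileChecksums(c(calls, freqs, targets, altFreqs)),
        individuals = individuals,
        cohort = cohort)
    if (!is.null(out))
        jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    invisible(report)
}

#' Run the truth-based comparison workflow
#'
#' @param calls character vector of call-set paths, one per individual.
#' @param truth character vector of truth paths (TSV or VCF with
#'   genotypes), recycled to the length of \code{calls}.
#' @param targets optional BED path restricting the evaluation.
#' @param out optional JSON output path.
#' @return The report, invisibly.
#' @export
runCompareTruth <- function(calls, truth, targets = NULL, out = NULL) {
    tgt <- if (is.null(targets)) NULL else readTargets(targets)
    truth <- rep_len(truth, length(calls))
    individuals <- lapply(seq_along(calls), function(i) {
        cs <- readCalls(calls[i], targets = tgt)
        tt <- readTruth(truth[i], targets = tgt)
        c(list(individual = individualId(cs)), truthMetrics(cs, tt))
    })
    report <- list(
        schema = .REPORT_SCHEMA,
        tool_version = as.character(utils::packageVersion("callAccuracy")),
        inputs = .fileChecksums(c(calls, truth, targets)),
        individuals = individuals)
    if (!is.null(out))
        jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    invisible(report)
}

#' Run the design calculations
#'
#' @param u1,u2,power,alpha see \code{\link{requiredInvariantSites}}.
#' @param specificity,variantRate,sensitivity see \code{\link{fpTpRatio}}.
#' @param out optional JSON output path.
#' @return A list with \code{required_invariant_sites} and
#'   \code{fp_per_true_variant}, invisibly.
#' @export
runDesign <- function(u1 = 0.999, u2 = 0.9999, power = 0.80, alpha = 0.05,
                      specificity = 0.99, variantRate = 0.001,
                      sensitivity = 1, out = NULL) {
    report <- list(
        schema = .REPORT_SCHEMA,
        required_invariant_sites = requiredInvariantSites(
            u1, u2, power = power, alpha = alpha),
        fp_per_true_variant = fpTpRatio(specificity, variantRate,
                                        sensitivity))
    if (!is.null(out))
        jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
    invisible(report)
}
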