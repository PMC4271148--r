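## Synthetic cohort generator with known true (s, u).
##
## The simulator draws per-ALLELE events explicitly — each variant allele
## detected with probability sTrue, each reference allele miscalled with
## probability 1 - uTrue, site called when any event fires — rather than
## using the closed-form site probabilities. Agreement between its
## empirical conditional detection rates and the model formulas is
## therefore a genuine cross-validation, not a tautology.

#' Simulate a cohort of call sets with known performance
#'
#' Generates a frequency panel, per-individual Hardy-Weinberg genotypes,
#' per-individual truth tables, and per-individual call sets produced by a
#' virtual pipeline with true per-allele sensitivity \code{sTrue} and
#' specificity \code{uTrue}.
#'
#' Panel positions are laid out deterministically across 22 synthetic
#' chromosomes (more when the site count would otherwise push positions
#' past the 32-bit coordinate range). The default \code{"sparse"} layout spaces sites 600 kb
#' apart, so LD thinning at 500 kb keeps every site; the \code{"dense"}
#' layout spaces them 100 kb apart to exercise the thinning filter.
#' Frequencies are drawn from \code{freqSampler} (default
#' \eqn{\mathrm{Uniform}(0.01, 0.5)}, a plausible spread for common panel
#' polymorphisms).
#'
#' @param nSites number of panel sites.
#' @param nIndividuals number of simulated individuals.
#' @param sTrue,uTrue true per-allele sensitivity and specificity.
#' @param freqSampler function of one argument \code{n} returning \code{n}
#'   allele frequencies in \eqn{[0, 1]}.
#' @param layout \code{"sparse"} (600 kb spacing) or \code{"dense"}
#'   (100 kb spacing).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A list with elements \code{panel}
#'   (\linkS4class{FrequencyPanel}), \code{genotypes} (integer matrix,
#'   sites x individuals, variant-allele counts 0/1/2), \code{truth} (list
#'   of \linkS4class{TruthTable}) and \code{calls} (list of
#'   \linkS4class{CallSet}).
#' @examples
#' sim <- simulateCohort(nSites = 100, nIndividuals = 2, seed = 1)
#' sim$calls[[1]]
#' @importFrom stats runif rbinom
#' @export
simulateCohort <- function(nSites = 10000L, nIndividuals = 1L,
                           sTrue = 0.95, uTrue = 0.999,
                           freqSampler = function(n) runif(n, 0.01, 0.5),
                           layout = c("sparse", "dense"), seed = 1L) {
    if (nSites < 1L) stop("'nSites' must be >= 1")
    if (nIndividuals < 1L) stop("'nIndividuals' must be >= 1")
    .checkProb(sTrue, "sTrue"); .checkProb(uTrue, "uTrue")
    layout <- match.arg(layout)
    spacing <- if (layout == "sparse") 600000L else 100000L
    set.seed(seed)

    ## 22 synthetic chromosomes by default; more when the per-chromosome
    ## coordinate range would overflow 32-bit positions at this spacing
    perChromMax <- (2147483647L - 1L) %/% spacing
    nChrom <- max(22L, as.integer(ceiling(nSites / perChromMax)))
    chromIdx <- rep(seq_len(nChrom), length.out = nSites)
    within <- (seq_len(nSites) - 1L) %/% nChrom
    stopifnot(max(within) <= perChromMax)
    chrom <- sprintf("chr%d", chromIdx)
    pos <- 1L + within * spacing
    f <- freqSampler(nSites)
    .checkProb(f, "freqSampler output")
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nSites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    panel <- FrequencyPanel(chrom, pos, ref, alt, f)
    ## re-read f in panel sort order (seqlevels chr1..chr22 by appearance)
    ord <- order(chromIdx, pos)
    chrom <- chrom[ord]; pos <- pos[ord]; f <- f[ord]

    genotypes <- matrix(0L, nrow = nSites, ncol = nIndividuals)
    truth <- vector("list", nIndividuals)
    calls <- vector("list", nIndividuals)
    for (k in seq_len(nIndividuals)) {
        g <- rbinom(nSites, 2L, f)          # HWE: variant-allele count
        varDet <- rbinom(nSites, g, sTrue) > 0L
        refMis <- rbinom(nSites, 2L - g, 1 - uTrue) > 0L
        det <- varDet | refMis
        genotypes[, k] <- g
        truth[[k]] <- TruthTable(chrom, pos, g > 0L)
        calls[[k]] <- CallSet(chrom[det], pos[det],
                              individualId = sprintf("sim%02d", k))
    }
    list(panel = panel, genotypes = genotypes, truth = truth, calls = calls)
}

#' Perturb panel frequencies to emulate population misspecification
#'
#' Scoring a call set against allele frequencies from the wrong population
#' biases the estimates but tends to preserve the ranking of pipelines.
#' This helper produces such a misspecified panel by resampling each
#' frequency from a Beta distribution centred on the true value:
#' \eqn{f' \sim \mathrm{Beta}(\kappa f, \kappa(1 - f))} with concentration
#' \eqn{\kappa}. Larger \eqn{\kappa} means milder misspecification.
#'
#' @param panel a \linkS4class{FrequencyPanel}.
#' @param concentration Beta concentration \eqn{\kappa > 0} (default 20).
#' @param seed integer seed.
#' @return A new \linkS4class{FrequencyPanel} with perturbed \code{af};
#'   positions and alleles are unchanged.
#' @examples
#' sim <- simulateCohort(nSites = 50, seed = 1)
#' perturbFrequencies(sim$panel, concentration = 20, seed = 2)
#' @importFrom stats rbeta
#' @export
perturbFrequencies <- function(panel, concentration = 20, seed = 1L) {
    if (concentration <= 0) stop("'concentration' must be > 0")
    set.seed(seed)
    f <- mcols(panel)$af
    a <- concentration * f
    b <- concentration * (1 - f)
    fp <- rbeta(length(f), pmax(a, 1e-12), pmax(b, 1e-12))
    fp[is.na(fp)] <- f[is.na(fp)]
    mcols(panel)$af <- pmin(pmax(fp, 0), 1)
    methods::validObject(panel)
    panel
}

#' Write a simulated cohort to disk
#'
#' Writes the panel as the canonical frequency TSV, each individual's truth
#' as a truth TSV, and each individual's calls as a minimal valid VCF 4.2
#' file (one PASS record per called position).
#'
#' @param sim a cohort as returned by \code{\link{simulateCohort}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a list of the written file paths (\code{panel},
#'   \code{truth}, \code{calls}).
#' @export
writeCohort <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    panelPath <- file.path(dir, "panel.tsv")
    writeFrequencyPanel(sim$panel, panelPath)
    truthPaths <- character(length(sim$truth))
    callPaths <- character(length(sim$calls))
    for (k in seq_along(sim$calls)) {
        id <- individualId(sim$calls[[k]])
        truthPaths[k] <- file.path(dir, sprintf("%s.truth.tsv", id))
        writeTruth(sim$truth[[k]], truthPaths[k])
        callPaths[k] <- file.path(dir, sprintf("%s.vcf", id))
        .writeMinimalVcf(sim$calls[[k]], sim$panel, callPaths[k])
    }
    invisible(list(panel = panelPath, truth = truthPaths,
                   calls = callPaths))
}

.writeMinimalVcf <- function(calls, panel, path) {
    chrom <- as.character(seqnames(calls))
    pos <- start(calls)
    m <- GenomicRanges::match(granges(calls), granges(panel))
    ref <- ifelse(is.na(m), "N", mcols(panel)$ref[m])
    alt <- ifelse(is.na(m), "A", mcols(panel)$alt[m])
    header <- c("##fileformat=VCFv4.2",
                sprintf("##contig=<ID=%s>", unique(chrom)),
                "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, pos, ref, alt)
    writeLines(c(header, body), path)
    invisible(path)
}
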