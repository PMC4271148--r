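## Maximum-likelihood estimation of (s, u) over LD-thinned random site sets.

## Counter-based per-set seed: reproducible for a given (masterSeed, i),
## independent of how many sets are drawn, and always < 2^31.
.setSeed <- function(masterSeed, i) {
    as.integer((as.double(masterSeed %% 2147483647L) * 48271 + i) %%
               2147483647)
}

#' Sample random LD-thinned site sets
#'
#' Nearby variants are in linkage disequilibrium, so their detection events
#' are not independent and cannot all enter one likelihood. Following the
#' thinning rule, a site set may contain two sites only if they lie on
#' different chromosomes or at least \code{minDistance} bases apart
#' (inclusive: a distance of exactly \code{minDistance} is allowed). Each
#' set is built by an independent uniform shuffle of the panel followed by a
#' greedy pass that accepts a site when it is far enough from every
#' already-accepted site on its chromosome.
#'
#' @param panel a \linkS4class{FrequencyPanel} (or any width-1
#'   \linkS4class{GRanges}).
#' @param nSets number of site sets to draw (the reference workflow uses
#'   1000).
#' @param minDistance minimum within-chromosome spacing in bases
#'   (default 500 kb).
#' @param seed master integer seed; per-set seeds are derived from it by a
#'   counter scheme, so results are reproducible and independent of
#'   \code{nSets}.
#' @return A list of \code{nSets} sorted integer vectors indexing into
#'   \code{panel}; each carries its derivation seed as attribute
#'   \code{"seed"}.
#' @examples
#' panel <- FrequencyPanel(rep("chr1", 3), c(1L, 500001L, 1000001L),
#'                         "A", "G", rep(0.2, 3))
#' sampleSiteSets(panel, nSets = 2, seed = 7)
#' @export
sampleSiteSets <- function(panel, nSets = 1000L, minDistance = 500000L,
                           seed = 1L) {
    if (length(panel) == 0L)
        stop("'panel' contains no sites")
    if (nSets < 1L)
        stop("'nSets' must be >= 1")
    if (minDistance < 0)
        stop("'minDistance' must be >= 0")
    chrom <- as.integer(factor(as.character(seqnames(panel))))
    pos <- start(panel)
    lapply(seq_len(nSets), function(i) {
        setSeed <- .setSeed(seed, i)
        idx <- .spacedSubset(chrom, pos, minDistance, setSeed)
        structure(idx, seed = setSeed)
    })
}

.spacedSubset <- function(chrom, pos, minDistance, setSeed) {
    n <- length(pos)
    set.seed(setSeed)
    ord <- sample.int(n)
    keep <- logical(n)
    acc <- vector("list", max(chrom))   # per-chromosome sorted positions
    for (i in ord) {
        ci <- chrom[i]; p <- pos[i]
        a <- acc[[ci]]
        if (is.null(a)) {
            acc[[ci]] <- p; keep[i] <- TRUE; next
        }
        j <- findInterval(p, a)
        if (j >= 1L && p - a[j] < minDistance) next
        if (j < length(a) && a[j + 1L] - p < minDistance) next
        acc[[ci]] <- append(a, p, after = j)
        keep[i] <- TRUE
    }
    which(keep)
}

#' Build site observations by intersecting a panel with a call set
#'
#' Marks each panel site as detected when the call set contains a variant
#' call at exactly that position (site-level matching: the called alternate
#' allele is not compared with the panel allele).
#'
#' @param panel a \linkS4class{FrequencyPanel}.
#' @param calls a \linkS4class{CallSet}.
#' @return A \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{f} and logical \code{detected}, one row per panel site.
#' @export
siteObservations <- function(panel, calls) {
    if (length(panel) == 0L)
        stop("'panel' contains no sites")
    det <- suppressWarnings(
        GenomicRanges::countOverlaps(granges(panel), granges(calls))) > 0L
    data.frame(chrom = as.character(seqnames(panel)), pos = start(panel),
               f = mcols(panel)$af, detected = det)
}

## Objective shared by fitMLE/fitJoint; parameters are clamped into [0,1]
## because the numerical gradient may probe just outside the box.
.negLogLik <- function(par, freq, det) {
    s <- min(max(par[1L], 0), 1)
    u <- min(max(par[2L], 0), 1)
    -logLikelihood(freq, det, s, u)
}

## Analytic gradient of the negative log-likelihood; keeps the bounded
## quasi-Newton accurate to well below the 1e-3 reporting scale.
.negLogLikGrad <- function(par, freq, det) {
    s <- min(max(par[1L], 0), 1)
    u <- min(max(par[2L], 0), 1)
    f <- freq
    p <- pDetectMarginal(f, s, u)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    dpds <- 2 * f^2 * (1 - s) + 2 * f * (1 - f) * u
    dpdu <- -2 * f * (1 - f) * (1 - s) - 2 * u * (1 - f)^2
    w <- ifelse(det, 1 / p, -1 / (1 - p))
    -c(sum(w * dpds), sum(w * dpdu))
}

.MLE_STARTS <- rbind(c(0.5, 0.5), c(0.9, 0.99), c(0.99, 0.9),
                     c(0.99, 0.999), c(0.5, 0.99))

#' Maximum-likelihood estimate of sensitivity and specificity
#'
#' Maximizes \code{\link{logLikelihood}} over \eqn{(s, u) \in [0, 1]^2} by
#' bounded quasi-Newton (\code{optim}, method \code{"L-BFGS-B"}) from five
#' fixed starting points, keeping the best converged optimum. Multiple
#' starts guard against the flat ridge the surface can develop near
#' \eqn{u = 1} when few non-detected common sites are available.
#'
#' @param f numeric vector of panel allele frequencies.
#' @param detected logical vector of site-level detection outcomes.
#' @param siteSetSeed optional integer recorded as the provenance of the
#'   site set behind these observations.
#' @return A \linkS4class{PerformanceEstimate}. Inputs in which every site
#'   was detected (or none was) are permitted but trigger a warning, as the
#'   optimum then typically sits on the boundary of the parameter square.
#' @examples
#' set.seed(1)
#' f <- runif(2000, 0.05, 0.5)
#' det <- runif(2000) < pDetectMarginal(f, s = 0.95, u = 0.999)
#' fitMLE(f, det)
#' @importFrom stats optim
#' @export
fitMLE <- function(f, detected, siteSetSeed = NA_integer_) {
    if (length(f) == 0L)
        stop("no site observations supplied")
    if (length(detected) != length(f))
        stop("'f' and 'detected' must have the same length")
    if (all(detected) || all(!detected))
        warning("all observations are ",
                if (all(detected)) "detected" else "non-detected",
                "; estimates may lie on the boundary of [0, 1]^2")
    best <- NULL
    for (k in seq_len(nrow(.MLE_STARTS))) {
        fit <- optim(.MLE_STARTS[k, ], .negLogLik, gr = .negLogLikGrad,
                     freq = f, det = detected,
                     method = "L-BFGS-B", lower = c(0, 0), upper = c(1, 1),
                     control = list(factr = 1e4))
        if (is.null(best) || fit$value < best$value)
            best <- fit
    }
    s <- min(max(best$par[1L], 0), 1)
    u <- min(max(best$par[2L], 0), 1)
    new("PerformanceEstimate", sHat = s, uHat = u,
        nSites = length(f), logLik = logLikelihood(f, detected, s, u),
        siteSetSeed = as.integer(siteSetSeed))
}

#' Joint fit across several individuals
#'
#' When individuals are independent, the cohort likelihood is the product
#' of the per-individual likelihoods, so its logarithm is the sum of the
#' per-individual log-likelihoods; a single \eqn{(s, u)} maximizing it is
#' obtained by fitting the pooled observations. With one individual this is
#' identical to \code{\link{fitMLE}}.
#'
#' @param observationsList a list with one element per individual; each
#'   element is a \code{data.frame} with columns \code{f} and
#'   \code{detected} (as returned by \code{\link{siteObservations}}).
#' @return A \linkS4class{PerformanceEstimate} for the shared parameters.
#' @export
fitJoint <- function(observationsList) {
    if (!is.list(observationsList) || length(observationsList) == 0L)
        stop("'observationsList' must be a non-empty list")
    f <- unlist(lapply(observationsList, function(d) d$f), use.names = FALSE)
    det <- unlist(lapply(observationsList, function(d) d$detected),
                  use.names = FALSE)
    fitMLE(f, det)
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the supplied values with replacement \code{nBoot} times,
#' computes the mean of each resample and returns the empirical
#' \eqn{(1-\mathrm{level})/2} and \eqn{1-(1-\mathrm{level})/2} quantiles.
#'
#' @param values numeric vector (at least 2 values), e.g. per-individual
#'   sensitivity estimates.
#' @param nBoot number of bootstrap resamples.
#' @param level interval coverage level in (0, 1).
#' @param seed integer seed for the resampling.
#' @return Numeric vector \code{c(low, high)}.
#' @examples
#' bootstrapCI(c(0.95, 0.96, 0.94, 0.97), nBoot = 500, seed = 2)
#' @importFrom stats quantile
#' @export
bootstrapCI <- function(values, nBoot = 2000L, level = 0.95, seed = 1L) {
    if (length(values) < 2L)
        stop("need at least 2 values to bootstrap")
    if (level <= 0 || level >= 1)
        stop("'level' must be in (0, 1)")
    set.seed(seed)
    n <- length(values)
    means <- vapply(seq_len(nBoot),
                    function(i) mean(values[sample.int(n, n, replace = TRUE)]),
                    numeric(1L))
    alpha <- (1 - level) / 2
    unname(quantile(means, c(alpha, 1 - alpha)))
}

#' Estimate performance for one individual over random site sets
#'
#' The full single-individual workflow: intersect the frequency panel with
#' the individual's call set, draw \code{nSets} LD-thinned random site sets,
#' fit \eqn{(s, u)} by maximum likelihood on each, and aggregate by the
#' across-set median. A percentile-bootstrap interval for the mean of the
#' per-set estimates is attached (degenerate when \code{nSets = 1}).
#'
#' @param calls a \linkS4class{CallSet}.
#' @param panel a \linkS4class{FrequencyPanel}; it must share chromosome
#'   names with the calls unless the call set is empty.
#' @inheritParams sampleSiteSets
#' @inheritParams bootstrapCI
#' @return An \linkS4class{EstimateSummary}; the per-set fits are available
#'   through \code{\link{perSetEstimates}}.
#' @examples
#' sim <- simulateCohort(nSites = 500, sTrue = 0.9, uTrue = 0.99, seed = 3)
#' estimateIndividual(sim$calls[[1]], sim$panel, nSets = 3, seed = 3)
#' @importFrom stats median
#' @export
estimateIndividual <- function(calls, panel, nSets = 1000L,
                               minDistance = 500000L, seed = 1L,
                               nBoot = 2000L, level = 0.95) {
    obs <- siteObservations(panel, calls)
    if (length(calls) > 0L &&
        !any(as.character(seqnames(calls)) %in% obs$chrom))
        stop("call set and panel share no chromosome names; ",
             "check reference naming conventions")
    sets <- sampleSiteSets(panel, nSets = nSets, minDistance = minDistance,
                           seed = seed)
    fits <- lapply(sets, function(idx) {
        fitMLE(obs$f[idx], obs$detected[idx],
               siteSetSeed = attr(idx, "seed"))
    })
    est <- data.frame(
        setSeed = vapply(fits, function(x) x@siteSetSeed, integer(1L)),
        nSites = vapply(fits, nSites, integer(1L)),
        sHat = vapply(fits, sHat, numeric(1L)),
        uHat = vapply(fits, uHat, numeric(1L)),
        logLik = vapply(fits, function(x) x@logLik, numeric(1L)))
    sMed <- median(est$sHat)
    uMed <- median(est$uHat)
    if (nrow(est) >= 2L) {
        sci <- bootstrapCI(est$sHat, nBoot = nBoot, level = level,
                           seed = .setSeed(seed, 0L))
        uci <- bootstrapCI(est$uHat, nBoot = nBoot, level = level,
                           seed = .setSeed(seed, -1L))
    } else {
        sci <- c(sMed, sMed); uci <- c(uMed, uMed)
    }
    new("EstimateSummary", sMedian = sMed, uMedian = uMed,
        sCI = sci, uCI = uci, nReplicates = nrow(est), estimates = est)
}
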