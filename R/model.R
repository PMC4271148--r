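## Detection-probability model.
##
## s = per-allele sensitivity, p(variant allele detected | present);
## u = per-allele specificity, p(no call on a reference allele).
## At a diploid site, detection means "any allele event fires", giving the
## three conditional detection probabilities marginalized below over
## Hardy-Weinberg genotype priors.

GENOTYPES <- c("hom_var", "het", "hom_ref")

.checkProb <- function(x, name) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
        stop("'", name, "' must be numeric in [0, 1]", call. = FALSE)
    invisible(x)
}

#' Hardy-Weinberg genotype priors
#'
#' Genotype frequencies implied by an alternate-allele frequency \code{f}
#' under Hardy-Weinberg equilibrium: homozygous alternate \eqn{f^2},
#' heterozygous \eqn{2f(1-f)}, homozygous reference \eqn{(1-f)^2}.
#'
#' @param f numeric vector of alternate-allele frequencies in \eqn{[0, 1]}.
#' @return A numeric matrix with one row per element of \code{f} and
#'   columns \code{hom_var}, \code{het}, \code{hom_ref}; rows sum to 1.
#' @examples
#' genotypePriors(c(0, 0.5, 1))
#' @export
genotypePriors <- function(f) {
    .checkProb(f, "f")
    cbind(hom_var = f^2, het = 2 * f * (1 - f), hom_ref = (1 - f)^2)
}

#' Conditional site-level detection probabilities
#'
#' Probability that a diploid site is called variant, given the genotype and
#' the per-allele performance parameters: each truly present variant allele
#' is detected with probability \code{s}, each reference allele is falsely
#' called with probability \code{1 - u}, and the site is called when any
#' allele event fires. This yields \eqn{s(2-s)} for a homozygous-alternate
#' site, \eqn{s + (1-s)(1-u)} for a heterozygote and \eqn{1 - u^2} for a
#' homozygous-reference site. \code{pNondetectGivenGenotype} returns the
#' complements \eqn{(1-s)^2}, \eqn{(1-s)u} and \eqn{u^2}; the pair sums to
#' 1 for every genotype.
#'
#' @param genotype character vector with values \code{"hom_var"},
#'   \code{"het"} or \code{"hom_ref"}.
#' @param s per-allele sensitivity in \eqn{[0, 1]}.
#' @param u per-allele specificity in \eqn{[0, 1]}.
#' @return Numeric vector of probabilities, one per genotype.
#' @examples
#' pDetectGivenGenotype("het", s = 0.9, u = 0.99)   # 0.901
#' pDetectGivenGenotype(c("hom_var", "hom_ref"), s = 0.95, u = 0.999)
#' @export
pDetectGivenGenotype <- function(genotype, s, u) {
    genotype <- match.arg(genotype, GENOTYPES, several.ok = TRUE)
    .checkProb(s, "s"); .checkProb(u, "u")
    p <- c(hom_var = s * (2 - s),
           het = s + (1 - s) * (1 - u),
           hom_ref = 1 - u^2)
    unname(p[genotype])
}

#' @rdname pDetectGivenGenotype
#' @export
pNondetectGivenGenotype <- function(genotype, s, u) {
    genotype <- match.arg(genotype, GENOTYPES, several.ok = TRUE)
    .checkProb(s, "s"); .checkProb(u, "u")
    p <- c(hom_var = (1 - s)^2, het = (1 - s) * u, hom_ref = u^2)
    unname(p[genotype])
}

#' Genotype-marginalized detection probability
#'
#' Probability that a site with population alternate-allele frequency
#' \code{f} is called variant in a random individual, marginalizing the
#' conditional detection probabilities over the Hardy-Weinberg genotype
#' priors:
#' \deqn{p(D) = f^2 s(2-s) + 2f(1-f)\,[s + (1-s)(1-u)] + (1-f)^2 (1-u^2).}
#'
#' @inheritParams genotypePriors
#' @inheritParams pDetectGivenGenotype
#' @return Numeric vector of detection probabilities, one per element of
#'   \code{f}.
#' @examples
#' pDetectMarginal(0.5, s = 1, u = 1)   # 0.75
#' pDetectMarginal(0, s = 0.95, u = 0.9)  # 1 - 0.9^2
#' @export
pDetectMarginal <- function(f, s, u) {
    .checkProb(f, "f"); .checkProb(s, "s"); .checkProb(u, "u")
    f^2 * s * (2 - s) +
        2 * f * (1 - f) * (s + (1 - s) * (1 - u)) +
        (1 - f)^2 * (1 - u^2)
}

## Probabilities are clamped away from {0, 1} before logs so boundary
## parameters give finite, heavily penalized likelihoods; keeps the bounded
## optimizer stable at the edges of [0,1]^2.
.PROB_CLAMP <- 1e-12

#' Log-likelihood of a set of site observations
#'
#' For sites treated as independent, the likelihood of the observed
#' detection pattern is the product over detected sites of \eqn{p(D_i)} and
#' over non-detected sites of \eqn{1 - p(D_j)}, each marginalized over
#' Hardy-Weinberg genotypes at the site's allele frequency. This function
#' returns its logarithm. Site probabilities are clamped to
#' \eqn{[10^{-12}, 1 - 10^{-12}]} before the log, so parameter values that
#' flatly contradict an observation yield a large finite penalty rather
#' than \code{-Inf}.
#'
#' @param f numeric vector of panel allele frequencies, one per site.
#' @param detected logical vector, same length as \code{f}: was a variant
#'   called at the site?
#' @inheritParams pDetectGivenGenotype
#' @return The log-likelihood (a single numeric value).
#' @examples
#' logLikelihood(0.5, TRUE, s = 1, u = 1)   # log(0.75)
#' @export
logLikelihood <- function(f, detected, s, u) {
    if (length(f) == 0L)
        stop("'f' must contain at least one site observation")
    if (length(detected) != length(f))
        stop("'f' and 'detected' must have the same length")
    if (anyNA(detected) || !is.logical(detected))
        stop("'detected' must be logical with no NA")
    p <- pDetectMarginal(f, s, u)
    p <- pmin(pmax(p, .PROB_CLAMP), 1 - .PROB_CLAMP)
    sum(log(p[detected])) + sum(log1p(-p[!detected]))
}
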