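## Experimental-design calculations: how many invariant positions are
## needed to tell two specificities apart, and the expected false-positive
## burden per true variant.

#' Invariant positions needed to distinguish two specificities
#'
#' Treats false-positive calls at invariant positions as two binomial
#' proportions \eqn{p_i = 1 - u_i} and applies the classical two-proportion
#' normal-approximation sample size
#' \deqn{n = \frac{\left(z_{\alpha/2}\sqrt{2\bar p(1-\bar p)} +
#'   z_{\beta}\sqrt{p_1(1-p_1) + p_2(1-p_2)}\right)^2}{(p_1 - p_2)^2},}
#' returned as the ceiling, per method. For example, distinguishing a
#' specificity of 0.999 from 0.9999 with 80\% power at two-sided
#' \eqn{\alpha = 0.05} requires on the order of ten thousand invariant
#' positions.
#'
#' @param u1,u2 the two specificities to distinguish, in (0, 1), not equal.
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @return Required number of invariant positions per method (integer-
#'   valued numeric). Symmetric in \code{u1}/\code{u2} and increasing as
#'   they approach each other.
#' @examples
#' requiredInvariantSites(0.999, 0.9999)
#' @importFrom stats qnorm
#' @export
requiredInvariantSites <- function(u1, u2, power = 0.80, alpha = 0.05) {
    for (nm in c("u1", "u2", "power", "alpha")) {
        v <- get(nm)
        if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
            stop("'", nm, "' must be a single value in (0, 1)")
    }
    if (u1 == u2)
        stop("'u1' and 'u2' must differ (equal specificities require ",
             "infinitely many sites)")
    p1 <- 1 - u1; p2 <- 1 - u2
    pbar <- (p1 + p2) / 2
    za <- qnorm(1 - alpha / 2)
    zb <- qnorm(power)
    n <- (za * sqrt(2 * pbar * (1 - pbar)) +
          zb * sqrt(p1 * (1 - p1) + p2 * (1 - p2)))^2 / (p1 - p2)^2
    ceiling(n)
}

#' Expected false positives per true variant position
#'
#' At a per-site deviation rate \code{variantRate}, a pipeline with the
#' given site-level specificity produces on average
#' \eqn{(1 - \mathrm{specificity})(1 - \mathrm{variantRate})} false
#' positives per site against \eqn{\mathrm{sensitivity} \times
#' \mathrm{variantRate}} true detections, so the expected validation burden
#' is their ratio. With specificity 0.99 and one true deviation per 1000
#' sites this is about 10 false positives per true variant — the reason
#' practically useful callers need specificities well above 0.99.
#'
#' @param specificity site-level specificity in \eqn{[0, 1]}.
#' @param variantRate per-site frequency of true deviations from the
#'   reference, in (0, 1).
#' @param sensitivity site-level sensitivity in (0, 1]; the default 1
#'   matches the usual back-of-envelope that ignores missed variants.
#' @return The expected ratio of false-positive findings to true variant
#'   positions.
#' @examples
#' fpTpRatio(0.99, 0.001)       # ~10
#' fpTpRatio(1, 0.001)          # 0
#' @export
fpTpRatio <- function(specificity, variantRate, sensitivity = 1) {
    .checkProb(specificity, "specificity")
    if (!is.numeric(variantRate) || variantRate <= 0 || variantRate >= 1)
        stop("'variantRate' must be in (0, 1)")
    if (!is.numeric(sensitivity) || sensitivity <= 0 || sensitivity > 1)
        stop("'sensitivity' must be in (0, 1]")
    (1 - specificity) * (1 - variantRate) / (sensitivity * variantRate)
}
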