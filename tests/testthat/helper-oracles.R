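## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: probabilities are written out from scratch and
## the grid search enumerates the parameter square exhaustively.

## Exhaustive grid search for the (s, u) maximizing the marginal detection
## likelihood; the independent check of the bounded quasi-Newton fit.
gridSearchMLE <- function(f, det, n = 1001L) {
    s <- seq(0, 1, length.out = n)
    u <- seq(0, 1, length.out = n)
    S <- matrix(s, n, n)
    U <- matrix(u, n, n, byrow = TRUE)
    A <- S * (2 - S)
    B <- S + (1 - S) * (1 - U)
    C <- 1 - U^2
    ll <- matrix(0, n, n)
    for (i in seq_along(f)) {
        p <- f[i]^2 * A + 2 * f[i] * (1 - f[i]) * B + (1 - f[i])^2 * C
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        ll <- ll + if (det[i]) log(p) else log1p(-p)
    }
    w <- arrayInd(which.max(ll), dim(ll))
    list(s = s[w[1L]], u = u[w[2L]], logLik = max(ll))
}

## Per-allele Monte-Carlo oracle for the conditional detection
## probabilities: one Bernoulli per allele, site detected if any fires.
mcDetectRate <- function(genotype, s, u, nrep, seed) {
    set.seed(seed)
    nVar <- switch(genotype, hom_var = 2L, het = 1L, hom_ref = 0L)
    varHit <- if (nVar > 0L)
        matrix(runif(nrep * nVar) < s, nrep) else matrix(FALSE, nrep, 1L)
    nRef <- 2L - nVar
    refHit <- if (nRef > 0L)
        matrix(runif(nrep * nRef) < (1 - u), nrep) else
        matrix(FALSE, nrep, 1L)
    mean(rowSums(varHit) + rowSums(refHit) > 0L)
}

## Tiny toy cohort shared by io/cli tests.
toyPanel <- function() {
    FrequencyPanel(chrom = c("chr1", "chr1", "chr2", "chr2", "chr3"),
                   pos = c(1000L, 600000L, 500L, 900000L, 42L),
                   ref = c("A", "C", "G", "T", "A"),
                   alt = c("G", "T", "A", "C", "C"),
                   af = c(0.1, 0.25, 0.4, 0.05, 0.3))
}
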