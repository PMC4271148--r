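test_that("a perfect pipeline calls exactly the truth-variant sites", {
    sim <- simulateCohort(nSites = 300, nIndividuals = 3, sTrue = 1,
                          uTrue = 1, seed = 9)
    for (k in 1:3) {
        vp <- S4Vectors::mcols(sim$truth[[k]])$variantPresent
        truthPos <- paste(
            as.character(GenomicRanges::seqnames(sim$truth[[k]]))[vp],
            GenomicRanges::start(sim$truth[[k]])[vp])
        callPos <- paste(
            as.character(GenomicRanges::seqnames(sim$calls[[k]])),
            GenomicRanges::start(sim$calls[[k]]))
        expect_setequal(callPos, truthPos)
    }
})

test_that("genotypes follow Hardy-Weinberg proportions at fixed f", {
    sim <- simulateCohort(nSites = 100000,
                          freqSampler = function(n) rep(0.5, n),
                          sTrue = 0.9, uTrue = 0.99, seed = 17)
    counts <- tabulate(sim$genotypes[, 1] + 1L, nbins = 3L)
    p <- chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
    expect_gt(p, 0.001)
})

test_that("empirical conditional detection rates match the model formulas", {
    ## the central cross-validation: the simulator draws per-allele events,
    ## the model states closed forms; they must agree within MC error
    s <- 0.9; u <- 0.995
    sim <- simulateCohort(nSites = 100000, sTrue = s, uTrue = u,
                          freqSampler = function(n) runif(n, 0.05, 0.95),
                          seed = 23)
    obs <- siteObservations(sim$panel, sim$calls[[1]])
    g <- sim$genotypes[, 1]
    expected <- c(pDetectGivenGenotype("hom_ref", s, u),
                  pDetectGivenGenotype("het", s, u),
                  pDetectGivenGenotype("hom_var", s, u))
    for (gg in 0:2) {
        n <- sum(g == gg)
        emp <- mean(obs$detected[g == gg])
        p <- expected[gg + 1L]
        se <- sqrt(p * (1 - p) / n)
        expect_lt(abs(emp - p), 3 * se,
                  label = sprintf("genotype %d (n=%d)", gg, n))
    }
})

test_that("the simulator is deterministic given a seed", {
    a <- simulateCohort(nSites = 200, nIndividuals = 2, seed = 33)
    b <- simulateCohort(nSites = 200, nIndividuals = 2, seed = 33)
    expect_identical(a$genotypes, b$genotypes)
    expect_identical(GenomicRanges::start(a$calls[[2]]),
                     GenomicRanges::start(b$calls[[2]]))
    expect_identical(S4Vectors::mcols(a$panel)$af,
                     S4Vectors::mcols(b$panel)$af)
    d <- simulateCohort(nSites = 200, nIndividuals = 2, seed = 34)
    expect_false(identical(a$genotypes, d$genotypes))
})

test_that("layouts control spacing and frequency perturbation is centred", {
    sparse <- simulateCohort(nSites = 100, seed = 3)
    posByChrom <- split(GenomicRanges::start(sparse$panel),
                        as.character(GenomicRanges::seqnames(sparse$panel)))
    expect_true(all(unlist(lapply(posByChrom, function(p)
        length(p) < 2 || all(diff(sort(p)) == 600000L)))))
    dense <- simulateCohort(nSites = 100, layout = "dense", seed = 3)
    posByChrom <- split(GenomicRanges::start(dense$panel),
                        as.character(GenomicRanges::seqnames(dense$panel)))
    expect_true(all(unlist(lapply(posByChrom, function(p)
        length(p) < 2 || all(diff(sort(p)) == 100000L)))))

    pert <- perturbFrequencies(sparse$panel, concentration = 20, seed = 4)
    f0 <- S4Vectors::mcols(sparse$panel)$af
    f1 <- S4Vectors::mcols(pert)$af
    expect_true(all(f1 >= 0 & f1 <= 1))
    expect_false(identical(f0, f1))
    ## Beta(kf, k(1-f)) has mean f: the average shift is small
    expect_lt(abs(mean(f1 - f0)), 0.05)
})

test_that("writeCohort emits readable panel, truth and VCF files", {
    sim <- simulateCohort(nSites = 60, nIndividuals = 2, sTrue = 0.9,
                          uTrue = 0.99, seed = 12)
    dir <- tempfile("cohort")
    paths <- writeCohort(sim, dir)
    panel <- readFrequencyPanel(paths$panel)
    expect_identical(length(panel), 60L)
    tt <- readTruth(paths$truth[1])
    expect_identical(S4Vectors::mcols(tt)$variantPresent,
                     S4Vectors::mcols(sim$truth[[1]])$variantPresent)
    cs <- readCalls(paths$calls[2])
    expect_setequal(GenomicRanges::start(cs),
                    GenomicRanges::start(sim$calls[[2]]))
})
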