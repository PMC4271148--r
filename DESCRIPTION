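Package: callAccuracy
Title: Estimating Variant-Calling Sensitivity and Specificity from
    Population Allele Frequencies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A maximum-likelihood framework for assessing the performance of
    a next-generation sequencing variant-calling experiment without an
    orthogonal truth platform. Given a per-individual set of called variant
    positions and a panel of sites with known population alternate-allele
    frequencies, the per-allele sensitivity and specificity of the pipeline
    are estimated by maximizing a Hardy-Weinberg-marginalized likelihood
    over random site sets thinned for linkage disequilibrium, with median
    aggregation and bootstrap confidence intervals. Includes a truth-based
    (genotyping-array style) comparator, a synthetic cohort simulator with
    known true parameters, and experimental-design utilities (two-proportion
    sample-size and false-positive burden calculations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Sequencing, VariantDetection, QualityControl, Software
RoxygenNote: 7.3.3
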