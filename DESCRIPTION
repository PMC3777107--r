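Package: ptvbayes
Title: Bayesian Association Testing of Protein-Truncating Variants and
    Quantitative Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gene-based association testing between protein-truncating
    variants (PTVs) and quantitative traits in a Bayesian model-comparison
    framework. Implements the similar-effects model (SEM), in which all PTV
    carriers in a gene share one mean shift on the standardized trait scale,
    and the grouped-effects model informed by predicted nonsense-mediated
    decay (GEM-NMD), which averages over assignments of variants to two
    opposite-effect groups weighted by NMD predictions from the 50-bp rule.
    Closed-form Bayes factors and effect-size posteriors, frequentist
    calibration of the Bayes factor as a test statistic (analytic critical
    values and p-values for SEM, Monte-Carlo for GEM-NMD), power and
    sample-size calculators, scenario simulators, and readers for VCF
    genotypes, phenotype tables and transcript exon models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
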