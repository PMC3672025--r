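Package: nextpeak
Title: Strand-Aware Normal-Exponential Two-Peak Model for ChIP-Seq Peak
    Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls transcription-factor binding peaks from mapped ChIP-seq
    tags with a generative model: cross-link positions are normal around the
    binding site, shearing distances are exponential, and the resulting
    mirrored exponentially-modified-Gaussian tag densities drive a
    per-position Poisson likelihood in which unmappable genomic positions
    are censored. Provides per-region maximum-likelihood estimates of the
    binding location, binding intensity and local background with asymptotic
    standard errors, a likelihood-ratio binding test, a saturated-model
    goodness-of-fit screen for PCR spikes and multiple binding events, exact
    PSSM motif p-values by score-distribution convolution for parameter
    training and evaluation, and a simulator reproducing the assumed
    data-generating process.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
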