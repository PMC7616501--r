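Package: gainTiming
Title: Timing Copy-Number Gains and Whole-Genome Duplication in Tumors
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the sequence and mutation-time placement of clonal
    copy-number gains, including those forming complex allele-specific
    states, from single-sample bulk whole-genome sequencing of tumors.
    Enumerates all candidate gain-route histories (paired per-allele
    binary gain trees with at most one whole-genome duplication),
    scores them with a binomial mixture likelihood over SNV
    multiplicities, and samples a joint posterior over routes, gain
    times, and a sample-shared whole-genome duplication time. Includes
    a whole-genome duplication caller, an event-count penalty against
    non-parsimonious histories, a tumor simulator with known ground
    truth, and cohort-level analyses of chromosomal-instability
    history relative to genome doubling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    yaml,
    optparse,
    knitr,
    rmarkdown
biocViews: CopyNumberVariation, SomaticMutation, Bayesian, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
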