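Package: HiCbinom
Title: Binomial Significance Testing for Hi-C Interaction Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls statistically significant chromatin interactions from
    mapped Hi-C read pairs using a coverage-product binomial null model.
    Relative sequence coverage of each genomic bin is taken to absorb known
    and unknown experimental biases; the probability that a random ligation
    links two bins is the product of their relative coverages, and observed
    pair counts are tested against the cumulative binomial with
    Benjamini-Hochberg control over all bin pairs. Includes in-silico
    restriction digestion, read-pair artefact filtering, sparse contact
    binning, a random-ligation simulator with bias weights and spike-in
    truth sets, and replicate-concordance tools.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: HiC, Epigenetics, Sequencing, StatisticalMethod
RoxygenNote: 7.3.3
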