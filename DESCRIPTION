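Package: pdxfidelity
Title: Genomic Fidelity of Patient-Derived Xenografts from Germline-Tumor-Xenograft Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses how faithfully patient-derived xenograft (PDX) models
    preserve the somatic mutation landscape of the primary tumors they were
    derived from. Reads matched germline/primary/PDX variant calls (VCF or a
    harmonized tab-separated table), applies depth, mapping-quality,
    base-quality, consequence and germline-polymorphism filters, classifies
    each somatic variant as shared, newly detected in the PDX, or newly
    undetected in the PDX, and summarizes counts, median allele fractions,
    gene-list hits and the transition/transversion spectrum. Gene-level copy
    number categories derived from CNVkit-style segment files are compared
    between primary and PDX samples. A clonal-engraftment simulator with
    subclone bottleneck loss, transition-biased de novo PDX mutations and
    binomial read sampling provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    jsonlite,
    yaml,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
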