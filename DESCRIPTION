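Package: strainref
Title: Strain-Specific Reference Genome Construction and Coordinate Liftover
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds strain-specific reference genomes from cohort variant
    calls. Classifies VCF sites into uniform (fixed differences from the
    base reference) and non-uniform (segregating within the cohort)
    classes with GATK-style hard filters, filters germline transposable
    element insertion and absence calls, applies the resulting edit plan
    to a base genome with N-masking of segregating SNPs, and emits exact
    UCSC chain files relating the two coordinate systems. Includes
    liftover of positions, intervals, VCF and GTF annotation through
    those chains, the closed-form genotype-configuration bias probability
    model with an exhaustive enumeration oracle, allele-detection power,
    an asymptotic SNP-discovery saturation curve fit, peak
    reproducibility QC with shuffled controls and Fisher enrichment, a
    Poisson-scan SNP hotspot test, and seeded synthetic-data generators
    for every input type.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    seqinr,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    BiocGenerics,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
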