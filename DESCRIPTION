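Package: EMSscreen
Title: Gene Identification in EMS Mutagenesis Screens from Whole-Genome
    Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline toolkit for mapping causative genes in forward genetic
    screens of ethyl methanesulfonate (EMS) mutagenized Drosophila strains
    from whole-genome variant calls. Implements a step-wise variant
    filtering cascade (genotype and site quality, SNV restriction,
    G/C-to-A/T transition enrichment, background-strain subtraction,
    conservation-score prioritization, region restriction), an internal
    variant effect annotator against GFF3 gene models, a cross-sample
    backfilled cohort genotype matrix with anonymous frequency counts, and
    gene-level intersection across non-complementing mutant strains.
    Includes a synthetic screen simulator (reference, gene models,
    conservation track, background and mutant strains with a planted
    causative gene) so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
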