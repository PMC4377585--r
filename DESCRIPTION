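Package: snpreanno
Title: Integrative Re-Annotation of Trait-Associated SNPs Across Gene
    Annotation Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies single-nucleotide variants against a baseline and
    multiple alternative transcript-annotation sets, calls codon-level coding
    consequences for CDS hits, computes cross-database re-annotation deltas
    for variants that the baseline annotation calls intronic or intergenic,
    profiles overlap with regulatory-feature tracks, and applies an
    expressed-gene filter based on the posterior standard deviation of
    expression estimates. Ships a deterministic synthetic-fixture generator
    (genome, discordant annotation sets, variants, regulatory tracks and
    expression tables with full ground truth) and a command-line front-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    seqinr,
    SummarizedExperiment,
    VariantAnnotation,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
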