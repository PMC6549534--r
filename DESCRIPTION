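Package: methcascade
Title: Integrative Expression-Methylation Filter Cascades for
    Epigenetically Driven Gene Nomination
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for nominating epigenetically driven genes from
    stage-wise multi-omics profiles of progressive liver disease.
    Implements CpG-island detection in promoter sequences under the
    classical length/GC/observed-expected CpG criteria, MeDIP-style
    percent-methylation quantitation with a control-tissue threshold,
    H3K4me3 fold-enrichment filtering, stage-wise differential expression
    with Benjamini-Hochberg correction, 2^-ddCt relative quantitation,
    and the two inverse-correlation filter cascades that single out
    concordantly hypomethylated/over-expressed (or hypermethylated/
    down-regulated) candidate genes. A fully seeded synthetic multi-omics
    generator with a planted ground truth makes every stage testable
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, DifferentialExpression,
    GeneRegulation, Software
RoxygenNote: 7.3.3
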