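Package: gv1scan
Title: Linkage, Copy-Number and Expression Analysis of the Mouse Gv1 Locus Region
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting a trait locus in an inbred-mouse cross, built
    around the identification of KRAB zinc-finger controllers of endogenous
    murine leukemia virus (MLV) expression. Implements N2 backcross linkage
    mapping with LOD scoring and genetic-to-physical peak interpolation,
    windowed read-depth-ratio copy-number profiling with median-filter
    segmentation and median-absolute-error strain clustering, splice-acceptor
    consensus (N[C/T]AG|G) classification and variant-impact calls,
    assembly-versus-reference alignment-segment filtering with duplicated- and
    unique-region detection and BAC end-overlap scaffolding, and per-locus ERV
    expression analysis with a permutation test, Benjamini-Hochberg correction
    and subclass fold summaries. A synthetic-data module generates every input
    the pipeline consumes so that all stages are testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    optparse
Config/testthat/edition: 3
biocViews: CopyNumberVariation, LinkageDisequilibrium, GeneExpression,
    Sequencing, Coverage, Clustering
RoxygenNote: 7.3.3
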