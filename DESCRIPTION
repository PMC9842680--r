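Package: methcode
Title: Cross-Species RRBS Methylation Analysis with Reference-Free
    Calling and Sequence-Based Methylation Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative DNA methylation analysis from reduced
    representation bisulfite sequencing (RRBS) without reference genomes.
    Includes in silico restriction digest and coverage simulation,
    reference-free consensus fragment construction with unconverted-library
    cytosine recovery, methylation calling, coverage-based fragment quality
    flags, methylation erosion statistics (proportion of discordant reads),
    sequence-composition features with phylogeny-aware regression models,
    k-mer classifiers of locus-level methylation state with cross-species
    transfer and inverted-species detection, tissue differential methylation
    with motif enrichment, and gene-centric promoter methylation analysis in
    a shared ortholog space. A synthetic data generator (species trees,
    annotated genomes, planted sequence-to-methylation rules, bisulfite read
    simulation) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    data.table,
    igraph,
    kernlab,
    Matrix,
    methods,
    nlme,
    rpart,
    stats,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
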