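Package: fibroqtl
Title: QTL Mapping and Candidate-Gene Networks for Liver Fibrosis in
    Recombinant Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A systems-genetics toolkit for mapping quantitative trait loci
    (QTLs) of liver fibrosis phenotypes and liver gene expression in
    recombinant inbred (RI) mouse panels such as the BXD set. Implements
    Haley-Knott regression genome scans with composite interval mapping,
    permutation-based genome-wide significance thresholds, 1.5-LOD support
    intervals, expression QTL (eQTL) mapping with cis/trans classification,
    a three-criterion candidate-gene selection funnel, and construction of
    candidate-gene co-expression networks and signed QTL heatmaps. Ships a
    synthetic RI-panel generator (genotypes, replicated phenotypes,
    expression matrices with planted cis/trans effects) so the whole
    pipeline can be exercised against known truth, plus readers and writers
    for GeneNetwork-style genotype, phenotype, annotation and expression
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
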