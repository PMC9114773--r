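Package: tmekit
Title: Receptor-Ligand Communication Scoring and Multiplex
    Immunofluorescence Quantification for Tumor Microenvironment Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two complementary analyses of the tumor
    microenvironment. First, a receptor-ligand communication scoring
    pipeline for single-cell RNA-seq: per-cell log2 normalization, a
    two-part (hurdle) likelihood-ratio differential-expression test of
    each (cell type, sample) stratum against the pooled background,
    Benjamini-Hochberg correction, interaction scores defined as the log2
    product of ligand and receptor fold changes, and a replicate
    consistency filter that requires significance in every sample of a
    condition group. Second, a multiplex immunofluorescence
    quantification pipeline: channel thresholding to binary masks,
    co-positivity mask combination for fibroblast subtypes, area
    normalization to a tumor marker mask, and two-group Student's t
    comparison. A synthetic-data module generates negative-binomial
    count matrices with dropout and planted fold changes, interaction
    priors, and multichannel images with known ground truth, so that
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
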