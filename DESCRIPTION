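Package: ovarioleEvo
Title: Molecular Evolution of Ovariole-Number Genes in Drosophila
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A multilayered molecular-evolution toolkit linking protein-coding
    divergence of ovariole-related genes to interspecies divergence in
    Drosophila ovariole number. Implements a Goldman-Yang codon substitution
    engine with Felsenstein pruning likelihoods and fits for the M0 (single
    dN/dS), free-ratio (per-branch dN/dS) and branch-site (model A) models
    with the chi-squared likelihood ratio test of positive selection;
    sentinel-aware per-branch rate tables; the tau index of expression
    specificity with average-linkage clustering of cell-type profiles;
    fold-over-genome-median gene screens with auditable criteria traces;
    one-tailed chi-squared enrichment tests of positive-selection frequency;
    phylogenetic generalized least squares under Brownian motion that
    predicts a tip phenotype from per-branch dN/dS; and generative
    simulators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
biocViews: Phylogenetics, SequenceAnalysis, GeneExpression, Regression
RoxygenNote: 7.3.3
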