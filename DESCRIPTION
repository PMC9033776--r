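Package: syndge
Title: Synergy-Aware Differential Expression for Two-Factor Perturbation RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bulk RNA-seq studies crossing a disease
    contrast with a drug perturbation (e.g. schizophrenia hiPSC neurons with
    and without the BET-protein inhibitor JQ1). Implements count filtering,
    TMM normalization, log2-CPM conversion, voom-type mean-variance precision
    weights, per-gene weighted linear models on a cell-means group coding,
    empirical-Bayes moderated contrasts with FDR control, an additive-effect
    model with a synergistic interaction contrast and standard-error-threshold
    gene categorization, competitive gene-set enrichment with an inter-gene
    correlation variance-inflation factor, hypergeometric over-representation
    analysis, unsigned weighted co-expression modules (topological overlap,
    static tree cut, eigengene merging, module-trait association), promoter
    RPKM rank-correlation, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
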