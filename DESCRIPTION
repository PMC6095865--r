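Package: darr
Title: Differential Dopamine Response Analysis for Paired Case-Control Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification, quality control and statistical analysis of paired
    baseline versus dopamine-stimulated RNA-seq expression in a case-control
    design. Implements RPKM calculation, quantile normalization, expressed-gene
    filtering, sample-level QC (sex-marker concordance, genotype concordance,
    completion rates, correlation- and PCA-based outlier detection), covariate
    residualization, paired differential-expression testing with fold changes,
    rank-based inverse-normal transformation, case-control association of
    expression and of the per-subject perturbation response, expression-PC
    adjustment, Benjamini-Hochberg FDR, and two-sided Fisher exact gene-set
    enrichment with tabular reporting. Includes a negative-binomial simulator
    of paired case-control expression data with planted effects for
    calibration and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
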