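Package: roiomics
Title: Spatial Multi-Omic Analysis of ROI-Level Transcriptomes and Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for region-of-interest (ROI) resolved tumor
    multi-omics, modeled on digital spatial profiling studies that pair
    probe-based transcriptomic counts from small regions with label-free
    proteomic intensities from larger regions. Provides probe-level quality
    control, negative-probe limits of quantitation and third-quartile (Q3)
    normalization for counts; log transformation, global-median centering,
    completeness filtering and low-abundance (missing-not-at-random)
    imputation for protein intensities; rank-based single-sample gene-set
    scoring; bootstrap consensus clustering with partitioning around medoids
    on Pearson distance; per-feature linear mixed models with a patient
    random intercept and tailored significance rules; one-tailed Fisher
    overrepresentation and pre-ranked gene-set enrichment analysis;
    cross-omic correlation after ROI aggregation; coefficient-of-variation
    screening for intratumoral heterogeneity; constrained log-scale cell-type
    deconvolution with a negative-probe background; and stratified Cox
    survival models on patient-level expression summaries. A seeded synthetic
    cohort generator with planted ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    lme4,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
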