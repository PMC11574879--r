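Package: tmeQuant
Title: Quantitative Tumor-Microenvironment Profiling from Multiplex
    Immunohistochemistry Cell Tables
Version: 0.1.0
Authors@R:
    person("TME", "Quant Developers", email = "tmequant@example.org",
           role = c("aut", "cre"))
Description: Tools for compartment-stratified quantification of the tumor
    microenvironment from segmented multiplex immunohistochemistry (mIHC)
    cell tables: kernel-density marker gating, declarative combinatorial
    phenotyping with subset-retention filtering, cell densities per mm2 and
    immune-activation ratio metrics, zero/tie-corrected Mann-Whitney group
    comparisons with Holm and FDR adjustment, Spearman co-infiltration
    matrices, Kaplan-Meier/Cox prognostic stratification including
    interaction subgroup analyses, and single-sample gene-set (ssGSEA)
    scoring of fibroblast signatures. Ships a seeded synthetic cohort
    generator emulating a two-group (desmoplastic vs non-desmoplastic
    growth pattern) liver-metastasis study so every stage is testable
    without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
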