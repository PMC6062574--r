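Package: umisense
Title: Sensitivity, Quality Control and Power Analysis for UMI-Based
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("UMIsense", "Developers", email = "umisense@example.org",
           role = c("aut", "cre"))
Description: Tools for benchmarking unique-molecular-identifier (UMI) based
    single-cell RNA-seq protocols. Provides a molecule-level synthetic data
    generator (negative-binomial expression, binomial capture, uneven PCR
    amplification, fixed-depth sequencing, ERCC-like spike-in ladders,
    doublets and barcode crosstalk), spike-in based sensitivity estimation
    via binomial logistic regression (molecules needed for 50% detection),
    cellular mRNA-content estimation, cell-level quality-control filters,
    species-mixing crosstalk quantification, exact read-depth downsampling
    with saturation statistics, and negative-binomial power simulations for
    two-group differential expression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
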