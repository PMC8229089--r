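Package: methmr
Title: Summary-Statistics Mendelian Randomization for Methylation-Trait
    Integration
Version: 0.1.0
Authors@R:
    person("methmr", "authors", email = "methmr@example.org", role = c("aut", "cre"))
Description: Tools to identify DNA methylation sites that causally contribute
    to a complex trait from molecular QTL and GWAS summary statistics. The
    package implements single-variant colocalization (SMR statistic) with a
    heterogeneity test that separates pleiotropy from linkage (HEIDI),
    LD-aware multi-SNP Mendelian randomization by generalized least squares
    over per-SNP Wald ratios with pleiotropic-outlier removal, a
    reverse-causation filter based on swapping exposure and outcome,
    expression-mediation chains (methylation to expression to trait), and
    positional matching of rare variants to mQTLs. A synthetic-data module
    generates two-sample cohorts with block LD and known causal structure
    (causal, pleiotropy, linkage, reverse-causation and null scenarios) so
    that every stage of the pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
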