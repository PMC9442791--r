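Package: PDXphos
Title: Multi-Plex TMT Proteomics and Phosphoproteomics Analysis for PDX
    Cohorts
Version: 0.1.0
Authors@R:
    person("PDXphos", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Downstream quantitative analysis of multi-plex isobaric (TMT)
    proteomics and phosphoproteomics experiments on patient-derived
    xenograft (PDX) cohorts: human-unique peptide filtering and protein
    rollup, three-stage cross-plex normalization (sample loading, internal
    reference standard, trimmed mean of M-values), phosphosite
    condensation, one-way ANOVA with Tukey post-hoc and
    Benjamini-Hochberg correction, single-sample and ranked gene set
    enrichment, kinase activity inference from kinase-substrate networks
    with an MCC-optimized prediction-score cutoff, and drug-sensitivity
    correlation signatures.  Includes a synthetic-data generator with
    planted ground truth so that every stage of the pipeline can be
    validated without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
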