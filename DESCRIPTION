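Package: hfeRisk
Title: Regional Genetic Risk and Diagnosed Prevalence of Hereditary
    Haemochromatosis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates HFE pathogenic allele frequencies (p.Cys282Tyr and
    p.His63Asp) by region or ancestry group, predicts risk-genotype
    frequencies under Hardy-Weinberg equilibrium at a triallelic locus,
    combines them with genotype penetrances into a regional genetic risk of
    haemochromatosis, and compares that risk against the prevalence of
    clinical diagnoses (ICD-10 E83.1) to rank regions by apparent
    under-diagnosis.  Includes density-based selection of ancestry core
    clusters on principal-component coordinates, community detection on
    identity-by-descent sharing graphs, and a synthetic-cohort generator so
    the whole pipeline is testable without access-controlled biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
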