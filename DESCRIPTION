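Package: pdl1time
Title: PD-L1 Scoring Algorithms and Tumor Immune Microenvironment Phenotyping
    in Muscle-Invasive Bladder Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the three clinically applied PD-L1 scoring algorithms
    (combined positive score CPS10, Ventana IC5, and the TCarea25/ICarea25 rule),
    cross-assay consensus scores over the SP142, SP263, 22C3 and 28-8 companion
    diagnostic assays, a combined immune cell infiltration score (ICIS) from
    digital immune-marker cell densities, WPGMA hierarchical clustering of
    patients into four tumor immune microenvironment phenotypes, inter-algorithm
    concordance statistics (overall percentage agreement, Venn partitioning,
    phenotype coverage), a CD8/sTILs rescue rule for PD-L1-negative inflamed
    tumors, and Kaplan-Meier / Cox proportional-hazards survival analysis by
    PD-L1 status and phenotype. A synthetic-cohort generator emulates the
    statistical structure of a 193-patient muscle-invasive bladder cancer tissue
    microarray cohort with four spatially profiled immune phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
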