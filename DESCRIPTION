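Package: amdseg
Title: Two-Step Clustering and Risk-Profile Segmentation of Neovascular AMD Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Case-only segmentation of neovascular age-related macular
    degeneration (AMD) patients by cardiovascular risk factors and AMD-risk
    genotypes (CFH rs1061170, ARMS2/HTRA1 rs1049331). Implements a two-stage
    mixed-type clustering pipeline: a BIRCH-style cluster-feature tree for
    pre-clustering followed by agglomerative merging under the log-likelihood
    distance with BIC-guided selection of the number of clusters. Includes
    questionnaire-derived variable construction (pack-years, decades of alcohol
    use, BMI with outlier truncation, medication-based hypertension and
    hypercholesterolemia histories), complete-case cohort assembly, per-cluster
    profiling with one-way ANOVA F statistics computed from raw records or from
    printed summary statistics, and a seeded synthetic-cohort generator that
    emulates a published four-cluster 253-patient cohort for validation and
    power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
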