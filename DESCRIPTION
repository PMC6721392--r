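Package: mixstrat
Title: Multimodal Biomarker Stratification of Dementia Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stratifies memory-clinic patients into biologically defined
    dementia groups - subcortical ischemic vascular disease (SIVD),
    Alzheimer's disease (AD), mixed dementia (MX), multiple infarcts (MI)
    and leukoaraiosis (LA) - from cerebrospinal-fluid analytes
    (amyloid-beta 42/40 ratio, phosphorylated tau, matrix
    metalloproteinases, albumin index), white-matter mean-diffusivity
    z-scores from diffusion tensor imaging, and composite
    neuropsychological T-scores. Provides a dual-axis rule-based
    classifier (CSF Alzheimer axis crossed with a DTI vascular axis) and
    a feature-matrix matcher, composite cognitive scoring, control-based
    diffusivity normalization, nonparametric group comparisons
    (Kruskal-Wallis, pairwise Mann-Whitney with family-wise correction),
    clinical-versus-biological cross-tabulation, and a calibrated
    synthetic-cohort generator so the full pipeline runs without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
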