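Package: pedpet
Title: Age-Specific Pediatric FDG-PET Templates and Single-Subject
    Hypometabolism Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for observer-independent analysis of pediatric
    18F-FDG-PET brain scans in epilepsy presurgical assessment. Builds
    age-stratified PET templates from a control cohort by a two-pass
    affine registration and averaging procedure, maps single-patient
    hypometabolism by voxelwise comparison against an age-matched control
    database (per-voxel t-maps, cluster-extent thresholding, atlas-region
    SD tables), classifies the epileptogenic focus by hemisphere and
    lobe, and evaluates agreement (Cohen's kappa with Landis-Koch bands)
    and validation statistics against resection masks. A synthetic brain
    phantom module generates structural templates, atlas parcellations,
    control cohorts and lesioned patients so that every stage is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
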