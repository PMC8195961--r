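Package: tumoratlas
Title: Statistical Tumor Atlas Mapping and Survival Modelling for
    Glioblastoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise statistical mapping of tumor location against
    overall-survival groups in co-registered binary segmentation masks:
    tumor distribution maps, per-group tumor odds maps, log-odds-ratio
    maps, voxel-wise Fisher exact tests with a permutation-based p-value
    adjustment, and significance masking. Also computes a tumor
    centrality metric (shortest distance from a reference point to the
    tumor border), fits the downstream Cox proportional-hazards,
    binomial-logistic and ordered-logistic models with an age-by-centrality
    interaction, and ships a synthetic-cohort generator so the full
    pipeline is reproducible and testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    survival,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
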