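Package: petmvpa
Title: Multivoxel Pattern Analysis of FDG-PET Brain Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multivoxel pattern analysis (MVPA) of resting-state
    FDG-PET brain volumes: synthetic 3D phantom cohort simulation with
    planted metabolic networks, pontine reference-region intensity
    normalization, isotropic Gaussian smoothing, whole-brain linear nu-SVM
    group discrimination with leave-pair-out cross-validation, signed
    weight-pattern (network) extraction, per-subject network mean
    metabolism, single and two-feature floating cut-off classification,
    and the supporting group statistics (pooled t tests, 2x2 chi-square,
    Pearson and Kendall correlations, ANCOVA).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
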