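Package: atrophyz
Title: Robustness Evaluation of Voxel-Wise Normative Brain-Atrophy Z-Score Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how image modifications (defacing-like
    perturbations, within-session repeat noise, global intensity changes)
    affect voxel-wise normative gray-matter atrophy z-score maps. Provides a
    synthetic phantom generator for age/sex-stratified reference cohorts and
    patient scans with planted regional atrophy, sex- and age-windowed
    voxel-wise mean/SD normative templates, z-score atrophy maps, a
    root-mean-square-error impact statistic with a test-retest benchmark,
    iterative Grubbs and benchmark-percentile outlier criteria, spatial
    deviation maps, and a pipeline that reproduces the full evaluation on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
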