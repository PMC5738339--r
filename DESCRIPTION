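Package: lsctp
Title: Local Similarity of Cortical Thickness Profiles on Surface Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sliding-window mapping of inter-subject similarity of cortical
    thickness profiles on triangulated surface meshes. Computes per-vertex
    all-pairs Pearson correlations of windowed thickness profiles averaged
    via the Fisher z transformation, estimates the spatial smoothness (FWHM)
    of vertex data from inter-neighbor difference variances, performs
    iterative nearest-neighbor smoothing, derives smoothness-matched Monte
    Carlo null distributions and critical thresholds, supports window-size
    selection via local variability maps, and summarizes maps over named
    regions of interest. Reads and writes FreeSurfer binary surface, curv
    and ASCII label formats alongside plain-text fallbacks, and ships a
    synthetic spherical cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
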