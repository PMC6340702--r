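Package: retinomap
Title: Bayesian Inference of Retinotopic Maps on the Cortical Surface
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds two-dimensional models of visual-field organization on
    flattened cortical surface meshes and registers individual subjects'
    noisy population-receptive-field (pRF) measurements to them by
    minimizing a topology-preserving potential function.  The registered
    mesh yields denoised, full-field per-vertex predictions of polar angle,
    eccentricity, pRF size and visual-area label, together with the
    evaluation metrics used to assess them (eccentricity-scaled errors,
    deformation summaries, cortical magnification).  Includes a synthetic
    data generator producing ground-truth models, warped subjects and noisy
    pRF measurements for download-free end-to-end validation, plus readers
    and writers for FreeSurfer surface/curv, OFF, TSV and JSON interchange
    formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, Rcpp, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
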