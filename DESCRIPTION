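Package: megsam
Title: Synthetic Aperture Magnetometry Analysis of Oddball MEG Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source localization of auditory mismatch responses from
    magnetoencephalography (MEG) oddball experiments using a scalar
    (optimal-orientation) LCMV beamformer with pseudo-T contrast statistics,
    maximal-statistic permutation inference at the group level, and virtual
    sensor time-course extraction.  Includes an analytic spherical-conductor
    forward model (Sarvas solution) and a synthetic oddball-MEG generator
    (275-channel helmet, evoked and deviance-specific dipole sources,
    correlated brain noise, sensor noise, transient artifacts) so that every
    analysis stage can be validated by dipole recovery at desk scale.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    RNifti,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
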