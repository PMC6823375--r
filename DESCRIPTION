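Package: ezstim
Title: EZ-Diffusion Modelling and Resting-State fMRI Quantification for
    Sham-Controlled Brain Stimulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sham-controlled non-invasive brain
    stimulation experiments. Implements the EZ-diffusion closed-form
    estimator for choice-reaction-time data (drift rate, boundary
    separation, non-decision time) with trial filtering, population
    pooling, and percentile-bootstrap confidence intervals and
    between-condition resampling tests; a first-passage Wiener diffusion
    simulator for generating realistic trial-level datasets; a
    resting-state fMRI quantification pipeline covering motion scrubbing
    (framewise displacement, DVARS, spatial SD), nuisance regression,
    Butterworth band-pass filtering, Gaussian smoothing, ALFF, regional
    homogeneity (Kendall's W), seed-based functional connectivity, paired
    Time-by-Stimulation contrasts and sign-flip permutation cluster
    inference; a synthetic resting-state scan generator with planted
    effects for pipeline validation; and the closed-form axial field and
    gradient of a cylindrical permanent stimulation magnet.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    RNifti,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
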