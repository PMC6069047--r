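Package: cecganc
Title: Motion-Artifact Cancellation for Capacitive ECG with Switched
    Affine-Projection Adaptive Filters
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Active noise cancellation for electrocardiograms measured by
    capacitive (non-contact) sensors.  Implements the affine projection
    algorithm (APA), the affine projection sign algorithm (APSA), a robust
    variable-step-size switch between the two, and a QRS-preserving switched
    variant that treats the cardiac QRS complex as impulsive noise so its
    power survives filtering while motion artifacts are removed.  Includes a
    four-channel synthetic capacitive-ECG generator with ground-truth R
    peaks, a Pan-Tompkins R-peak detector, R-peak based evaluation metrics
    (sensitivity, positive predictivity, estimated SNR), and a small command
    line front end for simulate/denoise/detect/evaluate/benchmark pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
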