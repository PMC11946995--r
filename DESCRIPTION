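Package: vibroscrew
Title: Vibroacoustic Detection of Pedicle Screw Loosening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for vibroacoustic assessment of pedicle screw anchorage.
    Generates standardized sine-sweep excitation signals, reads and writes
    24-bit PCM WAV recordings with CSV manifests, computes normalized
    256x218 log-mel spectrogram features, trains a squeeze-and-excitation
    residual network (SE-ResNet-18) to classify fixed versus loose screws,
    and evaluates it with leave-one-specimen-out cross-validation. Includes
    the optical-tracking loosening validation statistic (centered mean
    absolute relative implant-vertebra movement and its loose/fixed ratio)
    and a fully seeded synthetic vibroacoustic and trajectory simulator so
    the whole pipeline is exercisable without cadaveric data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
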