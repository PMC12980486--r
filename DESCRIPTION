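Package: lcmsnet
Title: End-to-End Classification of Raw LC-HRMS Runs with Depthwise
    1D-Convolutional Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies centroided liquid chromatography high-resolution
    mass spectrometry (LC-HRMS) runs directly from raw data, without peak
    picking or alignment. Runs are binned on an adaptive retention-time by
    m/z grid into pseudoimages, normalized by per-channel min-max scaling,
    and classified by an ensemble of depthwise 1D convolutional networks
    operating along the retention-time axis with a reject option driven by
    the top-two probability margin. Includes retention-time-shift data
    augmentation, random oversampling, a synthetic LC-HRMS generator with
    class-specific marker compounds and batch effects, mzML input/output,
    and an evaluation protocol with macro one-vs-rest metrics, stratified
    splitting, Wilcoxon signed-rank model comparison and Benjamini-Hochberg
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
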