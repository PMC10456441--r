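Package: smdfuse
Title: Surrogate Minimal Depth Random Forests for Multimodal
    Chemometric Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Class-weighted random-forest classification with per-node
    surrogate splits, surrogate minimal depth (SMD) variable selection and
    mean-adjusted-agreement variable-relation analysis for multimodal
    food-authentication data.  Includes chemometric preprocessing for
    LC-MS bucket tables (group-presence filtering, vector normalization,
    autoscaling) and FT-NIR replicate spectra (multiplicative scatter
    correction, first derivative, Savitzky-Golay smoothing, binning,
    replicate median), low-level data fusion of feature blocks, Ward
    clustering of the relation matrix with cross-modal cluster reporting,
    and a synthetic multimodal data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
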