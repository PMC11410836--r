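Package: boneaxis
Title: Automatic Radiographic Goniometry of the Foot by Bone-Axis Heatmap Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the hallux valgus angle (HVA) and the first-second
    intermetatarsal angle (IMA) on dorsoplantar foot radiographs by
    regressing per-bone axis heatmaps with a compact encoder-decoder
    convolutional network. Expert-drawn bone-axis line segments for the
    first proximal phalanx (PH1) and the five metatarsals (MT1-MT5) are
    encoded as Gaussian-smoothed line heatmaps; a five-level U-net style
    network is trained with an RMSE loss to predict the six channels; axis
    inclination angles are recovered from the high-value heatmap regions by
    a total-least-squares principal-axis fit, and HVA/IMA follow as signed
    angle differences. Includes a synthetic foot-phantom generator with
    known ground-truth axes, simulated human raters, and the validation
    statistics used to assess agreement with manual goniometry (MAE with a
    one-tailed non-inferiority t-test against a 3 degree margin, error
    bands, inter-rater difference statistics, and t-test power analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
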