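Package: lesionmap
Title: Spatial Frequency Mapping and Monte Carlo Cluster Inference for
    Brain Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analyzes the spatial distribution of brain metastases from
    co-registered lesion masks in a common standard space. Builds brain
    parenchymal masks from tissue probability maps, locates lesion centers
    and depths with exact 3D Euclidean distance transforms, constructs
    per-group tumor frequency maps from 20-mm sphere kernels, calibrates
    voxel-wise and cluster-size thresholds against a uniform random null
    by Monte Carlo simulation, and reports significant clusters with
    rank-based p-values. Includes a synthetic brain phantom and lesion
    cohort generator with known ground truth for end-to-end validation,
    plus rank-based group comparisons of lesion features.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
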