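Package: dscaif
Title: Automatic Arterial Input Function Detection for DSC-MRI by
    Agglomerative Hierarchical Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the arterial input function (AIF) in dynamic
    susceptibility contrast MRI perfusion series by unsupervised clustering
    of voxel time-concentration curves.  Implements average-linkage
    agglomerative hierarchical clustering with an M-statistic
    (peak height / (time-to-peak x FWHM)) cluster selector, together with
    k-means and fuzzy c-means baselines, the clinical candidate-curve filter
    chain (area-under-curve, roughness, and partial-volume ratio filters),
    a gamma-variate bolus-passage simulator with known ground truth, and
    evaluation metrics (partial-volume level, RMSE against the true AIF,
    and across-run robustness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    stats,
    utils,
    e1071,
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
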