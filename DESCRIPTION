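Package: autoplanr
Title: Automated Inverse Optimization for Radiotherapy Planning by Stepwise DVH Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A self-contained inverse treatment-planning engine for research on
    automated plan optimization. Provides deterministic voxel phantoms with
    named structures, a sparse pencil-beam dose-influence model, dose-volume
    objective functions with exact analytic gradients, a projected-gradient
    fluence optimizer, and an automated planning controller that iteratively
    reduces organ-at-risk dose-volume objectives until a prescribed target
    dose-heterogeneity limit is reached. Includes cumulative dose-volume
    histograms, clinical dose indices (D95, D5, D2%, Dmean) and paired plan
    comparison with the exact Wilcoxon signed-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
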