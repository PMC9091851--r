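Package: rppbone
Title: Radial Porosity Profiles of Limb-Bone Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies primary cortical porosity in radial sector/quadrant
    partitions of mid-diaphyseal limb-bone cross-sections and analyses the
    resulting radial porosity profiles (RPPs). Provides sector/quadrant
    geometry on labelled class rasters, porosity arithmetic with remodelling
    exclusion and missing-value rules, trajectory similarity measures
    (dynamic time warping, edit distance, longest common subsequence),
    k-means and complete-linkage clustering, group-based trajectory
    modelling (polynomial Gaussian mixtures fitted by EM with AIC/BIC/CVE
    model selection), cross-method congruence and skeletal-dissociation
    statistics, multinomial logistic prediction of group memberships with
    stepwise AIC/AICc selection, and seeded synthetic section and dataset
    generators with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nnet,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
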