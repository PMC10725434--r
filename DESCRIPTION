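Package: brainage3d
Title: Brain Age Prediction from 3D Structural MRI with a Combined
    CNN-MLP Regressor
Version: 0.1.0
Authors@R:
    person("Brainage3d", "Maintainers", email = "maintainers@brainage3d.org",
           role = c("aut", "cre"))
Description: Predicts brain age from registered 3D T1-weighted volumes with a
    deep 3D convolutional network, optionally fused with categorical sex
    information through a small multi-layer perceptron branch. Provides the
    full modelling workflow: NIfTI-1 input/output, isotropic cubic-spline
    resampling and intensity normalization, three predictor variants
    (CNN-MLP, CNN-only, CNN with a linear sex layer), k-fold cross-validated
    training with an optimizer/learning-rate grid, linear bias correction of
    the brain-age gap, Grad-CAM attention maps adapted to regression
    (per-subject, global average and sex-difference), and pooled two-sample
    comparison of brain-age gaps between clinical groups. A synthetic
    aging-brain phantom generator makes every stage testable at desk scale
    without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
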