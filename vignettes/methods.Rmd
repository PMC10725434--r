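---
title: "Brain age prediction with a combined CNN-MLP: models, phantoms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age prediction with a combined CNN-MLP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A person's "brain age" is the age a regression model assigns to their brain
from structural MRI, after training on healthy aging. The *brain age gap* —
predicted minus chronological age — is a candidate biomarker: a positive gap
suggests an older-appearing brain and has been linked to mild cognitive
impairment and Alzheimer's disease. `brainage3d` implements a complete
desk-scale workflow for this problem: mixed-input deep regression on
registered 3D T1-weighted volumes plus categorical sex, cross-validated
training with an optimizer grid, linear bias correction of the gap,
Grad-CAM attention maps adapted to regression, and pooled two-sample
comparison of gap distributions between clinical groups.

Because real multi-site T1 cohorts can neither be shipped nor trained on a
CPU in minutes, the package includes a synthetic aging-brain phantom
generator. The phantom is a *stated world*: its parameters define the
conditions under which every property of the pipeline is tested, and they
are fixed, not tuned to test outcomes.

## The predictor

The image path is a 3D CNN: `n_conv_blocks` blocks of (3×3×3 convolution
with same padding → batch normalization → ReLU → 2× max pooling), with 8
channels in the first block and doubling per block; then flatten →
dense(64, ReLU) → batch norm → dropout(0.3) → dense(16, ReLU). Three
variants share this trunk:

* **cnn_mlp** — a small MLP (dense 16 → dense 4, both ReLU) embeds the
  one-hot sex code; its output is concatenated with the 16 image features
  and passed through dense(4, ReLU) → dense(1, linear).
* **cnn_only** — the 16 image features feed the same head; sex is provably
  ignored.
* **cnn_linear_sex** — the sex code is appended to the image features and a
  single linear layer produces the output (the "streamlined" fusion).

The final unit is linear: the output is an unbounded real number of years.
At the production grid of 105×127×105 voxels (1.5 mm isotropic), five
blocks reduce the feature map to 3×3×3; at the 16³ desk scale three blocks
reduce it to 2³. Kernel size 3, stride 1, same padding and pool window 2
are the standard minimal reading of "conv + max pool with stride two";
none of these is asserted as an external fact.

There is no deep-learning framework in this package's dependency set; the
convolution stack, batch norm, pooling, dense layers, dropout, the exact
backward passes, and the five optimizers are implemented in plain R with
BLAS matrix products (`im2col` + GEMM for convolution). Every backward pass
is verified against central finite differences in the test suite's
development history and indirectly by the training tests.

## Training

Loss is mean squared error; MAE, RMSE and R² (about the mean of the true
ages) are the reported metrics. The optimizer grid crosses
{Adagrad, Adam, NAG, RMSprop, SGD} with (learning rate, decay) pairs
(0.01, 0.003) and (0.001, 0.0003); "decay" is per-update inverse-time decay
`lr_t = lr / (1 + decay·t)`, and NAG is SGD with Nesterov momentum 0.9 (the
momentum value is our choice; no schedule is externally specified).
Batch size defaults to 16. Cross-validation uses k = 10 folds by default,
stratified by 5-year age bins so each fold spans the age range.

Two internal numerical choices matter:

* **Target standardization** (`standardize_targets = TRUE`): ages are
  z-scored on the training fold and predictions are mapped back. Adam moves
  each parameter by roughly the learning rate per step; at lr = 0.001 and a
  few hundred updates, a raw-years head (mean target ≈ 54) cannot leave its
  zero initialization, whereas a standardized target is reachable. This is
  pure numerics — it does not change the model class.
* **Input normalization** (`normalize_input = TRUE`): each volume is
  z-scored over its nonzero foreground, the right default for real MRI with
  arbitrary scanner scaling. For phantoms, which are generated on a common
  intensity scale, it has a side effect worth knowing: the growing dark
  ventricle shifts the foreground mean, so after per-volume z-scoring
  *every* voxel's value carries a trace of age. The attention-localization
  experiment therefore disables it (see below).

Augmentation follows the training-time protocol: with 30% probability per
sample per epoch draw, a rotation with Euler angles uniform in ±10° followed
by an integer translation uniform in ±10 voxels, linear interpolation, zero
fill. Rotation-then-translation order, interpolation scheme and fill value
are our conventions (stated, testable, not external facts). Augmentation
never touches evaluation data or demographic labels.

## Bias correction

Deep age regressors underfit the age extremes (regression dilution), making
the gap correlate negatively with age. `fit_bias()` runs OLS of the gap on
chronological age; `apply_bias()` subtracts the fitted offset
`intercept + slope·age`. By OLS orthogonality, on the fitting set the
corrected gap has exactly zero mean and zero slope against age (machine
precision). The fit is intended for training-side predictions and applied
to held-out or external sets, which avoids leaking test labels; correction
is monotone at fixed age, so it never reorders two same-aged subjects.

## Attention maps

Grad-CAM is adapted to scalar regression: channel weights are the spatial
average of the derivative of the predicted age with respect to a conv
block's post-ReLU activations (default: last block), the map is
`ReLU(Σ_c w_c A_c)` upsampled trilinearly to the input grid, then min-max
normalized to [0,1] per subject (a constant raw map normalizes to all
zeros). The ReLU keeps evidence pushing toward *older* age; signed maps are
available with `normalize = "raw"`. Group maps average per-subject
normalized maps (default order; averaging raw maps first is also possible),
and the sex-difference map is mean(male) − mean(female), min-max normalized.

## The phantom world

Each phantom is a registered, head-like volume on a fixed grid (default
16³ voxels spanning a 160 mm field of view): a bright spherical cortical
shell (intensity 1.0) of thickness `30 − 0.15·age` mm, interior tissue at
0.5, a dark central ventricle (0.05) of radius `6 + 0.25·age` mm, and
background 0. Boundaries are smoothed over one voxel, so the age signal
remains continuous even on coarse grids. A designated anterior subregion is
intensity-scaled by `sex_scale_male` (default 1.08) for males; with the
default `sex_age_slope = 0` this subregion is the *only* place the sexes
differ. Gaussian noise (sd 0.02, ~4% of the tissue-shell contrast)
is added last from a per-subject seed. Ages are uniform on the requested
range — distribution-simple for recovery tests, not matched to any
empirical cohort histogram.

Two worlds beyond the default are used by the acceptance criteria:

* **Sex-interaction world** (`sex_scale_male = 1`, `sex_age_slope = 0.08`,
  `shell_age_slope = 0`): male ventricles grow ~a third faster, no visible
  sex cue in the image, and all age signal is ventricular. The image alone
  then confounds age and sex, so the sex input is genuinely informative —
  the world in which the cnn_mlp ≤ cnn_only MAE comparison is run (five
  seed replicates, directional, not a significance claim).
* **Ventricle-only world** (`shell_age_slope = 0`): only the ventricle
  varies with age, giving the attention test a known ground-truth region.

What the phantom does **not** emulate: anatomy, multiple tissue classes,
scanner artifacts, nonlinear deformation, site effects. A green recovery
test establishes that the pipeline can learn a smooth monotone morphological
age signal at desk scale — not that it reaches any particular accuracy on
real MRI.

## Numerical details and conventions

* Resampling is separable natural cubic-spline interpolation per axis;
  values at exactly coincident grid points are preserved, and queries
  beyond the input extent are edge-clamped rather than extrapolated. When no
  output shape is given, the output grid is `floor(extent / spacing)`.
* Foreground for intensity normalization is `voxels != 0` (not `> 0`):
  z-scoring maps about half the foreground below zero, so a `> 0` mask
  would change between applications and break idempotence. Exact zeros are
  treated as resampling background and left untouched.
* Rotation happens in voxel space about the grid center (phantom voxels are
  isotropic); translation is in integer voxels after rotation.
* The pooled-variance (Student) two-sample t-test is used for group gap
  comparison, reproducing printed clinical-table statistics computed from
  (n, mean, sd) summaries; Welch's variant would differ in the third
  decimal for the group sizes involved.
* All randomness flows from explicit integer seeds; per-subject and
  per-fold seeds are derived deterministically from a master seed, and
  training is bit-reproducible for a fixed seed on a fixed BLAS.

## Known limitations

* **Grad-CAM localization at desk scale.** With a flatten→dense regression
  head, Grad-CAM's spatially averaged channel weights discard the spatial
  information carried by the dense weights; localization must come from the
  activation maps alone. At 16³, the last block's receptive fields span the
  whole head, early-block "darkness" detectors respond to the ventricle
  *and* the equally dark background, and the bright shell dominates
  activation magnitude. In our experiments the top-decile attention mass
  over a 2-voxel-dilated ventricle mask stayed between 0.00 and 0.31 across
  target layers, training lengths and normalization orders — below the 0.5
  the localization property asserts. The corresponding acceptance test is
  implemented faithfully and left failing rather than weakened; the
  closed-form Grad-CAM oracle passes, so this is a property of the method
  at this scale, not of the implementation. Periventricular localization
  as reported at full scale plausibly requires richer features and finer
  relative resolution than a 16³ phantom affords.
* Pure-R convolution is fast enough for 16³–32³ training and single
  105×127×105 forward passes, but full-scale *training* is out of scope.
* The NIfTI codec covers NIfTI-1, 3D, common dtypes and gzip; it does not
  implement quaternion orientations (sform only) or NIfTI-2.
* `normalize_intensity` assumes exact zeros are background; affine
  intensity shifts that move the zero level change the foreground mask.
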