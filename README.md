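# brainage3d

Brain age prediction from registered 3D T1-weighted MRI with a combined
CNN-MLP regressor, in pure R.

A person's *brain age* is the age a model trained on healthy aging assigns
to their brain scan; the *brain age gap* `gap = predicted − age` is a
compact biomarker of accelerated or preserved aging. `brainage3d`
implements the full workflow for researchers who want to study this
pipeline end to end at desk scale:

* **Phantoms** — a synthetic aging-brain generator (bright cortical shell
  that thins with age, dark central ventricle that grows with age,
  sex-coded subregion, Gaussian noise) so every stage is testable with no
  data download.
* **I/O + preprocessing** — a self-contained NIfTI-1 reader/writer,
  isotropic cubic-spline resampling (production grid 105×127×105 at
  1.5 mm), foreground intensity z-scoring.
* **Models** — three variants built on a 3D conv trunk
  (conv → batchnorm → ReLU → maxpool, channels 8, 16, 32, …):
  `cnn_mlp` (image + sex MLP fusion), `cnn_only`, and `cnn_linear_sex`.
  The network engine (conv3d via im2col + BLAS, exact backprop, Adagrad /
  Adam / NAG / RMSprop / SGD) is implemented in the package.
* **Training** — MSE loss; MAE / RMSE / R² metrics; age-stratified k-fold
  cross-validation; the 5 × 2 optimizer/learning-rate grid; 30%-probability
  rotation/translation augmentation.
* **Bias correction** — OLS of gap on age, subtracted from predictions.
* **Attention** — Grad-CAM adapted to regression: per-subject maps, global
  averages, male−female difference maps, written as NIfTI.
* **Group statistics** — pooled two-sample t-tests on gaps, from raw data
  or from printed `(n, mean ± sd)` summaries.

## Worked example

```r
library(brainage3d)

# 1. a cohort of 120 synthetic subjects on a 16^3 grid
params <- phantom_params(noise_sd = 0.02)
cohort <- generate_cohort(120, 18, 90, male_fraction = 0.5, params, seed = 2025)
split  <- stratified_split(cohort, test_fraction = 0.2, seed = 17)

# 2. train a CNN-only model (3 blocks fit a 16^3 grid)
spec  <- model_spec("cnn_only", input_shape = c(16, 16, 16), n_conv_blocks = 3)
cfg   <- train_config(optimizer = "adam", learning_rate = 1e-3, decay = 3e-4,
                      epochs = 30, seed = 404)
model <- train(spec, split$train, cfg)

# 3. held-out accuracy
ages <- vapply(split$test, `[[`, numeric(1), "age")
pred <- predict(model, split$test)
compute_metrics(ages, pred)
#> MAE 1.615 years | RMSE 2.195 years | R^2 0.987

# against a chance baseline of
mean(abs(ages - mean(ages)))
#> [1] 16.27436

# 4. bias-correct the gap and compare two groups from printed summaries
bias <- fit_bias(ages, pred)
corrected <- apply_bias(bias, ages, pred)
compare_groups_from_summary(group_summary(208, 0.413, 3.515),
                            group_summary(172, 1.393, 3.606))
#> two-sample t = -2.674, df = 378, p = 0.007827 (mean difference -0.980 years)
```

The held-out MAE of 1.6 years against a 16.3-year chance baseline, and
R² = 0.99, show the pipeline recovering the phantom's smooth morphological
age signal; the t-test reproduces a printed clinical-table comparison of
mild-cognitive-impairment vs Alzheimer's gap distributions from summary
statistics alone.

## Command line

```sh
Rscript inst/cli/brainage3d simulate --n 24 --grid 16,16,16 --seed 7 --out cohort/
Rscript inst/cli/brainage3d train    --cohort cohort/ --out model.rds --blocks 2 --epochs 10
Rscript inst/cli/brainage3d predict  --model model.rds --cohort cohort/ --out pred.tsv
Rscript inst/cli/brainage3d bias-fit --pred-table pred.tsv --out-model bias.tsv
Rscript inst/cli/brainage3d compare  --table pred.tsv --group-col sex
```

Every run writes a `*.manifest.json` (config snapshot, seeds, package
version, input digests) sufficient to reproduce it.

## Scope

Inputs are assumed already nonlinearly registered to a common (MNI-like)
space; registration, skull stripping and bias-field correction belong to
external tools. Full-scale GPU training, pretrained weights, and two-stage
cascade refinements are out of scope.
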