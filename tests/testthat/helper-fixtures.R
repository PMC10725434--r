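# Shared fixtures. Everything is generated in code; nothing binary ships
# with the package.

# fast noise-free phantom world for geometry tests
quiet_params <- function(...) phantom_params(noise_sd = 0, ...)

# small random volume
rand_volume <- function(d = c(16L, 16L, 16L), spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  volume_image(array(rnorm(prod(d)), dim = d), spacing = spacing)
}

# tiny model spec that trains in seconds
tiny_spec <- function(variant = "cnn_mlp", shape = c(8L, 8L, 8L), blocks = 2L) {
  model_spec(variant, input_shape = shape, n_conv_blocks = blocks,
             base_channels = 2L, dense_image_units = c(6L, 4L),
             mlp_sex_units = c(3L, 2L), head_units = c(3L, 1L))
}

# tiny cohort on an 8^3 grid (grid_shape >= 16 is enforced by
# phantom_params, so shrink by resampling when an 8^3 cohort is needed)
tiny_cohort <- function(n = 8, seed = 42, noise_sd = 0.02, ...) {
  generate_cohort(n, 20, 88, 0.5, phantom_params(noise_sd = noise_sd, ...),
                  seed = seed)
}

shrink_record <- function(r, shape = c(8L, 8L, 8L)) {
  v <- resample_isotropic(r$volume, r$volume$spacing[1] * 2, shape)
  subject_record(r$id, r$age, r$sex, v)
}

tiny_cohort8 <- function(n = 8, seed = 42, noise_sd = 0.02, ...) {
  co <- tiny_cohort(n, seed, noise_sd, ...)
  co$records <- lapply(co$records, shrink_record)
  co
}

# Tiny single-block predictor whose Grad-CAM has a closed form:
# conv channel 1 copies the input, channel 2 doubles it (center taps only);
# batch norm is pinned to identity; the head reduces to a pure sum of the
# pooled activations with per-channel weights alpha. For positive inputs:
#   d(out)/dA = alpha_c at pooled argmax positions, 0 elsewhere
#   weight_c  = alpha_c * Vp / V = alpha_c / 8 for a 4^3 grid
#   raw map   = ReLU(sum_c weight_c * A_c),  A_1 = X, A_2 = 2X.
linear_toy_model <- function(shape = c(4L, 4L, 4L), alpha = c(0.7, -0.2)) {
  spec <- model_spec("cnn_only", input_shape = shape, n_conv_blocks = 1,
                     base_channels = 2, dense_image_units = c(3L, 2L),
                     head_units = c(2L, 1L), dropout_rate = 0)
  pred <- build_model(spec, init_seed = 1)
  ctr <- brainage3d:::CONV_CENTER_OFFSET
  W <- matrix(0, 27, 2)
  W[ctr, 1] <- 1; W[ctr, 2] <- 2
  pred$image_layers[[1]]$W <- W
  pred$image_layers[[1]]$b <- c(0, 0)
  # identity batch norm in inference mode
  pred$image_layers[[2]]$run_mean <- c(0, 0)
  pred$image_layers[[2]]$run_var <- c(1, 1) - brainage3d:::BN_EPS
  vp <- prod(floor(shape / 2))
  d1 <- pred$image_layers[[6]]                 # dense after flatten
  d1$W <- cbind(c(rep(alpha[1], vp), rep(alpha[2], vp)), 0, 0)
  d1$b <- c(100, 0, 0)                         # keep ReLU strictly active
  pred$image_layers[[6]] <- d1
  pred$image_layers[[8]]$run_mean <- c(0, 0, 0)  # identity bn1d
  pred$image_layers[[8]]$run_var <- c(1, 1, 1) - brainage3d:::BN_EPS
  d2 <- pred$image_layers[[10]]                # dense 3 -> 2
  d2$W <- matrix(c(1, 0, 0, 0, 0, 0), 3, 2)
  d2$b <- c(0, 0)
  pred$image_layers[[10]] <- d2
  h1 <- pred$head_layers[[1]]                  # dense 2 -> 2
  h1$W <- matrix(c(1, 0, 0, 0), 2, 2); h1$b <- c(0, 0)
  pred$head_layers[[1]] <- h1
  h2 <- pred$head_layers[[3]]                  # final linear dense
  h2$W <- matrix(c(1, 0), 2, 1); h2$b <- 0
  pred$head_layers[[3]] <- h2
  pred$normalize_input <- FALSE
  pred
}

toy_record <- function(shape = c(4L, 4L, 4L), seed = 3) {
  set.seed(seed)
  # strictly positive input with a unique maximum in every pool window
  x <- array(runif(prod(shape), 0.5, 1.5), dim = shape)
  subject_record("toy", 50, "male", volume_image(x))
}
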