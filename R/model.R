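# Predictor variants.
#
# Image path: n_conv_blocks blocks of (3x3x3 conv, same padding -> batch norm
# -> ReLU -> 2x max pool), channels 8, 16, 32, ...; then flatten ->
# dense(64, ReLU) -> batch norm -> dropout(0.3) -> dense(16, ReLU).
# cnn_mlp:        sex one-hot -> dense(16, ReLU) -> dense(4, ReLU);
#                 concat(16+4) -> dense(4, ReLU) -> dense(1, linear).
# cnn_only:       image features -> dense(4, ReLU) -> dense(1, linear).
# cnn_linear_sex: concat(image features, sex one-hot) -> dense(1, linear).

#' Model architecture specification
#'
#' Selects one of the three predictor variants and fixes the architecture
#' hyperparameters. Channels double every block starting from
#' `base_channels`; spatial dimensions halve (floor) at every block, and the
#' spec is rejected if any axis would collapse below one voxel.
#'
#' @param variant `"cnn_mlp"` (image + sex MLP fusion), `"cnn_only"`, or
#'   `"cnn_linear_sex"` (sex appended through a single linear layer).
#' @param input_shape integer triple, the model input grid.
#' @param n_conv_blocks number of conv blocks (default 5; use 3 for 16^3
#'   desk-scale phantoms).
#' @param base_channels channels of the first block (default 8).
#' @param dense_image_units two dense widths after flattening (default 64, 16).
#' @param dropout_rate dropout after the first image dense layer (default 0.3).
#' @param mlp_sex_units sex-branch dense widths (default 16, 4).
#' @param head_units fusion head widths (default 4, 1; last must be 1).
#' @return an object of class `model_spec`.
#' @examples
#' s <- model_spec("cnn_mlp", input_shape = c(105, 127, 105))
#' s$conv_shapes[[6]]  # 3 3 3 after five halvings
#' @export
model_spec <- function(variant = c("cnn_mlp", "cnn_only", "cnn_linear_sex"),
                       input_shape = c(105L, 127L, 105L),
                       n_conv_blocks = 5L, base_channels = 8L,
                       dense_image_units = c(64L, 16L), dropout_rate = 0.3,
                       mlp_sex_units = c(16L, 4L), head_units = c(4L, 1L)) {
  variant <- match.arg(variant)
  input_shape <- as.integer(input_shape)
  if (length(input_shape) != 3L || any(input_shape < 1L)) {
    stopf("input_shape must be 3 positive integers")
  }
  if (!is_count(n_conv_blocks) || n_conv_blocks < 1) {
    stopf("n_conv_blocks must be a positive integer")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("dropout_rate must lie in [0, 1)")
  if (utils::tail(head_units, 1) != 1L) stopf("final head layer must have exactly 1 unit")
  shapes <- vector("list", n_conv_blocks + 1L)
  shapes[[1]] <- input_shape
  s <- input_shape
  for (k in seq_len(n_conv_blocks)) {
    s2 <- as.integer(floor(s / 2))
    if (any(s2 < 1L)) {
      ax <- which(s2 < 1L)[1]
      stopf("input_shape axis %d (%d voxels) collapses below 1 voxel at conv block %d; reduce n_conv_blocks",
            ax, input_shape[ax], k)
    }
    s <- s2
    shapes[[k + 1L]] <- s
  }
  structure(list(variant = variant, input_shape = input_shape,
                 n_conv_blocks = as.integer(n_conv_blocks),
                 base_channels = as.integer(base_channels),
                 dense_image_units = as.integer(dense_image_units),
                 dropout_rate = dropout_rate,
                 mlp_sex_units = as.integer(mlp_sex_units),
                 head_units = as.integer(head_units),
                 conv_shapes = shapes),
            class = "model_spec")
}

sex_onehot <- function(sexes) {
  m <- cbind(male = as.numeric(sexes == "male"),
             female = as.numeric(sexes == "female"))
  if (any(rowSums(m) != 1)) stopf("sex must be 'male' or 'female'")
  m
}

#' Build an (untrained) predictor
#'
#' Weights are initialized with He/Glorot scaling under `init_seed`, which is
#' recorded in the predictor fingerprint so untrained outputs are
#' reproducible across runs.
#'
#' @param spec a [model_spec].
#' @param init_seed integer seed for weight initialization.
#' @return an object of class `brainage_predictor`.
#' @export
build_model <- function(spec, init_seed = 42L) {
  if (!inherits(spec, "model_spec")) stopf("spec must be a model_spec")
  with_seed_(init_seed, {
    image_layers <- list()
    c_in <- 1L
    for (k in seq_len(spec$n_conv_blocks)) {
      c_out <- as.integer(spec$base_channels * 2^(k - 1))
      shp <- spec$conv_shapes[[k]]
      image_layers <- c(image_layers, list(
        layer_conv(shp, c_in, c_out),
        layer_bn3d(c_out),
        layer_relu(block = k),
        layer_pool(shp, c_out)
      ))
      c_in <- c_out
    }
    final_shape <- spec$conv_shapes[[spec$n_conv_blocks + 1L]]
    flat <- prod(final_shape) * c_in
    image_layers <- c(image_layers, list(
      layer_flatten(final_shape, c_in),
      layer_dense(flat, spec$dense_image_units[1]),
      layer_relu(),
      layer_bn1d(spec$dense_image_units[1]),
      layer_dropout(spec$dropout_rate),
      layer_dense(spec$dense_image_units[1], spec$dense_image_units[2]),
      layer_relu()
    ))
    img_dim <- spec$dense_image_units[2]

    sex_layers <- NULL
    head_in <- img_dim
    if (spec$variant == "cnn_mlp") {
      sex_layers <- list(
        layer_dense(2L, spec$mlp_sex_units[1]), layer_relu(),
        layer_dense(spec$mlp_sex_units[1], spec$mlp_sex_units[2]), layer_relu()
      )
      head_in <- img_dim + spec$mlp_sex_units[2]
      head_layers <- list(
        layer_dense(head_in, spec$head_units[1]), layer_relu(),
        layer_dense(spec$head_units[1], 1L, init = "glorot")
      )
    } else if (spec$variant == "cnn_only") {
      head_layers <- list(
        layer_dense(img_dim, spec$head_units[1]), layer_relu(),
        layer_dense(spec$head_units[1], 1L, init = "glorot")
      )
    } else {                                   # cnn_linear_sex
      head_in <- img_dim + 2L
      head_layers <- list(layer_dense(head_in, 1L, init = "glorot"))
    }
    structure(list(spec = spec, image_layers = image_layers,
                   sex_layers = sex_layers, head_layers = head_layers,
                   img_dim = img_dim,
                   target_norm = c(mean = 0, sd = 1),
                   normalize_input = TRUE,
                   fingerprint = list(init_seed = as.integer(init_seed),
                                      train_seed = NA_integer_,
                                      config_hash = NA_character_),
                   history = numeric(0)),
              class = "brainage_predictor")
  })
}

#' @export
print.brainage_predictor <- function(x, ...) {
  cat(sprintf("<brainage_predictor> variant=%s, input %s, %d conv blocks\n",
              x$spec$variant, paste(x$spec$input_shape, collapse = "x"),
              x$spec$n_conv_blocks))
  cat(sprintf("  trained: %s (init seed %d)\n",
              if (length(x$history)) sprintf("%d epochs", length(x$history)) else "no",
              x$fingerprint$init_seed))
  invisible(x)
}

# Normalize a raw intensity array the same way normalize_intensity treats a
# volume (foreground z-score); used on every model input when
# normalize_input is on.
normalize_array <- function(a) {
  mask <- a != 0
  if (!any(mask)) return(a)
  v <- a[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(a)
  a[mask] <- (v - mean(v)) / s
  a
}

# Assemble the V x N input matrix from a list of volume arrays.
stack_volumes <- function(vols, spec, normalize) {
  v <- prod(spec$input_shape)
  x <- matrix(0, v, length(vols))
  for (i in seq_along(vols)) {
    a <- vols[[i]]
    if (!identical(dim(a), spec$input_shape)) {
      stopf("volume %d shape [%s] does not match model input [%s]",
            i, paste(dim(a), collapse = "x"),
            paste(spec$input_shape, collapse = "x"))
    }
    if (normalize) a <- normalize_array(a)
    x[, i] <- as.numeric(a)
  }
  x
}

# Full forward pass over a batch. Returns scalar outputs on the model's
# internal (standardized) scale plus all caches needed for backprop.
forward_pass <- function(pred, x, sexmat, n, training) {
  img <- path_forward(pred$image_layers, x, n, training)
  pred$image_layers <- img$layers
  h <- img$y                                   # N x img_dim
  sex <- NULL
  if (pred$spec$variant == "cnn_mlp") {
    sex <- path_forward(pred$sex_layers, sexmat, n, training)
    pred$sex_layers <- sex$layers
    h <- cbind(h, sex$y)
  } else if (pred$spec$variant == "cnn_linear_sex") {
    h <- cbind(h, sexmat)
  }
  head <- path_forward(pred$head_layers, h, n, training)
  pred$head_layers <- head$layers
  list(y = as.numeric(head$y), pred = pred,
       caches = list(image = img$caches, sex = if (!is.null(sex)) sex$caches,
                     head = head$caches))
}

# Backward pass from d(output). With stop_at_block set, gradients are only
# propagated down to (and returned at) that conv block's post-ReLU
# activation; parameter gradients below it are not needed then.
backward_pass <- function(pred, caches, dy, n, stop_at_block = NULL) {
  dyh <- matrix(dy, ncol = 1L)
  head <- path_backward(pred$head_layers, caches$head, dyh, n)
  dh <- head$dx
  dimg <- dh[, seq_len(pred$img_dim), drop = FALSE]
  grads_sex <- NULL
  if (pred$spec$variant == "cnn_mlp") {
    dsex <- dh[, pred$img_dim + seq_len(pred$spec$mlp_sex_units[2]), drop = FALSE]
    sex <- path_backward(pred$sex_layers, caches$sex, dsex, n)
    grads_sex <- sex$grads
  }
  stop_before <- 0L
  if (!is.null(stop_at_block)) {
    blocks <- vapply(pred$image_layers, function(l) {
      if (identical(l$kind, "relu") && !is.na(l$block %||% NA_integer_)) l$block
      else NA_integer_
    }, integer(1))
    target <- which(blocks == stop_at_block)
    if (!length(target)) stopf("conv block %d out of range", stop_at_block)
    stop_before <- target
  }
  img <- path_backward(pred$image_layers, caches$image, dimg, n,
                       stop_before = stop_before)
  list(grads = list(image = img$grads, sex = grads_sex, head = head$grads),
       d_target = if (stop_before > 0L) img$dx,
       target_index = stop_before)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict brain age for a set of subjects
#'
#' Runs the predictor in inference mode (dropout off, batch norm on running
#' statistics); outputs are deterministic and returned in input order.
#'
#' @param object a trained [build_model()] predictor.
#' @param records a `subject_cohort` or list of [subject_record]s.
#' @param batch_size inference batch size (memory knob only).
#' @param ... unused.
#' @return numeric vector of predicted ages (years), one per record.
#' @export
predict.brainage_predictor <- function(object, records, batch_size = 16L, ...) {
  records <- as_records(records)
  vols <- lapply(records, function(r) {
    if (is.null(r$volume)) stopf("record '%s' has no attached volume", r$id)
    r$volume$data
  })
  sexes <- record_sexes(records)
  n <- length(records)
  out <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- stack_volumes(vols[idx], object$spec, object$normalize_input)
    fp <- forward_pass(object, x, sex_onehot(sexes[idx]), length(idx),
                       training = FALSE)
    out[idx] <- fp$y
  }
  unname(out * object$target_norm[["sd"]] + object$target_norm[["mean"]])
}
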