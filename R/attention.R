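# Grad-CAM for scalar regression.
#
# Channel weights are the spatial average of d(predicted age)/d(activation)
# at a chosen conv block's post-ReLU activation; the map is
# ReLU(sum_c w_c * A_c), trilinearly upsampled to the input grid. The ReLU
# keeps evidence pushing the prediction toward older age; sign-preserving
# raw maps are available via `normalize = "raw"`.

#' Attention map container
#'
#' @param data 3D array on the model input grid.
#' @param normalization `"per_subject"` (values min-max scaled to \[0,1\]) or
#'   `"raw"`.
#' @return an object of class `attention_map`.
#' @export
attention_map <- function(data, normalization = c("per_subject", "raw")) {
  normalization <- match.arg(normalization)
  if (!is.array(data) || length(dim(data)) != 3L) stopf("attention data must be a 3D array")
  if (normalization == "per_subject" && (min(data) < 0 || max(data) > 1)) {
    stopf("normalized attention values must lie in [0, 1]")
  }
  structure(list(data = data, normalization = normalization),
            class = "attention_map")
}

# min-max to [0,1]; an all-equal map becomes all zeros.
minmax_norm <- function(a) {
  rng <- max(a) - min(a)
  if (rng <= .Machine$double.eps * max(1, abs(max(a)))) {
    return(array(0, dim = dim(a)))
  }
  (a - min(a)) / rng
}

#' Grad-CAM attention map for one subject
#'
#' @param model a trained predictor.
#' @param record a [subject_record] with attached volume.
#' @param layer conv block index to explain (default: the last block).
#' @param normalize `"per_subject"` (default, min-max to \[0,1\]; an
#'   all-equal raw map normalizes to all zeros) or `"raw"`.
#' @return an [attention_map] on the model input grid.
#' @export
gradcam <- function(model, record, layer = NULL,
                    normalize = c("per_subject", "raw")) {
  normalize <- match.arg(normalize)
  if (!inherits(model, "brainage_predictor")) stopf("model must be a brainage_predictor")
  if (!inherits(record, "subject_record")) stopf("record must be a subject_record")
  nb <- model$spec$n_conv_blocks
  if (is.null(layer)) layer <- nb
  if (!is_count(layer) || layer < 1 || layer > nb) {
    stopf("layer must be a conv block index in 1..%d", nb)
  }
  x <- stack_volumes(list(record$volume$data), model$spec, model$normalize_input)
  fp <- forward_pass(model, x, sex_onehot(record$sex), 1L, training = FALSE)
  bp <- backward_pass(fp$pred, fp$caches, 1, 1L, stop_at_block = layer)
  # activation at the target: output of the block's ReLU (V_l x C_l for N=1)
  acts <- x
  for (i in seq_len(bp$target_index)) {
    acts <- layer_forward(fp$pred$image_layers[[i]], acts, 1L, FALSE)$y
  }
  w <- colMeans(bp$d_target)                  # one weight per channel
  cam <- pmax(as.numeric(acts %*% w), 0)
  shp <- model$spec$conv_shapes[[layer]]
  cam <- upsample_trilinear(array(cam, dim = shp), model$spec$input_shape)
  if (normalize == "per_subject") cam <- minmax_norm(cam)
  attention_map(cam, normalize)
}

#' Average attention map
#'
#' Voxel-wise arithmetic mean of per-subject maps of identical shape.
#'
#' @param maps nonempty list of [attention_map]s.
#' @return an [attention_map] with the inputs' normalization flag.
#' @export
average_attention <- function(maps) {
  if (!length(maps)) stopf("empty map list")
  if (!all(vapply(maps, inherits, logical(1), "attention_map"))) {
    stopf("all elements must be attention_map objects")
  }
  d <- dim(maps[[1]]$data)
  acc <- array(0, dim = d)
  for (m in maps) {
    if (!identical(dim(m$data), d)) stopf("attention maps differ in shape")
    acc <- acc + m$data
  }
  attention_map(acc / length(maps), maps[[1]]$normalization)
}

#' Sex-difference attention map
#'
#' `mean(male maps) - mean(female maps)`, min-max normalized to \[0,1\]
#' (a constant difference normalizes to all zeros). Use
#' `normalize = "raw"` for the signed pre-normalization difference.
#'
#' @param male_maps,female_maps nonempty lists of [attention_map]s of
#'   consistent shape.
#' @param normalize `"minmax"` (default) or `"raw"`.
#' @return an [attention_map].
#' @export
difference_attention <- function(male_maps, female_maps,
                                 normalize = c("minmax", "raw")) {
  normalize <- match.arg(normalize)
  if (!length(male_maps) || !length(female_maps)) stopf("both groups must be nonempty")
  diff <- average_attention(male_maps)$data - average_attention(female_maps)$data
  if (normalize == "minmax") {
    attention_map(minmax_norm(diff), "per_subject")
  } else {
    attention_map(diff, "raw")
  }
}

#' Write an attention map as NIfTI for overlay
#'
#' @param map an [attention_map].
#' @param path output `.nii` / `.nii.gz` path.
#' @param spacing,origin spatial metadata of the underlying input grid.
#' @return the path, invisibly.
#' @export
write_attention <- function(map, path, spacing = c(1.5, 1.5, 1.5),
                            origin = c(0, 0, 0)) {
  if (!inherits(map, "attention_map")) stopf("map must be an attention_map")
  write_volume(volume_image(map$data, spacing, origin), path)
}
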