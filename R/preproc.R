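# Minimal preprocessing: isotropic cubic-spline resampling to the model grid
# and foreground intensity normalization. Inputs are assumed already
# nonlinearly registered to a common space; registration itself is the job of
# external tools and out of scope here.

# Cubic-spline resample along one axis (separable scheme). xin/xout are mm
# positions of voxel centers along that axis.
resample_axis_spline <- function(a, axis, xin, xout) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  # edge clamp: never extrapolate beyond the sampled extent
  xq <- pmin(pmax(xout, min(xin)), max(xin))
  outm <- matrix(0, nrow = length(xout), ncol = ncol(m))
  for (j in seq_len(ncol(m))) {
    outm[, j] <- stats::splinefun(xin, m[, j], method = "natural")(xq)
  }
  res <- array(outm, dim = c(length(xout), d[perm[2]], d[perm[3]]))
  aperm(res, order(perm))
}

#' Resample a volume to isotropic spacing with cubic splines
#'
#' Separable natural cubic-spline interpolation along each axis brings the
#' volume to `target_spacing` mm isotropic voxels. When `output_shape` is
#' omitted the output grid covers the input extent
#' (`floor(extent_mm / target_spacing)` voxels per axis); the production
#' default grid for model input is 105 x 127 x 105 at 1.5 mm. Queries beyond
#' the input extent are edge-clamped.
#'
#' @param vol a [volume_image].
#' @param target_spacing isotropic output voxel size in mm (default 1.5).
#' @param output_shape optional integer triple forcing the output grid shape.
#' @return a resampled [volume_image] with isotropic spacing.
#' @export
resample_isotropic <- function(vol, target_spacing = 1.5, output_shape = NULL) {
  assert_volume(vol)
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0) {
    stopf("target_spacing must be a positive scalar (mm)")
  }
  d <- dim(vol$data)
  if (is.null(output_shape)) {
    output_shape <- pmax(1L, as.integer(floor(d * vol$spacing / target_spacing)))
  } else {
    output_shape <- as.integer(output_shape)
    if (length(output_shape) != 3L || any(output_shape < 1L)) {
      stopf("output_shape must be 3 positive integers")
    }
  }
  a <- vol$data
  for (axis in 1:3) {
    xin <- (seq_len(d[axis]) - 1) * vol$spacing[axis]
    xout <- (seq_len(output_shape[axis]) - 1) * target_spacing
    if (length(xin) < 2L) {
      # degenerate single-plane axis: replicate
      a <- do.call(`[`, c(list(a), lapply(1:3, function(k) {
        if (k == axis) rep(1L, output_shape[axis]) else seq_len(dim(a)[k])
      }), list(drop = FALSE)))
    } else {
      a <- resample_axis_spline(a, axis, xin, xout)
    }
    d <- dim(a)
  }
  volume_image(a, spacing = rep(target_spacing, 3), origin = vol$origin)
}

#' Normalize volume intensity to zero mean, unit variance over the foreground
#'
#' Foreground is the set of nonzero voxels (exact zeros are treated as
#' resampling background and left untouched), which makes the operation
#' idempotent. Rejects constant volumes.
#'
#' @param vol a [volume_image].
#' @return a normalized [volume_image].
#' @export
normalize_intensity <- function(vol) {
  assert_volume(vol)
  mask <- vol$data != 0
  if (!any(mask)) stopf("cannot normalize: volume has zero variance (all background)")
  v <- vol$data[mask]
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) {
    stopf("cannot normalize: volume has zero variance over the foreground")
  }
  out <- vol$data
  out[mask] <- (v - mean(v)) / s
  volume_image(out, spacing = vol$spacing, origin = vol$origin)
}
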