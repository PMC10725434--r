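# Shared interpolation machinery: trilinear sampling, rigid transforms for
# augmentation, and trilinear upsampling for attention maps. Coordinates are
# 0-based voxel indices throughout.

# Sample arr at fractional voxel coordinates (vectors x,y,z). Outside the
# grid: zero fill (clamp = FALSE) or edge clamp (clamp = TRUE).
trilinear_sample <- function(arr, x, y, z, clamp = FALSE) {
  d <- dim(arr)
  if (clamp) {
    x <- pmin(pmax(x, 0), d[1] - 1)
    y <- pmin(pmax(y, 0), d[2] - 1)
    z <- pmin(pmax(z, 0), d[3] - 1)
  }
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  out <- numeric(length(x))
  corner <- function(ix, iy, iz) {
    ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
      iz >= 0 & iz <= d[3] - 1
    v <- numeric(length(ix))
    if (any(ok)) {
      idx <- 1 + ix[ok] + d[1] * (iy[ok] + d[2] * iz[ok])
      v[ok] <- arr[idx]
    }
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    nz <- wgt != 0
    if (any(nz)) {
      v <- corner(x0 + dx, y0 + dy, z0 + dz)
      out <- out + wgt * v
    }
  }
  out
}

euler_rotation <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

grid_coords <- function(d) {
  # 0-based voxel index grid as three vectors of length prod(d)
  list(
    x = rep.int(0:(d[1] - 1), d[2] * d[3]),
    y = rep.int(rep(0:(d[2] - 1), each = d[1]), d[3]),
    z = rep(0:(d[3] - 1), each = d[1] * d[2])
  )
}

#' Apply a rigid (rotation + integer translation) transform to a volume
#'
#' Rotates about the grid center by three Euler angles (degrees, applied
#' X then Y then Z) and then shifts the sampling grid by `shift_vox`, so that
#' `out[v] = in(R^-1 (v - c) + c + shift)`. Trilinear interpolation, zero
#' fill outside the grid. With zero angles and shift `(+1,0,0)` the content
#' moves one voxel toward the origin along axis 1 and the trailing plane is
#' zero-filled.
#'
#' @param vol a [volume_image].
#' @param angles_deg numeric length-3 Euler angles in degrees.
#' @param shift_vox numeric length-3 translation in voxels.
#' @return a transformed [volume_image] with the same grid shape.
#' @export
apply_rigid <- function(vol, angles_deg = c(0, 0, 0), shift_vox = c(0, 0, 0)) {
  assert_volume(vol)
  d <- dim(vol$data)
  g <- grid_coords(d)
  ctr <- (d - 1) / 2
  rinv <- t(euler_rotation(angles_deg))   # inverse of a rotation = transpose
  px <- g$x - ctr[1]; py <- g$y - ctr[2]; pz <- g$z - ctr[3]
  sx <- rinv[1, 1] * px + rinv[1, 2] * py + rinv[1, 3] * pz + ctr[1] + shift_vox[1]
  sy <- rinv[2, 1] * px + rinv[2, 2] * py + rinv[2, 3] * pz + ctr[2] + shift_vox[2]
  sz <- rinv[3, 1] * px + rinv[3, 2] * py + rinv[3, 3] * pz + ctr[3] + shift_vox[3]
  out <- trilinear_sample(vol$data, sx, sy, sz)
  volume_image(array(out, dim = d), spacing = vol$spacing, origin = vol$origin)
}

# Trilinear upsampling (align-corners = FALSE convention, edge clamped):
# output voxel center j maps to input coordinate (j + .5) * din/dout - .5.
upsample_trilinear <- function(arr, out_shape) {
  din <- dim(arr)
  out_shape <- as.integer(out_shape)
  if (identical(din, out_shape)) return(arr)
  g <- grid_coords(out_shape)
  sc <- din / out_shape
  out <- trilinear_sample(arr,
                          (g$x + 0.5) * sc[1] - 0.5,
                          (g$y + 0.5) * sc[2] - 0.5,
                          (g$z + 0.5) * sc[3] - 0.5,
                          clamp = TRUE)
  array(out, dim = out_shape)
}
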