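# Synthetic aging-brain phantoms.
#
# Each phantom is a registered, brain-like volume on a fixed grid whose
# morphology encodes age and sex: a bright cortical shell that thins with
# age, a dark central ventricle that grows with age (the hallmark aging
# signals that attention maps localize around the lateral ventricles), a
# designated frontal subregion whose intensity carries the sex contrast, and
# additive Gaussian noise. Boundaries are smoothed over ~1 voxel so the age
# signal stays sub-voxel continuous even on coarse desk-scale grids.

#' Phantom generator parameters
#'
#' Defaults describe a 160 mm field of view: head radius 70 mm, cortical
#' shell 30 mm thick at age 0 thinning by 0.15 mm/year, central ventricle
#' 6 mm at age 0 growing by 0.25 mm/year. All derived radii/thicknesses stay
#' positive and nested over the supported age range 18-90 years; parameter
#' sets violating that are rejected at construction.
#'
#' @param grid_shape integer triple, voxels per axis (all >= 16).
#' @param spacing_mm voxel size in mm; default spans a 160 mm field of view.
#' @param head_radius_mm outer radius of the bright shell.
#' @param ventricle_base_radius ventricle radius at age 0 (mm).
#' @param ventricle_age_slope ventricle growth (mm/year, positive).
#' @param shell_base_thickness shell thickness at age 0 (mm).
#' @param shell_age_slope shell thinning (mm/year, negative).
#' @param sex_scale_male intensity factor applied to the designated frontal
#'   subregion for males (1 = no visible sex contrast).
#' @param sex_age_slope extra ventricle growth for males (mm/year); default 0
#'   so that, by default, the sexes differ only inside the frontal subregion.
#'   Set positive to create a world where the image alone confounds age and
#'   sex and the sex input is genuinely informative.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(16L, 16L, 16L),
                           spacing_mm = 160 / max(grid_shape),
                           head_radius_mm = 70,
                           ventricle_base_radius = 6,
                           ventricle_age_slope = 0.25,
                           shell_base_thickness = 30,
                           shell_age_slope = -0.15,
                           sex_scale_male = 1.08,
                           sex_age_slope = 0,
                           noise_sd = 0.02) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    stopf("grid_shape must be 3 integers, each >= 16")
  }
  p <- structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                      head_radius_mm = head_radius_mm,
                      ventricle_base_radius = ventricle_base_radius,
                      ventricle_age_slope = ventricle_age_slope,
                      shell_base_thickness = shell_base_thickness,
                      shell_age_slope = shell_age_slope,
                      sex_scale_male = sex_scale_male,
                      sex_age_slope = sex_age_slope,
                      noise_sd = noise_sd),
                 class = "phantom_params")
  for (age in c(18, 90)) for (sex in c("male", "female")) {
    geo <- phantom_geometry(age, sex, p)
    if (geo$shell_thickness <= 0) {
      stopf("shell thickness non-positive (%.2f mm) at age %g", geo$shell_thickness, age)
    }
    if (geo$ventricle_radius <= 0) {
      stopf("ventricle radius non-positive (%.2f mm) at age %g", geo$ventricle_radius, age)
    }
    if (geo$ventricle_radius >= p$head_radius_mm - geo$shell_thickness) {
      stopf("ventricle (%.1f mm) reaches the shell at age %g; shrink slopes",
            geo$ventricle_radius, age)
    }
  }
  p
}

# Closed-form morphology for a given age/sex; the generator and the tests
# both consume this, so measured geometry can be checked against it.
phantom_geometry <- function(age, sex, params) {
  vslope <- params$ventricle_age_slope +
    if (sex == "male") params$sex_age_slope else 0
  list(
    ventricle_radius = params$ventricle_base_radius + vslope * age,
    shell_thickness = params$shell_base_thickness + params$shell_age_slope * age
  )
}

# Smooth step: ~0 below the crossing, ~1 above, transition width w (mm).
smooth_gate <- function(signed_dist_mm, w) stats::plogis(signed_dist_mm * 4 / w)

# Mask of the designated frontal (anterior, +y) subregion carrying the sex
# contrast: inside the head, beyond +20 mm of the center along axis 2.
phantom_sex_region <- function(params) {
  d <- params$grid_shape
  g <- grid_coords(d)
  ctr <- (d - 1) / 2
  sp <- params$spacing_mm
  r <- sqrt(((g$x - ctr[1]) * sp)^2 + ((g$y - ctr[2]) * sp)^2 +
              ((g$z - ctr[3]) * sp)^2)
  region <- (g$y - ctr[2]) * sp > 20 & r < params$head_radius_mm
  array(region, dim = d)
}

#' Generate a synthetic aging-brain phantom
#'
#' Deterministic for a fixed `(age, sex, params, subject_seed)` tuple. The
#' volume contains a bright outer shell whose thickness shrinks linearly with
#' age, a dark central ventricle whose radius grows linearly with age,
#' sex-dependent intensity scaling of the designated frontal subregion, and
#' i.i.d. Gaussian noise added last.
#'
#' @param age chronological age in years, within \[18, 90\].
#' @param sex `"male"` or `"female"`.
#' @param params a [phantom_params] object.
#' @param subject_seed integer seed for the subject's noise draw.
#' @return a [volume_image].
#' @examples
#' p <- phantom_params(noise_sd = 0)
#' v20 <- generate_phantom(20, "female", p, subject_seed = 1)
#' v80 <- generate_phantom(80, "female", p, subject_seed = 1)
#' # ventricle (dark center) is larger at 80:
#' sum(v80$data < 0.15) > sum(v20$data < 0.15)
#' @export
generate_phantom <- function(age, sex, params = phantom_params(),
                             subject_seed = 0L) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) ||
      age < 18 || age > 90) {
    stopf("age must lie in [18, 90] years, got %s", format(age))
  }
  if (!inherits(params, "phantom_params")) stopf("params must be phantom_params")
  geo <- phantom_geometry(age, sex, params)
  if (geo$ventricle_radius <= 0 || geo$shell_thickness <= 0) {
    stopf("derived geometry non-positive at age %g", age)
  }
  d <- params$grid_shape
  sp <- params$spacing_mm
  g <- grid_coords(d)
  ctr <- (d - 1) / 2
  r <- sqrt(((g$x - ctr[1]) * sp)^2 + ((g$y - ctr[2]) * sp)^2 +
              ((g$z - ctr[3]) * sp)^2)
  w <- sp  # edge transition ~1 voxel
  rout <- params$head_radius_mm
  rin <- rout - geo$shell_thickness
  f_head <- smooth_gate(rout - r, w)       # 1 inside the head
  f_shell <- smooth_gate(r - rin, w)       # 1 in the shell band
  f_vent <- smooth_gate(geo$ventricle_radius - r, w)  # 1 in the ventricle
  tissue <- 1.0 * f_shell + 0.5 * (1 - f_shell)
  img <- f_head * (tissue * (1 - f_vent) + 0.05 * f_vent)
  img <- array(img, dim = d)
  if (sex == "male" && params$sex_scale_male != 1) {
    region <- phantom_sex_region(params)
    img[region] <- img[region] * params$sex_scale_male
  }
  if (params$noise_sd > 0) {
    noise <- with_seed_(subject_seed,
                        stats::rnorm(prod(d), sd = params$noise_sd))
    img <- img + array(noise, dim = d)
  }
  volume_image(img, spacing = rep(sp, 3),
               origin = -ctr * sp)
}

#' Analytic ventricle mask for a phantom
#'
#' Ground-truth region of the dark central ventricle at a given age,
#' optionally dilated — the reference region for attention-localization
#' checks.
#'
#' @param age age in years.
#' @param sex `"male"` or `"female"`.
#' @param params a [phantom_params] object.
#' @param dilate_mm radial dilation of the mask in mm (default 0).
#' @return logical 3D array on the phantom grid.
#' @export
phantom_ventricle_mask <- function(age, sex, params, dilate_mm = 0) {
  geo <- phantom_geometry(age, match.arg(sex, c("male", "female")), params)
  d <- params$grid_shape
  sp <- params$spacing_mm
  g <- grid_coords(d)
  ctr <- (d - 1) / 2
  r <- sqrt(((g$x - ctr[1]) * sp)^2 + ((g$y - ctr[2]) * sp)^2 +
              ((g$z - ctr[3]) * sp)^2)
  array(r <= geo$ventricle_radius + dilate_mm, dim = d)
}

#' Generate a cohort of phantom subjects
#'
#' Ages are uniform on `[age_low, age_high]`, sexes Bernoulli with
#' `male_fraction`, per-subject noise seeds derived reproducibly from the
#' master seed. The result carries the records (with attached volumes) and a
#' demographic table.
#'
#' @param n number of subjects (>= 1).
#' @param age_low,age_high age range in years (within \[18, 90\]).
#' @param male_fraction probability a subject is male.
#' @param params a [phantom_params] object.
#' @param seed master integer seed.
#' @return an object of class `subject_cohort`: a list with `records` (list
#'   of [subject_record]) and `demographics` (data.frame id, age, sex).
#' @export
generate_cohort <- function(n, age_low = 18, age_high = 90,
                            male_fraction = 0.5,
                            params = phantom_params(), seed = 1L) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer, got %s", format(n))
  draws <- with_seed_(seed, list(
    ages = stats::runif(n, age_low, age_high),
    male = stats::runif(n) < male_fraction
  ))
  records <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- if (draws$male[i]) "male" else "female"
    vol <- generate_phantom(draws$ages[i], sex, params,
                            subject_seed = derive_seed(seed, i))
    records[[i]] <- subject_record(sprintf("sub%04d", i), draws$ages[i], sex, vol)
  }
  demographics <- data.frame(
    id = vapply(records, `[[`, character(1), "id"),
    age = draws$ages,
    sex = ifelse(draws$male, "male", "female"),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, demographics = demographics,
                 params = params, seed = seed),
            class = "subject_cohort")
}

#' @export
print.subject_cohort <- function(x, ...) {
  cat(sprintf("<subject_cohort> n=%d, ages %.1f-%.1f, %d male / %d female\n",
              nrow(x$demographics), min(x$demographics$age),
              max(x$demographics$age), sum(x$demographics$sex == "male"),
              sum(x$demographics$sex == "female")))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Saves each volume as gzipped NIfTI plus a tab-delimited demographic table
#' (columns id, age, sex, path).
#'
#' @param cohort a `subject_cohort`.
#' @param dir output directory (created if absent).
#' @return path of the demographic table, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "subject_cohort")) stopf("cohort must be a subject_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$demographics
  tab$path <- file.path(dir, paste0(tab$id, ".nii.gz"))
  for (i in seq_along(cohort$records)) {
    write_volume(cohort$records[[i]]$volume, tab$path[i])
  }
  out <- file.path(dir, "demographics.tsv")
  utils::write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `demographics.tsv` and the NIfTI volumes.
#' @return a `subject_cohort`.
#' @export
read_cohort <- function(dir) {
  tabpath <- file.path(dir, "demographics.tsv")
  if (!file.exists(tabpath)) stopf("no demographics.tsv under '%s'", dir)
  tab <- utils::read.delim(tabpath, stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(tab)), function(i) {
    subject_record(tab$id[i], tab$age[i], tab$sex[i],
                   volume = read_volume(tab$path[i]), path = tab$path[i])
  })
  structure(list(records = records, demographics = tab[c("id", "age", "sex")]),
            class = "subject_cohort")
}

#' Augmentation configuration
#'
#' Mirrors the training-time augmentation protocol: with probability
#' `probability`, a random 3D rotation with each Euler angle uniform in
#' ±`rotation_range_deg` followed by an integer-voxel translation uniform in
#' ±`translation_range_vox` per axis.
#'
#' @param probability chance a sample is augmented (default 0.3).
#' @param rotation_range_deg symmetric rotation bound in degrees (default 10).
#' @param translation_range_vox symmetric translation bound in voxels
#'   (default 10).
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(probability = 0.3, rotation_range_deg = 10,
                           translation_range_vox = 10) {
  if (!is.numeric(probability) || probability < 0 || probability > 1) {
    stopf("probability must lie in [0, 1]")
  }
  if (rotation_range_deg < 0 || translation_range_vox < 0) {
    stopf("augmentation ranges must be >= 0")
  }
  structure(list(probability = probability,
                 rotation_range_deg = rotation_range_deg,
                 translation_range_vox = as.integer(translation_range_vox)),
            class = "augment_config")
}

#' Randomly augment a volume
#'
#' With probability `cfg$probability` applies a random rotation then integer
#' translation (see [augment_config()]); otherwise returns the input
#' unchanged. Only the volume is touched — demographic labels are never
#' altered. Deterministic given `draw_seed`.
#'
#' @param vol a [volume_image].
#' @param cfg an [augment_config].
#' @param draw_seed integer seed for this draw.
#' @return a [volume_image] with the same grid shape.
#' @export
augment <- function(vol, cfg, draw_seed = 0L) {
  assert_volume(vol)
  if (!inherits(cfg, "augment_config")) stopf("cfg must be an augment_config")
  draw <- with_seed_(draw_seed, {
    hit <- stats::runif(1) < cfg$probability
    angles <- stats::runif(3, -cfg$rotation_range_deg, cfg$rotation_range_deg)
    tr <- cfg$translation_range_vox
    shift <- if (tr > 0) sample(seq(-tr, tr), 3, replace = TRUE) else c(0L, 0L, 0L)
    list(hit = hit, angles = angles, shift = shift)
  })
  if (!draw$hit) return(vol)
  apply_rigid(vol, draw$angles, draw$shift)
}
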