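#' 3D volume container
#'
#' A `volume_image` bundles a 3D intensity array with its voxel spacing (mm)
#' and the world offset of voxel (1,1,1). It is the imaging unit consumed by
#' every operation in the package.
#'
#' @param data numeric 3D array of intensities.
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, mm offset of the first voxel.
#' @return an object of class `volume_image`.
#' @examples
#' v <- volume_image(array(rnorm(8^3), dim = c(8, 8, 8)), spacing = c(2, 2, 2))
#' dim(v$data)
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("volume data must be a 3D array, got %s dimension(s)",
          length(dim(data)))
  }
  if (!all(is.finite(data))) stopf("volume data must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("spacing must be 3 positive finite values")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stopf("origin must be 3 finite values")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume_image <- function(x) inherits(x, "volume_image")

assert_volume <- function(x, what = "vol") {
  if (!is_volume_image(x)) stopf("%s must be a volume_image", what)
  invisible(x)
}

#' Subject record
#'
#' Couples a subject id, chronological age and sex category with its volume.
#'
#' @param id character scalar identifier.
#' @param age chronological age in years.
#' @param sex `"male"` or `"female"`.
#' @param volume a [volume_image] (or `NULL` when volumes live on disk).
#' @param path optional file path of the stored volume.
#' @return an object of class `subject_record`.
#' @export
subject_record <- function(id, age, sex, volume = NULL, path = NA_character_) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age)) {
    stopf("age must be a finite scalar")
  }
  if (!is.null(volume)) assert_volume(volume, "volume")
  structure(list(id = as.character(id), age = as.numeric(age), sex = sex,
                 volume = volume, path = path),
            class = "subject_record")
}

# Accept either a subject_cohort or a bare list of records.
as_records <- function(x) {
  if (inherits(x, "subject_cohort")) return(x$records)
  if (inherits(x, "subject_record")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "subject_record"))) {
    return(x)
  }
  stopf("expected a subject_cohort or a list of subject_record objects")
}

record_ages <- function(records) vapply(records, `[[`, numeric(1), "age")
record_sexes <- function(records) vapply(records, `[[`, character(1), "sex")
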