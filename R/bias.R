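# Linear bias correction of the brain-age gap.
#
# Deep age regressors systematically overpredict young and underpredict old
# subjects (regression dilution). The remedy fitted here is ordinary least
# squares of the gap (predicted - age) on chronological age; the fitted
# offset is subtracted from the predictions. Fit on training-side
# predictions, apply to held-out or external sets.

#' Fit the linear bias model
#'
#' OLS of `gap = predicted - age` on `age`.
#'
#' @param ages chronological ages (years), length >= 2 with nonzero variance.
#' @param predicted predicted ages (years), same length.
#' @return an object of class `bias_model` with `intercept` (years), `slope`
#'   (years gap per year of age) and `fit_n`.
#' @examples
#' m <- fit_bias(c(20, 40, 60), c(30, 40, 50))
#' c(m$intercept, m$slope)  # 20, -0.5
#' @export
fit_bias <- function(ages, predicted) {
  if (length(ages) != length(predicted)) {
    stopf("length mismatch: %d ages vs %d predictions", length(ages), length(predicted))
  }
  if (length(ages) < 2L) stopf("need at least 2 observations to fit bias")
  if (stats::var(ages) == 0) stopf("zero age variance: bias slope unidentifiable")
  gap <- predicted - ages
  fit <- stats::lm.fit(cbind(1, ages), gap)
  co <- fit$coefficients
  if (any(!is.finite(co))) stopf("bias fit produced non-finite coefficients")
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 fit_n = length(ages)),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> gap = %.4g %+.4g * age (fit on n=%d)\n",
              x$intercept, x$slope, x$fit_n))
  invisible(x)
}

#' Apply bias correction
#'
#' `corrected_i = predicted_i - (intercept + slope * age_i)`.
#'
#' @param model a [fit_bias()] model.
#' @param ages chronological ages (years).
#' @param predicted predicted ages (years), same length.
#' @return corrected predicted ages (years).
#' @export
apply_bias <- function(model, ages, predicted) {
  if (!inherits(model, "bias_model")) stopf("model must be a bias_model")
  if (length(ages) != length(predicted)) {
    stopf("length mismatch: %d ages vs %d predictions", length(ages), length(predicted))
  }
  predicted - (model$intercept + model$slope * ages)
}
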