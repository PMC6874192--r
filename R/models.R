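# Empirical single-predictor models: scatter factor as a linear function of
# %air, %dense bone, or compensator IQR. Fits are shipped as data (JSON), not
# hard-coded coefficients.

#' Fit a linear scatter-factor predictor
#'
#' Ordinary least squares of factor values on a single predictor.
#'
#' @param xs Predictor values (percent air, percent dense bone, or IQR in cm).
#' @param ys Factor values (PSF or CSF).
#' @param predictor_name One of `"air_pct"`, `"dense_bone_pct"`, `"iqr_cm"`.
#' @return Object of class `scatter_fit`: `slope`, `intercept`, `r2`, `n`,
#'   `x_range`, `predictor_name`.
#' @export
fit_line <- function(xs, ys, predictor_name = c("air_pct", "dense_bone_pct", "iqr_cm")) {
  predictor_name <- match.arg(predictor_name)
  if (length(xs) != length(ys)) stop_invalid("xs and ys must have equal length")
  if (length(xs) < 2L) stop_invalid("need at least 2 points")
  if (diff(range(xs)) == 0) {
    stop(errorCondition("degenerate fit: all predictor values equal",
                        class = c("protoscatter_singular_fit", "protoscatter_error")))
  }
  fit <- stats::lm(ys ~ xs)
  sm <- suppressWarnings(summary(fit))  # exact lines trip lm's perfect-fit note
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared, n = length(xs), x_range = range(xs),
                 predictor_name = predictor_name,
                 slope_se = sm$coefficients[2, 2]),
            class = "scatter_fit")
}

#' @export
print.scatter_fit <- function(x, ...) {
  cat(sprintf("<scatter_fit> factor = %.6g %+.6g * %s  (r2 %.3f, n %d)\n",
              x$intercept, x$slope, x$predictor_name, x$r2, x$n))
  invisible(x)
}

#' Predict a scatter factor from a fitted model
#'
#' Single-predictor models only hold when one heterogeneity type dominates
#' the field: prediction refuses (overridably) when both appreciable air and
#' appreciable dense bone are declared for the same field. Predictions beyond
#' 1.5 times the fitted predictor range are flagged as extrapolations.
#'
#' @param object A `scatter_fit`.
#' @param x Predictor value(s).
#' @param air_pct,dense_bone_pct Optional field composition context, percent.
#' @param allow_mixed Override the mixed air/bone guard.
#' @param ... Unused.
#' @return Numeric predictions with logical attribute `extrapolated`.
#' @export
predict.scatter_fit <- function(object, x, air_pct = NULL, dense_bone_pct = NULL,
                                allow_mixed = FALSE, ...) {
  if (!is.null(air_pct) && !is.null(dense_bone_pct) &&
      air_pct > 5 && dense_bone_pct > 2 && !allow_mixed) {
    stop_invalid(paste("field has appreciable air (%.1f%%) and dense bone (%.1f%%);",
                       "single-predictor models do not apply (allow_mixed = TRUE to override)"),
                 air_pct, dense_bone_pct)
  }
  lo <- object$x_range[1]; hi <- object$x_range[2]
  span <- hi - lo
  # 1.5x the fitted range, centred on the range
  extrap <- x < lo - 0.25 * span | x > hi + 0.25 * span
  if (any(extrap)) {
    warning("prediction beyond 1.5x the fitted predictor range")
  }
  structure(object$intercept + object$slope * x, extrapolated = extrap)
}

#' Write a fitted model to JSON
#'
#' @param fit A `scatter_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(predictor = fit$predictor_name, slope = fit$slope,
         intercept = fit$intercept, r2 = fit$r2, n = fit$n,
         x_range = fit$x_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' Accepts fits produced by [write_fit_json()] or user-entered literature
#' coefficients with the same keys.
#'
#' @param path JSON path.
#' @return A `scatter_fit`.
#' @export
read_fit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = j$slope, intercept = j$intercept,
                 r2 = j$r2 %||% NA_real_, n = j$n %||% NA_integer_,
                 x_range = j$x_range %||% c(NA_real_, NA_real_),
                 predictor_name = j$predictor, slope_se = NA_real_),
            class = "scatter_fit")
}
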