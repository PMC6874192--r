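# HU -> material conversion: five-class binning and a piecewise-linear
# stopping-power calibration in the spirit of the Schneider CT calibration.

HU_MIN <- -1024L
HU_MAX <- 3000L

#' Material class labels
#'
#' The five material classes used for field-composition analysis, in
#' increasing HU order: air, thin tissue, soft tissue, bone, dense bone.
#'
#' @return Character vector of the five class labels.
#' @export
material_classes <- function() {
  c("air", "thin_tissue", "soft_tissue", "bone", "dense_bone")
}

# Upper bin edges (right-closed). HU <= -650 is air, ..., HU > 500 and
# <= 1245 is dense bone; values are clamped to [-1000, 1245] so every HU in
# the CT range maps to exactly one class.
.material_edges <- c(-650, -500, 125, 500)

#' Classify Hounsfield units into the five material classes
#'
#' Bins follow the study convention: air (to -650 HU), thin tissue (to
#' -500 HU), soft tissue (to 125 HU), bone (to 500 HU), dense bone (to
#' 1245 HU). Values below -1000 clamp to air and values above 1245 map to
#' dense bone, so classification is total on the CT range.
#'
#' @param hu Integer-valued HU, vectorised. Must lie in [-1024, 3000].
#' @return Factor with levels `material_classes()`.
#' @examples
#' classify_hu(c(-800, 0, 600))
#' @export
classify_hu <- function(hu) {
  if (length(hu) == 0L) stop_invalid("hu must be non-empty")
  if (anyNA(hu) || !is.numeric(hu)) stop_invalid("hu must be numeric and non-missing")
  if (any(hu != round(hu))) stop_invalid("hu must be integer-valued")
  if (any(hu < HU_MIN) || any(hu > HU_MAX)) {
    stop_invalid("hu out of range [%d, %d]", HU_MIN, HU_MAX)
  }
  # right-closed bins: count of upper edges strictly below hu
  idx <- 1L + (hu > -650) + (hu > -500) + (hu > 125) + (hu > 500)
  factor(material_classes()[idx], levels = material_classes())
}

#' Read a stopping-power calibration table
#'
#' A calibration is a set of knots `(hu, rsp, density, inv_x0)`; properties at
#' intermediate HU are piecewise-linear interpolations, clamped outside the
#' knot range. `inv_x0` is the inverse radiation length relative to water.
#'
#' @param path CSV file with header `hu,rsp,density,inv_x0`.
#' @return An object of class `rsp_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_config("calibration file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("hu", "rsp", "density", "inv_x0")
  if (!all(needed %in% names(df))) {
    stop_config("calibration must have columns %s", paste(needed, collapse = ", "))
  }
  as_calibration(df)
}

#' Build a calibration object from a knot table
#'
#' @param df Data frame with columns `hu`, `rsp`, `density`, `inv_x0`.
#' @return An object of class `rsp_calibration`.
#' @export
as_calibration <- function(df) {
  if (nrow(df) == 0L) stop_config("empty calibration")
  df <- df[order(df$hu), , drop = FALSE]
  if (any(diff(df$hu) <= 0)) stop_config("calibration HU knots must be strictly increasing")
  if (min(df$hu) > -1000 || max(df$hu) < 1245) {
    stop_config("calibration must cover [-1000, 1245] HU")
  }
  if (any(df$rsp < 0) || any(df$density < 0) || any(df$inv_x0 < 0)) {
    stop_config("calibration values must be non-negative")
  }
  structure(list(knots = df), class = "rsp_calibration")
}

#' The packaged default calibration
#'
#' Seven knots spanning air to dense bone, qualitatively reproducing the
#' water/air/bone ordering of stopping power and scattering strength without
#' embedding full stoichiometric tissue tables.
#'
#' @return An `rsp_calibration`.
#' @export
default_calibration <- function() {
  path <- system.file("extdata", "default_calibration.csv", package = "protoscatter")
  read_calibration(path)
}

#' Material properties at given HU
#'
#' Piecewise-linear interpolation of the calibration knots; exact at knots;
#' clamped to the end knots outside the covered HU range. Grids store integer
#' HU, but the calibration itself is evaluated in double precision at any HU.
#'
#' @param hu HU values (vectorised), in [-1024, 3000].
#' @param cal An `rsp_calibration`.
#' @return Data frame with columns `hu`, `rsp`, `density`, `inv_x0`.
#' @export
material_properties <- function(hu, cal = default_calibration()) {
  if (!inherits(cal, "rsp_calibration")) stop_config("cal must be an rsp_calibration")
  if (any(hu < HU_MIN) || any(hu > HU_MAX)) {
    stop_invalid("hu out of range [%d, %d]", HU_MIN, HU_MAX)
  }
  k <- cal$knots
  data.frame(
    hu = hu,
    rsp = stats::approx(k$hu, k$rsp, xout = hu, rule = 2)$y,
    density = stats::approx(k$hu, k$density, xout = hu, rule = 2)$y,
    inv_x0 = stats::approx(k$hu, k$inv_x0, xout = hu, rule = 2)$y
  )
}

# Dense lookup tables over the full HU range for fast voxel access during ray
# tracing: value for HU h sits at index h - HU_MIN + 1.
build_material_tables <- function(cal = default_calibration()) {
  hu <- HU_MIN:HU_MAX
  props <- material_properties(hu, cal)
  list(rsp = props$rsp, inv_x0 = props$inv_x0, density = props$density,
       offset = 1L - HU_MIN)
}

# Table lookup helpers (hu integer vector -> property vector)
lookup_rsp <- function(tabs, hu) tabs$rsp[hu + tabs$offset]
lookup_inv_x0 <- function(tabs, hu) tabs$inv_x0[hu + tabs$offset]
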