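# Field material composition: isodose region selection, HU histogram, and the
# five-class percentage breakdown.

#' Isodose mask of a dose array
#'
#' Voxels receiving at least `fraction` of the maximum dose (inclusive) and a
#' strictly positive dose. At `fraction = 0.5` this is the study's
#' composition-analysis region.
#'
#' @param dose 3-D numeric array (or list from [compute_dose_grid()]).
#' @param fraction Threshold fraction of the maximum, in [0, 1].
#' @return Logical array.
#' @export
isodose_mask <- function(dose, fraction = 0.5) {
  if (is.list(dose) && !is.null(dose$dose)) dose <- dose$dose
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1) {
    stop_invalid("fraction must be in [0, 1]")
  }
  mx <- max(dose)
  if (!is.finite(mx) || mx <= 0) stop_degenerate("dose grid has no positive maximum")
  dose >= fraction * mx & dose > 0
}

#' Material composition of a masked region
#'
#' Fraction of masked voxels in each of the five HU material classes; the
#' air and dense-bone fractions are the study's predictors A and B (as
#' percentages).
#'
#' @param grid An `hu_grid`.
#' @param mask Logical array congruent with the grid.
#' @return Object of class `composition_breakdown`: named numeric vector of
#'   fractions over `material_classes()`, summing to 1, with attribute
#'   `n_voxels`.
#' @export
composition_breakdown <- function(grid, mask) {
  if (!is.logical(mask) || !identical(dim(mask), dim(grid$values))) {
    stop_invalid("mask must be a logical array congruent with the grid")
  }
  n <- sum(mask)
  if (n == 0L) stop_insufficient("mask selects no voxels")
  cls <- classify_hu(grid$values[mask])
  counts <- table(cls)
  frac <- as.numeric(counts) / n
  names(frac) <- names(counts)
  structure(frac, n_voxels = n, class = c("composition_breakdown", "numeric"))
}

#' @export
print.composition_breakdown <- function(x, ...) {
  cat("<composition_breakdown>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %6.1f%%\n", nm, 100 * unclass(x)[nm]))
  invisible(x)
}

#' Air percentage of a composition (predictor A)
#' @param comp A `composition_breakdown`.
#' @return Percentage 0-100.
#' @export
air_pct <- function(comp) 100 * unclass(comp)[["air"]]

#' Dense-bone percentage of a composition (predictor B)
#' @param comp A `composition_breakdown`.
#' @return Percentage 0-100.
#' @export
dense_bone_pct <- function(comp) 100 * unclass(comp)[["dense_bone"]]

#' HU histogram of a masked region
#'
#' @param grid An `hu_grid`.
#' @param mask Logical array congruent with the grid.
#' @param binwidth Histogram bin width in HU.
#' @return Data frame with columns `hu` (bin center) and `count`.
#' @export
hu_histogram <- function(grid, mask, binwidth = 10) {
  if (sum(mask) == 0L) stop_insufficient("mask selects no voxels")
  hu <- grid$values[mask]
  bins <- floor((hu + 1024) / binwidth)
  tab <- table(bins)
  data.frame(hu = (as.integer(names(tab)) + 0.5) * binwidth - 1024,
             count = as.integer(tab))
}
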