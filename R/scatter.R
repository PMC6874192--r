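# The verification-plan workflow: dose in the patient, dose at the matched
# water-equivalent depth in a homogeneous water phantom with the compensator,
# and again without it. PSF = d_p/c / d_vp/c, CSF = d_vp/c / d_vp/nc,
# CPSF = PSF * CSF.

#' Scatter factors from the three dose values
#'
#' Pure ratio arithmetic: PSF is the patient dose over the verification dose
#' with compensator; CSF is the verification dose with compensator over that
#' without; CPSF is their product.
#'
#' @param d_patient Dose in the patient with the compensator.
#' @param d_verif_comp Dose in the water verification geometry with the
#'   compensator, at the matched water-equivalent depth.
#' @param d_verif_nocomp Same point and beam without the compensator.
#' @param wed_cm Matched water-equivalent depth (carried through for
#'   reporting).
#' @return Object of class `scatter_factors`.
#' @export
scatter_factors <- function(d_patient, d_verif_comp, d_verif_nocomp, wed_cm = NA_real_) {
  if (any(c(d_patient, d_verif_comp, d_verif_nocomp) <= 0)) {
    stop_degenerate("all three doses must be positive (got %g, %g, %g)",
                    d_patient, d_verif_comp, d_verif_nocomp)
  }
  psf <- d_patient / d_verif_comp
  csf <- d_verif_comp / d_verif_nocomp
  structure(list(psf = psf, csf = csf, cpsf = psf * csf, wed_cm = wed_cm,
                 d_patient = d_patient, d_verif_comp = d_verif_comp,
                 d_verif_nocomp = d_verif_nocomp),
            class = "scatter_factors")
}

#' @export
print.scatter_factors <- function(x, ...) {
  cat(sprintf("<scatter_factors> PSF %.4f  CSF %.4f  CPSF %.4f  (WED %.2f cm)\n",
              x$psf, x$csf, x$cpsf, x$wed_cm))
  invisible(x)
}

#' Build the water verification geometry at matched WED
#'
#' Returns a homogeneous water grid (same spacing and origin as the patient
#' grid; extended in z if needed) and the point on the central axis whose
#' geometric depth in water equals the patient water-equivalent depth to the
#' given point. The beam geometry (source position, air gap, compensator
#' placement) is preserved; only the patient material changes.
#'
#' @param grid Patient `hu_grid`.
#' @param beam `beam_spec` with geometry set; the point must lie on its axis.
#' @param point_mm Calculation point on the central axis, world mm.
#' @param cal Calibration.
#' @return List: `grid` (water `hu_grid`), `point_mm` (matched point), and
#'   `wed_cm`.
#' @export
build_verification_geometry <- function(grid, beam, point_mm, cal = default_calibration()) {
  if (is.null(beam$axis_mm)) stop_invalid("beam geometry not set")
  if (max(abs(point_mm[1:2] - beam$axis_mm)) > 1e-6) {
    stop_invalid("point must lie on the central beam axis")
  }
  tabs <- build_material_tables(cal)
  src_z <- beam$iso_z_mm - beam$sad_cm * 10
  src <- c(beam$axis_mm, src_z)
  tr <- trace_ray(grid, src, c(0, 0, 1), t_max = point_mm[3] - src_z)
  wed_cm <- cumulative_path(grid, tr, tabs, point_mm[3] - src_z)[["wed_cm"]]
  dims <- dim(grid$values)
  need_mm <- wed_cm * 10 + 2 * grid$spacing[3]
  nz <- dim(grid$values)[3]
  if (need_mm > nz * grid$spacing[3]) {
    nz <- ceiling(need_mm / grid$spacing[3])
    message(sprintf("verification water grid extended to %d z-voxels to cover WED %.2f cm",
                    nz, wed_cm))
  }
  water <- if (identical(nz, dims[3]) && all(grid$values == 0L)) {
    grid  # already a water box: reuse so the identity case cancels exactly
  } else {
    hu_grid(array(0L, c(dims[1], dims[2], nz)), grid$spacing, grid$origin)
  }
  point2 <- c(beam$axis_mm, grid$origin[3] + wed_cm * 10)
  list(grid = water, point_mm = point2, wed_cm = wed_cm)
}

#' Compute PSF, CSF and CPSF for a field
#'
#' Runs the full verification workflow: dose at the calculation point in the
#' patient with the compensator; the water verification geometry at the same
#' water-equivalent depth with the compensator; and the same geometry without
#' it. The three dose calls share beam, beamlet lattice and SOBP weights.
#' The calculation point is the target centroid on the central axis.
#'
#' @param grid Patient `hu_grid`.
#' @param beam A `beam_spec`.
#' @param comp A `compensator_map` (may be all-zero), or `NULL`.
#' @param target A `target_spec`.
#' @param cal Calibration.
#' @return A `scatter_factors` object; also carries `gradient_pct_per_mm`,
#'   the local axial SOBP gradient at the point (large values flag a
#'   gradient-region calculation point).
#' @export
compute_scatter_factors <- function(grid, beam, comp = NULL, target,
                                    cal = default_calibration()) {
  beam <- set_beam_geometry(beam, grid, target)
  point <- c(beam$axis_mm, beam$iso_z_mm)
  tabs <- build_material_tables(cal)
  sobp <- sobp_weights(beam$range_cm, beam$modulation_cm)
  d_p <- dose_at_point(grid, beam, comp, point, cal, sobp = sobp, tabs = tabs)
  ver <- build_verification_geometry(grid, beam, point, cal)
  d_vc <- dose_at_point(ver$grid, beam, comp, ver$point_mm, cal, sobp = sobp, tabs = tabs)
  d_vn <- dose_at_point(ver$grid, beam, NULL, ver$point_mm, cal, sobp = sobp, tabs = tabs)
  sf <- scatter_factors(d_p$value, d_vc$value, d_vn$value, wed_cm = ver$wed_cm)
  # local axial depth-dose gradient at the point's water-equivalent depth
  t_ax <- if (is.null(comp)) 0 else comp_thickness_at(comp, 0, 0)
  zeta <- ver$wed_cm + t_ax * (if (is.null(comp)) PMMA_RSP else comp$material_rsp)
  eps <- 0.05
  g <- (sobp_dose(zeta + eps, sobp) - sobp_dose(max(zeta - eps, 0), sobp)) /
    (2 * eps) / sobp_dose(zeta, sobp)
  sf$gradient_pct_per_mm <- 100 * g / 10
  sf
}
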