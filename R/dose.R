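# Pencil-beam dose engine. Dose at a point is a superposition over a regular
# beamlet lattice fanning from a point source: each beamlet carries the SOBP
# depth dose at its own water-equivalent depth (compensator plus patient),
# spread laterally by a Gaussian whose width combines the in-air source sigma
# with Highland widths for the compensator and patient material actually
# traversed. Dose units are arbitrary; only ratios at matched water-equivalent
# depth are meaningful, which is all the scatter factors use.

# Beamlet lattice offsets (mm) at the isocenter plane: symmetric square
# lattice clipped to the aperture circle.
beamlet_offsets <- function(field_radius_cm, spacing_cm) {
  s <- spacing_cm * 10
  rf <- field_radius_cm * 10
  k <- floor(rf / s)
  off <- s * (-k:k)
  g <- expand.grid(u = off, v = off)
  g[g$u^2 + g$v^2 <= rf^2 + 1e-9, , drop = FALSE]
}

#' Dose at a point from a passively scattered field
#'
#' @param grid Patient `hu_grid`.
#' @param beam A `beam_spec` with `axis_mm` and `iso_z_mm` set (see
#'   [compute_scatter_factors()], which pins them to the target centroid).
#' @param comp A `compensator_map` or `NULL` for an open field.
#' @param point_mm Calculation point in world mm; must lie inside the grid.
#' @param cal An `rsp_calibration`.
#' @param sobp Optional precomputed [sobp_weights()] result (reused across the
#'   three calls of a scatter-factor evaluation so the weights are identical).
#' @param tabs Optional prebuilt material lookup tables.
#' @return Object of class `dose_sample`: `value` (engine units), `position`,
#'   and `wed_cm` (central-axis water-equivalent depth to the point's plane).
#' @export
dose_at_point <- function(grid, beam, comp = NULL, point_mm, cal = default_calibration(),
                          sobp = NULL, tabs = NULL) {
  if (!inherits(beam, "beam_spec")) stop_invalid("beam must be a beam_spec")
  if (is.null(beam$axis_mm) || is.null(beam$iso_z_mm)) {
    stop_invalid("beam geometry not set: axis_mm and iso_z_mm are required")
  }
  up <- grid_upper(grid)
  if (any(point_mm < grid$origin) || any(point_mm > up)) {
    stop_invalid("calculation point lies outside the grid")
  }
  tabs <- tabs %||% build_material_tables(cal)
  sobp <- sobp %||% sobp_weights(beam$range_cm, beam$modulation_cm)

  ax <- beam$axis_mm
  iso_z <- beam$iso_z_mm
  sad_mm <- beam$sad_cm * 10
  src <- c(ax[1], ax[2], iso_z - sad_mm)
  z_p <- point_mm[3]
  if (z_p <= src[3]) stop_invalid("point is upstream of the source")

  offs <- beamlet_offsets(beam$field_radius_cm, beam$beamlet_spacing_cm)
  nb <- nrow(offs)
  # central-axis WED to the point's depth plane (reported with the sample)
  ax_dir <- c(0, 0, 1)
  ax_tr <- trace_ray(grid, src, ax_dir, t_max = z_p - src[3])
  wed_axis <- cumulative_path(grid, ax_tr, tabs, z_p - src[3])[["wed_cm"]]
  if (nb == 0L) {
    return(structure(list(value = 0, position = point_mm, wed_cm = wed_axis),
                     class = "dose_sample"))
  }

  bx <- ax[1] + offs$u
  by <- ax[2] + offs$v
  dz <- sad_mm  # iso plane is sad_mm downstream of the source
  wed <- numeric(nb); xx0 <- numeric(nb); dpat_mm <- numeric(nb)
  px <- numeric(nb); py <- numeric(nb)
  for (b in seq_len(nb)) {
    dir <- c(bx[b] - src[1], by[b] - src[2], dz)
    dir <- dir / sqrt(sum(dir^2))
    t_plane <- (z_p - src[3]) / dir[3]
    tr <- trace_ray(grid, src, dir, t_max = t_plane)
    cp <- cumulative_path(grid, tr, tabs, t_plane)
    wed[b] <- cp[["wed_cm"]]
    xx0[b] <- cp[["x_over_x0"]]
    dpat_mm[b] <- cp[["geom_mm"]]
    px[b] <- src[1] + t_plane * dir[1]
    py[b] <- src[2] + t_plane * dir[2]
  }

  tcomp <- if (is.null(comp)) numeric(nb) else {
    comp_thickness_at(comp, offs$u / 10, offs$v / 10)
  }
  rsp_comp <- if (is.null(comp)) PMMA_RSP else comp$material_rsp
  x0_comp <- if (is.null(comp)) PMMA_X0_CM else comp$x0_cm
  zeta <- tcomp * rsp_comp + wed
  dd <- sobp_dose(zeta, sobp)

  energy <- bragg_kleeman_energy(beam$range_cm)
  sig_src <- beam$source_sigma_cm * 10
  drift_comp <- beam$air_gap_cm * 10 + dpat_mm
  sig_comp <- ifelse(tcomp > 0,
                     highland_theta0(pmax(tcomp, 1e-6) / x0_comp, energy) * drift_comp,
                     0)
  sig_pat <- ifelse(xx0 > 0,
                    highland_theta0(pmax(xx0, 1e-12), energy) * dpat_mm / sqrt(3),
                    0)
  sig2 <- sig_src^2 + sig_comp^2 + sig_pat^2
  r2 <- (px - point_mm[1])^2 + (py - point_mm[2])^2
  isq <- (sad_mm / (z_p - src[3]))^2
  val <- sum(dd * exp(-r2 / (2 * sig2)) / (2 * pi * sig2)) *
    (beam$beamlet_spacing_cm * 10)^2 * isq
  structure(list(value = val, position = point_mm, wed_cm = wed_axis),
            class = "dose_sample")
}

#' Dose grid on a (possibly subsampled) voxel lattice
#'
#' Beamlet-major accumulation: each beamlet is traced once, then deposits its
#' Gaussian-spread SOBP dose on every sampled z-plane. Intended for isodose
#' contouring and visualisation, not for the scatter-factor ratios (those use
#' [dose_at_point()] at full fidelity).
#'
#' @param grid Patient `hu_grid`.
#' @param beam A `beam_spec` with geometry set.
#' @param comp Optional `compensator_map`.
#' @param cal Calibration.
#' @param stride Voxel subsampling stride (same in x, y, z).
#' @return List: `dose` (3-D array on the subsampled lattice), `spacing`,
#'   `origin` of that lattice.
#' @export
compute_dose_grid <- function(grid, beam, comp = NULL, cal = default_calibration(),
                              stride = 2L) {
  tabs <- build_material_tables(cal)
  sobp <- sobp_weights(beam$range_cm, beam$modulation_cm)
  dims <- dim(grid$values)
  sp <- grid$spacing
  ix <- seq(1L, dims[1], by = stride)
  iy <- seq(1L, dims[2], by = stride)
  iz <- seq(1L, dims[3], by = stride)
  xs <- grid$origin[1] + (ix - 0.5) * sp[1]
  ys <- grid$origin[2] + (iy - 0.5) * sp[2]
  zs <- grid$origin[3] + (iz - 0.5) * sp[3]
  ax <- beam$axis_mm; iso_z <- beam$iso_z_mm
  sad_mm <- beam$sad_cm * 10
  src <- c(ax[1], ax[2], iso_z - sad_mm)
  offs <- beamlet_offsets(beam$field_radius_cm, beam$beamlet_spacing_cm)
  nb <- nrow(offs)
  energy <- bragg_kleeman_energy(beam$range_cm)
  sig_src <- beam$source_sigma_cm * 10
  rsp_comp <- if (is.null(comp)) PMMA_RSP else comp$material_rsp
  x0_comp <- if (is.null(comp)) PMMA_X0_CM else comp$x0_cm
  tcomp <- if (is.null(comp)) numeric(nb) else comp_thickness_at(comp, offs$u / 10, offs$v / 10)
  dose <- array(0, c(length(ix), length(iy), length(iz)))
  dA <- (beam$beamlet_spacing_cm * 10)^2
  for (b in seq_len(nb)) {
    dir <- c(offs$u[b], offs$v[b], sad_mm)
    dir <- dir / sqrt(sum(dir^2))
    tr <- trace_ray(grid, src, dir)
    t_planes <- (zs - src[3]) / dir[3]
    cps <- vapply(t_planes, function(t) cumulative_path(grid, tr, tabs, t), numeric(3))
    zeta <- tcomp[b] * rsp_comp + cps["wed_cm", ]
    dd <- sobp_dose(zeta, sobp)
    dpat <- cps["geom_mm", ]
    sig_comp <- if (tcomp[b] > 0) {
      highland_theta0(tcomp[b] / x0_comp, energy) * (beam$air_gap_cm * 10 + dpat)
    } else rep(0, length(zs))
    sig_pat <- ifelse(cps["x_over_x0", ] > 0,
                      highland_theta0(pmax(cps["x_over_x0", ], 1e-12), energy) *
                        dpat / sqrt(3), 0)
    sig2 <- sig_src^2 + sig_comp^2 + sig_pat^2
    isq <- (sad_mm / (zs - src[3]))^2
    for (k in seq_along(zs)) {
      if (dd[k] <= 0) next
      pbx <- src[1] + t_planes[k] * dir[1]
      pby <- src[2] + t_planes[k] * dir[2]
      g <- outer((xs - pbx)^2, (ys - pby)^2, `+`)
      dose[, , k] <- dose[, , k] +
        dd[k] * isq[k] * dA * exp(-g / (2 * sig2[k])) / (2 * pi * sig2[k])
    }
  }
  list(dose = dose, spacing = sp * stride,
       origin = grid$origin + (stride - 1) * sp / 2)
}
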