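# Range compensator design and the thickness-irregularity (IQR) metric.
# A compensator map is a lateral thickness grid, in cm of compensator
# material (PMMA by default), indexed by position relative to the central
# beam axis at the isocenter plane.

#' Compensator thickness map
#'
#' @param thickness Matrix of thicknesses (cm), rows indexed by `x_cm`,
#'   columns by `y_cm`. All values >= 0.
#' @param x_cm,y_cm Lateral cell-center coordinates (cm) relative to the
#'   central axis.
#' @param material_rsp Relative stopping power of the compensator material
#'   (PMMA 1.16).
#' @param x0_cm Radiation length of the material in cm (PMMA 34.1).
#' @return Object of class `compensator_map`.
#' @export
compensator_map <- function(thickness, x_cm, y_cm,
                            material_rsp = PMMA_RSP, x0_cm = PMMA_X0_CM) {
  thickness <- as.matrix(thickness)
  if (any(thickness < 0)) stop_invalid("compensator thickness must be >= 0")
  if (nrow(thickness) != length(x_cm) || ncol(thickness) != length(y_cm)) {
    stop_invalid("thickness dimensions must match x_cm, y_cm")
  }
  structure(list(thickness = thickness, x_cm = as.numeric(x_cm),
                 y_cm = as.numeric(y_cm), material_rsp = material_rsp,
                 x0_cm = x0_cm),
            class = "compensator_map")
}

#' A zero-thickness compensator covering a circular aperture
#'
#' @param field_radius_cm Aperture radius, cm.
#' @param spacing_cm Lateral cell spacing, cm.
#' @return A `compensator_map` with all-zero thickness.
#' @export
zero_compensator <- function(field_radius_cm, spacing_cm = 0.25) {
  k <- ceiling(field_radius_cm / spacing_cm)
  x <- spacing_cm * (-k:k)
  compensator_map(matrix(0, length(x), length(x)), x, x)
}

# Nearest-cell thickness lookup at lateral positions (cm relative to axis);
# positions outside the map get 0.
comp_thickness_at <- function(comp, x_cm, y_cm) {
  dx <- if (length(comp$x_cm) > 1L) diff(comp$x_cm[1:2]) else 1
  dy <- if (length(comp$y_cm) > 1L) diff(comp$y_cm[1:2]) else 1
  i <- round((x_cm - comp$x_cm[1]) / dx) + 1L
  j <- round((y_cm - comp$y_cm[1]) / dy) + 1L
  ok <- i >= 1L & i <= length(comp$x_cm) & j >= 1L & j <= length(comp$y_cm)
  out <- numeric(length(x_cm))
  out[ok] <- comp$thickness[cbind(i[ok], j[ok])]
  out
}

#' Design a range compensator by source-ray tracing
#'
#' For each lateral position, the thickness is `(R - WED_distal) / rsp`,
#' where `WED_distal` is the water-equivalent depth along the diverging source
#' ray to the distal end of the target on that ray, floored at zero. Rays that
#' miss the target inherit the maximum thickness of their filled neighbours
#' (no smearing margins beyond that rule).
#'
#' @param grid Patient `hu_grid`.
#' @param beam `beam_spec` (geometry is pinned to the target centroid).
#' @param target A `target_spec`; must intersect the beam.
#' @param cal Calibration.
#' @param lateral_spacing_cm Cell spacing of the thickness map; defaults to
#'   the beamlet spacing.
#' @return A `compensator_map`.
#' @export
design_compensator <- function(grid, beam, target, cal = default_calibration(),
                               lateral_spacing_cm = beam$beamlet_spacing_cm) {
  tabs <- build_material_tables(cal)
  beam <- set_beam_geometry(beam, grid, target)
  ax <- beam$axis_mm
  sad_mm <- beam$sad_cm * 10
  src <- c(ax[1], ax[2], beam$iso_z_mm - sad_mm)
  s <- lateral_spacing_cm
  k <- ceiling(beam$field_radius_cm / s) + 1L
  x <- s * (-k:k)
  n <- length(x)
  th <- matrix(NA_real_, n, n)
  hit <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      dir <- c(x[i] * 10, x[j] * 10, sad_mm)
      dir <- dir / sqrt(sum(dir^2))
      tr <- trace_ray(grid, src, dir)
      if (length(tr$idx) == 0L) next
      in_target <- target$mask[tr$idx]
      if (!any(in_target)) next
      last <- max(which(in_target))
      t_distal <- tr$t0s[last] + tr$lens[last]
      wed_distal <- cumulative_path(grid, tr, tabs, t_distal)[["wed_cm"]]
      th[i, j] <- max(0, (beam$range_cm - wed_distal) / PMMA_RSP)
      hit[i, j] <- TRUE
    }
  }
  if (!any(hit)) stop_invalid("target does not intersect the beam")
  # fill missing rays with the maximum neighbouring thickness
  while (any(is.na(th))) {
    nas <- which(is.na(th), arr.ind = TRUE)
    filled_any <- FALSE
    newvals <- rep(NA_real_, nrow(nas))
    for (r in seq_len(nrow(nas))) {
      i <- nas[r, 1]; j <- nas[r, 2]
      nb <- c(if (i > 1) th[i - 1, j], if (i < n) th[i + 1, j],
              if (j > 1) th[i, j - 1], if (j < n) th[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) { newvals[r] <- max(nb); filled_any <- TRUE }
    }
    th[nas] <- newvals
    if (!filled_any) { th[is.na(th)] <- 0; break }
  }
  if (all(th <= 1e-12)) {
    warning("beam range does not exceed the distal target WED anywhere; zero compensator")
  }
  compensator_map(th, x, x)
}

#' Highland scattering radius of a field
#'
#' The lateral region around the central axis that can scatter into the
#' calibration point: three projected Highland sigmas (99.7% containment) of
#' the beam after the median compensator thickness, drifted over the air gap
#' plus the depth of the point. The median thickness is floored at 0.1 cm so
#' an open or thin compensator still yields a finite radius.
#'
#' @param beam A `beam_spec`.
#' @param comp A `compensator_map` with at least one cell inside the aperture.
#' @param depth_cm Depth of the calculation point in the phantom, cm.
#' @return Radius in cm.
#' @export
scatter_radius <- function(beam, comp, depth_cm) {
  if (depth_cm < 0) stop_invalid("depth_cm must be >= 0")
  g <- expand.grid(x = comp$x_cm, y = comp$y_cm)
  inside <- g$x^2 + g$y^2 <= beam$field_radius_cm^2
  if (!any(inside)) stop_invalid("compensator has no cells inside the aperture")
  med <- stats::median(comp$thickness[cbind(
    match(g$x[inside], comp$x_cm), match(g$y[inside], comp$y_cm))])
  med <- max(med, 0.1)
  energy <- bragg_kleeman_energy(beam$range_cm)
  theta0 <- highland_theta0(med / comp$x0_cm, energy)
  3 * theta0 * (beam$air_gap_cm + depth_cm)
}

#' Interquartile range of compensator thickness near the axis
#'
#' Q3 - Q1 of the thickness values at lateral cells within `radius_cm` of the
#' central axis, with quantiles by linear interpolation of order statistics
#' (type 7). The study's irregularity metric for compensator shape.
#'
#' @param comp A `compensator_map`.
#' @param radius_cm Inclusion radius around the axis, cm (typically from
#'   [scatter_radius()]).
#' @return Object of class `iqr_metric`: `iqr` (cm), `radius_used`, `n_samples`.
#' @export
compensator_iqr <- function(comp, radius_cm) {
  g <- expand.grid(ix = seq_along(comp$x_cm), iy = seq_along(comp$y_cm))
  r2 <- comp$x_cm[g$ix]^2 + comp$y_cm[g$iy]^2
  sel <- r2 <= radius_cm^2
  if (sum(sel) < 4L) {
    stop_insufficient("fewer than 4 thickness samples within radius %.2f cm", radius_cm)
  }
  vals <- comp$thickness[cbind(g$ix[sel], g$iy[sel])]
  q <- stats::quantile(vals, c(0.25, 0.75), type = 7, names = FALSE)
  structure(list(iqr = q[2] - q[1], radius_used = radius_cm,
                 n_samples = sum(sel)), class = "iqr_metric")
}

#' Generate a compensator of controllable ruggedness
#'
#' Thin near the axis with a quadratic peripheral build-up carrying seeded
#' azimuthal lobes, both scaled by `ruggedness`: the irregularity lives on
#' the periphery, as it does for clinical compensators whose edges follow the
#' most variable anatomy. Used to generate families over which the
#' CSF-versus-IQR trend can be studied.
#'
#' @param ruggedness Non-negative scale of the thickness irregularity (cm of
#'   peripheral build-up).
#' @param base_cm Central base thickness, cm.
#' @param field_radius_cm,spacing_cm Map geometry.
#' @param seed RNG seed for the lobe phase.
#' @return A `compensator_map`.
#' @export
make_rugged_compensator <- function(ruggedness, base_cm = 1,
                                    field_radius_cm = 5, spacing_cm = 0.25,
                                    seed = 1L) {
  if (ruggedness < 0) stop_invalid("ruggedness must be >= 0")
  k <- ceiling(field_radius_cm / spacing_cm)
  x <- spacing_cm * (-k:k)
  xx <- outer(x, rep(1, length(x)))
  yy <- t(xx)
  r <- sqrt(xx^2 + yy^2) / field_radius_cm
  phi <- atan2(yy, xx)
  ph <- with_seed(seed, stats::runif(1, 0, 2 * pi))
  th <- base_cm + ruggedness * r^2 * (1 + 0.4 * cos(3 * phi + ph))
  compensator_map(pmax(th, 0), x, x)
}

#' Write a compensator thickness map to CSV
#'
#' Long format with header `x_cm,y_cm,thickness_cm`.
#'
#' @param comp A `compensator_map`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compensator_csv <- function(comp, path) {
  g <- expand.grid(x_cm = comp$x_cm, y_cm = comp$y_cm)
  g$thickness_cm <- as.vector(comp$thickness)
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a compensator thickness map from CSV
#'
#' @param path CSV with columns `x_cm,y_cm,thickness_cm` on a full lateral grid.
#' @param material_rsp,x0_cm Material constants.
#' @return A `compensator_map`.
#' @export
read_compensator_csv <- function(path, material_rsp = PMMA_RSP, x0_cm = PMMA_X0_CM) {
  df <- utils::read.csv(path)
  if (!all(c("x_cm", "y_cm", "thickness_cm") %in% names(df))) {
    stop_invalid("compensator CSV needs columns x_cm,y_cm,thickness_cm")
  }
  xs <- sort(unique(df$x_cm)); ys <- sort(unique(df$y_cm))
  th <- matrix(NA_real_, length(xs), length(ys))
  th[cbind(match(df$x_cm, xs), match(df$y_cm, ys))] <- df$thickness_cm
  if (anyNA(th)) stop_invalid("compensator CSV does not cover a full grid")
  compensator_map(th, xs, ys, material_rsp = material_rsp, x0_cm = x0_cm)
}

#' Export a compensator top surface as ASCII STL
#'
#' Triangulates the thickness map's top surface over a flat base; a minimal
#' mirror of the clinical workflow in which compensators are exchanged as STL.
#'
#' @param comp A `compensator_map`.
#' @param path Output `.stl` path.
#' @return `path`, invisibly.
#' @export
write_compensator_stl <- function(comp, path) {
  xs <- comp$x_cm; ys <- comp$y_cm; th <- comp$thickness
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid compensator", con)
  facet <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2)); if (nn > 0) nrm <- nrm / nn
    writeLines(c(sprintf("  facet normal %g %g %g", nrm[1], nrm[2], nrm[3]),
                 "    outer loop",
                 sprintf("      vertex %g %g %g", p1[1], p1[2], p1[3]),
                 sprintf("      vertex %g %g %g", p2[1], p2[2], p2[3]),
                 sprintf("      vertex %g %g %g", p3[1], p3[2], p3[3]),
                 "    endloop", "  endfacet"), con)
  }
  for (i in seq_len(length(xs) - 1L)) {
    for (j in seq_len(length(ys) - 1L)) {
      p00 <- c(xs[i], ys[j], th[i, j])
      p10 <- c(xs[i + 1], ys[j], th[i + 1, j])
      p01 <- c(xs[i], ys[j + 1], th[i, j + 1])
      p11 <- c(xs[i + 1], ys[j + 1], th[i + 1, j + 1])
      facet(p00, p10, p11)
      facet(p00, p11, p01)
    }
  }
  writeLines("endsolid compensator", con)
  invisible(path)
}
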