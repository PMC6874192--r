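# Beam model: Bragg-Kleeman range/energy relation, an analytic pristine Bragg
# curve, spread-out Bragg peak (SOBP) construction by nonnegative least
# squares, and the Highland multiple-Coulomb-scattering angle.

PROTON_MASS_MEV <- 938.272
X0_WATER_CM <- 36.08
PMMA_RSP <- 1.16
PMMA_X0_CM <- 34.1

#' Bragg-Kleeman range-energy relation
#'
#' R = alpha * E^p with alpha = 0.0022 cm MeV^-p and p = 1.77, the usual
#' power-law fit for protons in water.
#'
#' @param energy_mev Proton kinetic energy in MeV, 3 to 250.
#' @return Range in cm of water (distal 90% range).
#' @export
bragg_kleeman_range <- function(energy_mev) {
  if (any(!is.finite(energy_mev)) || any(energy_mev < 3) || any(energy_mev > 250)) {
    stop_invalid("energy must be in [3, 250] MeV")
  }
  0.0022 * energy_mev^1.77
}

#' Inverse Bragg-Kleeman: energy from range
#'
#' @param range_cm Range in cm water.
#' @return Proton kinetic energy in MeV.
#' @export
bragg_kleeman_energy <- function(range_cm) {
  if (any(!is.finite(range_cm)) || any(range_cm <= 0)) {
    stop_invalid("range must be positive")
  }
  (range_cm / 0.0022)^(1 / 1.77)
}

# Straggling width (cm) used for the distal falloff window.
straggling_sigma <- function(range_R) 0.012 * range_R^0.935

# Width (cm) of the analytic Bragg-peak bump; wider than pure range
# straggling to stand in for the energy spread of a clinical beam.
peak_width <- function(range_R) pmax(4 * straggling_sigma(range_R), 0.25)

pristine_raw <- function(z, range_R) {
  s <- straggling_sigma(range_R)
  w <- peak_width(range_R)
  zp <- range_R - 0.25 * w
  plateau <- 0.33 + 0.12 * (z / range_R)^2
  bump <- exp(-(z - zp)^2 / (2 * w^2))
  cutoff <- range_R + 3 * s
  win <- ifelse(z <= range_R, 1,
                ifelse(z >= cutoff, 0, cos(pi / 2 * (z - range_R) / (3 * s))^2))
  (plateau + bump) * win
}

.pristine_cache <- new.env(parent = emptyenv())

pristine_norm <- function(range_R) {
  key <- sprintf("%.9g", range_R)
  val <- .pristine_cache[[key]]
  if (is.null(val)) {
    zz <- seq(0, range_R + 3 * straggling_sigma(range_R), length.out = 4001L)
    val <- max(pristine_raw(zz, range_R))
    .pristine_cache[[key]] <- val
  }
  val
}

#' Analytic pristine Bragg depth-dose curve
#'
#' Smooth approximation: a slowly rising entrance plateau plus a Gaussian
#' peak just proximal of the range, tapered to zero within three straggling
#' widths beyond the range. Normalised to 1 at its maximum.
#'
#' @param z Depth in cm water (vectorised), >= 0.
#' @param range_R Beam range in cm water.
#' @return Relative dose in [0, 1].
#' @export
pristine_depth_dose <- function(z, range_R) {
  if (any(!is.finite(z)) || any(z < 0)) stop_invalid("depth z must be >= 0")
  if (!is.numeric(range_R) || length(range_R) != 1L || range_R <= 0) {
    stop_invalid("range_R must be a positive scalar")
  }
  pristine_raw(z, range_R) / pristine_norm(range_R)
}

#' Spread-out Bragg peak weights
#'
#' Pristine peaks at pulled-back ranges R, R - M/(n-1), ..., R - M are
#' combined by nonnegative least squares on a fixed depth grid so the summed
#' curve is flat across the modulation interval.
#'
#' @param range_R Distal range R in cm water.
#' @param modulation_M Modulation width M in cm water, 0 < M <= R.
#' @param n_peaks Number of pristine peaks; default is dense enough for
#'   plateau ripple of a few tenths of a percent.
#' @return Object of class `sobp` with `weights`, `ranges`, and the achieved
#'   plateau `flatness` (max/min dose ratio over [R - M, R - 0.1]).
#' @export
sobp_weights <- function(range_R, modulation_M,
                         n_peaks = max(8L, ceiling(modulation_M / 0.15) + 1L)) {
  if (modulation_M <= 0 || modulation_M > range_R) {
    stop_invalid("need 0 < modulation_M <= range_R")
  }
  if (n_peaks < 1L) stop_invalid("n_peaks must be >= 1")
  if (n_peaks == 1L) {
    sob <- structure(list(weights = 1, ranges = range_R, flatness = NA_real_,
                          range_R = range_R, modulation_M = modulation_M),
                     class = "sobp")
    return(sob)
  }
  ranges <- range_R - modulation_M * (seq_len(n_peaks) - 1L) / (n_peaks - 1L)
  ranges <- pmax(ranges, 0.3)
  zz <- seq(max(range_R - modulation_M - 0.05, 0.05), range_R - 0.05, by = 0.02)
  A <- vapply(ranges, function(rk) pristine_depth_dose(zz, rk), numeric(length(zz)))
  w <- pracma::lsqnonneg(A, rep(1, length(zz)))$x
  sob <- structure(list(weights = w, ranges = ranges, flatness = NA_real_,
                        range_R = range_R, modulation_M = modulation_M),
                   class = "sobp")
  plat <- seq(range_R - modulation_M, range_R - 0.1, by = 0.01)
  vals <- sobp_dose(plat, sob)
  sob$flatness <- max(vals) / min(vals)
  if (sob$flatness > 1.04) {
    warning(sprintf("SOBP plateau max/min ratio %.3f exceeds 1.04; increase n_peaks",
                    sob$flatness))
  }
  sob
}

#' Evaluate an SOBP depth-dose curve
#'
#' @param z Depth in cm water (vectorised).
#' @param sobp An object from [sobp_weights()].
#' @return Summed weighted pristine dose at each depth.
#' @export
sobp_dose <- function(z, sobp) {
  if (!inherits(sobp, "sobp")) stop_invalid("sobp must come from sobp_weights()")
  out <- numeric(length(z))
  for (k in seq_along(sobp$ranges)) {
    if (sobp$weights[k] > 0) {
      out <- out + sobp$weights[k] * pristine_depth_dose(z, sobp$ranges[k])
    }
  }
  out
}

#' Highland multiple-Coulomb-scattering angle
#'
#' theta0 = (14.1 MeV / pv) sqrt(x/X0) (1 + (1/9) log10(x/X0)), with
#' pv = E (E + 2m) / (E + m) for kinetic energy E and proton mass m.
#'
#' @param x_over_x0 Path length in radiation lengths, > 0.
#' @param energy_mev Proton kinetic energy in MeV.
#' @return Characteristic scattering angle in radians.
#' @export
highland_theta0 <- function(x_over_x0, energy_mev) {
  if (any(!is.finite(x_over_x0)) || any(x_over_x0 <= 0)) {
    stop_invalid("x_over_x0 must be positive")
  }
  pv <- energy_mev * (energy_mev + 2 * PROTON_MASS_MEV) /
    (energy_mev + PROTON_MASS_MEV)
  (14.1 / pv) * sqrt(x_over_x0) * (1 + log10(x_over_x0) / 9)
}

#' Beam / field specification
#'
#' @param range_cm Distal range R in cm water.
#' @param modulation_cm Modulation width M in cm water (0 < M <= R).
#' @param field_radius_cm Aperture (field) radius at isocenter, cm.
#' @param sad_cm Source-axis distance, cm; must exceed the range.
#' @param air_gap_cm Compensator-to-surface air gap, cm.
#' @param beamlet_spacing_cm Beamlet lattice spacing at isocenter, cm.
#' @param source_sigma_cm In-air lateral source sigma at isocenter, cm.
#' @param axis_mm Optional lateral (x, y) world position of the central axis.
#' @param iso_z_mm Optional world z of the isocenter plane.
#' @return Object of class `beam_spec`.
#' @export
beam_spec <- function(range_cm, modulation_cm, field_radius_cm = 5,
                      sad_cm = 200, air_gap_cm = 5, beamlet_spacing_cm = 0.2,
                      source_sigma_cm = 0.4, axis_mm = NULL, iso_z_mm = NULL) {
  if (modulation_cm <= 0 || modulation_cm > range_cm) {
    stop_invalid("need 0 < modulation_cm <= range_cm")
  }
  if (field_radius_cm <= 0) stop_invalid("field_radius_cm must be positive")
  if (sad_cm <= range_cm) stop_invalid("sad_cm must exceed range_cm")
  if (beamlet_spacing_cm <= 0 || source_sigma_cm <= 0 || air_gap_cm < 0) {
    stop_invalid("beamlet_spacing_cm and source_sigma_cm must be positive, air_gap_cm >= 0")
  }
  structure(list(range_cm = range_cm, modulation_cm = modulation_cm,
                 field_radius_cm = field_radius_cm, sad_cm = sad_cm,
                 air_gap_cm = air_gap_cm, beamlet_spacing_cm = beamlet_spacing_cm,
                 source_sigma_cm = source_sigma_cm,
                 axis_mm = axis_mm, iso_z_mm = iso_z_mm),
            class = "beam_spec")
}

#' Read a beam specification from JSON
#'
#' Expects the keys of [beam_spec()], e.g. `{"range_cm": 15.0,
#' "modulation_cm": 8.0, "field_radius_cm": 5.0, "sad_cm": 200,
#' "air_gap_cm": 5, "beamlet_spacing_cm": 0.2, "source_sigma_cm": 0.4}`.
#'
#' @param path JSON file path.
#' @return A `beam_spec`.
#' @export
read_beam_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(beam_spec, cfg[intersect(names(cfg), names(formals(beam_spec)))])
}

# Pin the beam geometry (central axis and isocenter plane) to a grid/target.
set_beam_geometry <- function(beam, grid, target) {
  beam$axis_mm <- target$centroid[1:2]
  beam$iso_z_mm <- target$centroid[3]
  beam
}
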