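# Shared small-scale fixtures: 18 cm phantoms at 3 mm keep the full pipeline
# in the seconds range while leaving every mechanism (divergence, Highland
# widths, SOBP coverage) active.

small_shape <- c(60, 60, 60)
small_spacing <- c(3, 3, 3)

small_water <- function() make_water_box(small_shape, small_spacing)

small_beam <- function(range_cm = 12, modulation_cm = 6, field_radius_cm = 3,
                       beamlet_spacing_cm = 0.3, ...) {
  beam_spec(range_cm, modulation_cm, field_radius_cm,
            beamlet_spacing_cm = beamlet_spacing_cm, ...)
}

# fine-step midpoint-rule WED oracle (independent of the voxel-boundary
# traversal under test)
wed_oracle <- function(grid, origin, direction, step_mm = 0.02, t_max_mm = 400) {
  tabs <- protoscatter:::build_material_tables(default_calibration())
  tt <- seq(step_mm / 2, t_max_mm, by = step_mm)
  px <- origin[1] + tt * direction[1]
  py <- origin[2] + tt * direction[2]
  pz <- origin[3] + tt * direction[3]
  d <- dim(grid$values); lo <- grid$origin; sp <- grid$spacing
  ix <- floor((px - lo[1]) / sp[1]) + 1
  iy <- floor((py - lo[2]) / sp[2]) + 1
  iz <- floor((pz - lo[3]) / sp[3]) + 1
  ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
  idx <- (iz[ok] - 1) * d[1] * d[2] + (iy[ok] - 1) * d[1] + ix[ok]
  sum(step_mm * tabs$rsp[grid$values[idx] + tabs$offset]) / 10
}
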