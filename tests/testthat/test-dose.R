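# Dose engine properties. All use the small water box, where every identity
# is exact by construction.

water_dose_setup <- function(field_radius_cm = 3, beamlet_spacing_cm = 0.3) {
  wb <- small_water()
  beam <- small_beam(field_radius_cm = field_radius_cm,
                     beamlet_spacing_cm = beamlet_spacing_cm)
  beam <- protoscatter:::set_beam_geometry(beam, wb$grid, wb$target)
  list(wb = wb, beam = beam, point = c(beam$axis_mm, beam$iso_z_mm))
}

test_that("beamlet lattice refinement changes the dose by less than 0.5%", {
  s1 <- water_dose_setup(beamlet_spacing_cm = 0.3)
  s2 <- water_dose_setup(beamlet_spacing_cm = 0.15)
  d1 <- dose_at_point(s1$wb$grid, s1$beam, NULL, s1$point)
  d2 <- dose_at_point(s2$wb$grid, s2$beam, NULL, s2$point)
  expect_lt(abs(d1$value - d2$value) / d2$value, 0.005)
})

test_that("dose is mirror symmetric about the central axis", {
  s <- water_dose_setup()
  off <- c(9, 0, 0)  # 9 mm off axis, inside the field
  dplus <- dose_at_point(s$wb$grid, s$beam, NULL, s$point + off)
  dminus <- dose_at_point(s$wb$grid, s$beam, NULL, s$point - off)
  expect_equal(dplus$value, dminus$value, tolerance = 1e-10)
})

test_that("lateral equilibrium: off-axis equals on-axis under a broad field", {
  s <- water_dose_setup(field_radius_cm = 6)
  d0 <- dose_at_point(s$wb$grid, s$beam, NULL, s$point)
  d1 <- dose_at_point(s$wb$grid, s$beam, NULL, s$point + c(6, 0, 0))
  expect_lt(abs(d1$value - d0$value) / d0$value, 0.002)
})

test_that("the engine is exactly linear in the SOBP weights", {
  s <- water_dose_setup()
  sobp <- sobp_weights(s$beam$range_cm, s$beam$modulation_cm)
  d1 <- dose_at_point(s$wb$grid, s$beam, NULL, s$point, sobp = sobp)
  sobp3 <- sobp
  sobp3$weights <- 3 * sobp$weights
  d3 <- dose_at_point(s$wb$grid, s$beam, NULL, s$point, sobp = sobp3)
  expect_identical(d3$value, 3 * d1$value)
})

test_that("a zero-thickness compensator changes no dose value", {
  s <- water_dose_setup()
  sobp <- sobp_weights(s$beam$range_cm, s$beam$modulation_cm)
  d_open <- dose_at_point(s$wb$grid, s$beam, NULL, s$point, sobp = sobp)
  d_zero <- dose_at_point(s$wb$grid, s$beam, zero_compensator(3), s$point,
                          sobp = sobp)
  expect_identical(d_open$value, d_zero$value)
})

test_that("points outside the grid or upstream of the source are rejected", {
  s <- water_dose_setup()
  expect_error(dose_at_point(s$wb$grid, s$beam, NULL, c(500, 90, 90)),
               class = "protoscatter_invalid_input")
  beam_nogeo <- small_beam()
  expect_error(dose_at_point(s$wb$grid, beam_nogeo, NULL, s$point),
               class = "protoscatter_invalid_input")
})

test_that("dose grid peaks on the axis inside the SOBP span", {
  wb <- make_water_box(c(30, 30, 30), 4)
  beam <- beam_spec(9, 6, field_radius_cm = 2.5, beamlet_spacing_cm = 0.5)
  beam <- protoscatter:::set_beam_geometry(beam, wb$grid, wb$target)
  dg <- compute_dose_grid(wb$grid, beam, stride = 2L)
  peak <- which(dg$dose == max(dg$dose), arr.ind = TRUE)[1, ]
  nd <- dim(dg$dose)
  # lateral peak position on the axis (grid center)
  expect_lte(abs(peak[1] - (nd[1] + 1) / 2), 1)
  expect_lte(abs(peak[2] - (nd[2] + 1) / 2), 1)
  # depth of max within the modulation span
  zpk <- dg$origin[3] + (peak[3] - 0.5) * dg$spacing[3]
  expect_gte(zpk / 10, beam$range_cm - beam$modulation_cm - 0.5)
  expect_lte(zpk / 10, beam$range_cm)
})
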