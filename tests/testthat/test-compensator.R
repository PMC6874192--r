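test_that("compensator for a flat distal face in water is uniform (R - d)/rsp", {
  wb <- small_water()
  # distal target face: central cube, 12 voxels of 3 mm => distal at 10.8 cm
  tz <- range(which(apply(wb$target$mask, 3, any)))
  d_cm <- tz[2] * 0.3
  beam <- small_beam(range_cm = d_cm + 2.32, modulation_cm = 6)
  comp <- design_compensator(wb$grid, beam, wb$target, lateral_spacing_cm = 0.3)
  # cells whose source ray passes through the target footprint
  g <- expand.grid(x = comp$x_cm, y = comp$y_cm)
  inside <- sqrt(g$x^2 + g$y^2) <= 1.5
  th <- comp$thickness[cbind(match(g$x, comp$x_cm), match(g$y, comp$y_cm))][inside]
  expect_equal(mean(th), 2.0, tolerance = 0.02)
  expect_lt(diff(range(th)), 0.05)
})

test_that("deeper distal edges get thinner compensator (monotone rule)", {
  # two-level distal surface: stack a deeper soft-tissue step behind half the target
  wb <- small_water()
  mask <- wb$target$mask
  idx <- which(mask, arr.ind = TRUE)
  half <- idx[, 1] <= 30
  zmax <- max(idx[, 3])
  # extend target 6 voxels deeper on the x <= 30 half
  for (k in 1:6) {
    ext <- idx[half & idx[, 3] == zmax, ]
    ext[, 3] <- zmax + k
    mask[ext] <- TRUE
  }
  target <- target_spec(mask, wb$grid$spacing, wb$grid$origin)
  beam <- small_beam(range_cm = 14, modulation_cm = 7)
  comp <- design_compensator(wb$grid, beam, target, lateral_spacing_cm = 0.3)
  t_deep <- protoscatter:::comp_thickness_at(comp, -0.9, 0)   # deep half
  t_shallow <- protoscatter:::comp_thickness_at(comp, 0.9, 0) # shallow half
  expect_lt(t_deep, t_shallow)
  expect_equal(t_shallow - t_deep, 6 * 0.3 / 1.16, tolerance = 0.05)
})

test_that("range at or below the distal WED gives a zero compensator", {
  wb <- small_water()
  tz <- range(which(apply(wb$target$mask, 3, any)))
  d_cm <- tz[2] * 0.3
  # range exactly at the distal WED: zero thickness over the target footprint
  # (diverging corner rays can exit through the target side and keep a rim)
  beam <- small_beam(range_cm = d_cm, modulation_cm = 6)
  comp <- suppressWarnings(design_compensator(wb$grid, beam, wb$target,
                                              lateral_spacing_cm = 0.3))
  central <- protoscatter:::comp_thickness_at(comp, c(0, 0.6, -0.6), c(0, 0, 0))
  expect_true(all(central <= 0.02))
  # range below the minimum distal WED (even for side-exiting corner rays):
  # all-zero map with a warning
  beam2 <- small_beam(range_cm = 6, modulation_cm = 5)
  expect_warning(comp2 <- design_compensator(wb$grid, beam2, wb$target,
                                             lateral_spacing_cm = 0.3),
                 "zero compensator")
  expect_true(all(comp2$thickness == 0))
})

test_that("designed compensator closes the range equation along target rays", {
  # for every ray hitting the target: t*rsp + WED_distal = R within one voxel
  ph <- make_lung_phantom(0.3, seed = 2, small_shape, small_spacing, 3)
  beam <- small_beam(range_cm = 12, modulation_cm = 7)
  beam <- protoscatter:::set_beam_geometry(beam, ph$grid, ph$target)
  comp <- design_compensator(ph$grid, beam, ph$target, lateral_spacing_cm = 0.3)
  tabs <- protoscatter:::build_material_tables(default_calibration())
  src <- c(beam$axis_mm, beam$iso_z_mm - beam$sad_cm * 10)
  g <- expand.grid(x = comp$x_cm, y = comp$y_cm)
  sel <- which(g$x^2 + g$y^2 <= 1.5^2)
  errs <- vapply(sel, function(i) {
    dir <- c(g$x[i] * 10, g$y[i] * 10, beam$sad_cm * 10)
    dir <- dir / sqrt(sum(dir^2))
    tr <- protoscatter:::trace_ray(ph$grid, src, dir)
    it <- which(ph$target$mask[tr$idx])
    if (!length(it)) return(0)
    t_d <- tr$t0s[max(it)] + tr$lens[max(it)]
    wed_d <- protoscatter:::cumulative_path(ph$grid, tr, tabs, t_d)[["wed_cm"]]
    t_comp <- protoscatter:::comp_thickness_at(comp, g$x[i], g$y[i])
    abs(t_comp * comp$material_rsp + wed_d - beam$range_cm)
  }, 0)
  expect_lt(max(errs), 0.3 * 1.2)  # one voxel's water-equivalent thickness
})

test_that("IQR follows the linear-interpolation order-statistic convention", {
  # 2x2 map holding {1,2,3,4}: Q3 - Q1 = 3.25 - 1.75 = 1.5 (brute-force
  # type-7 quantiles frozen by hand)
  comp <- compensator_map(matrix(c(1, 2, 3, 4), 2, 2), c(-0.1, 0.1), c(-0.1, 0.1))
  m <- compensator_iqr(comp, 1)
  expect_equal(m$iqr, 1.5)
  expect_equal(m$n_samples, 4L)
  # constant map: IQR 0
  c0 <- compensator_map(matrix(2, 9, 9), seq(-1, 1, by = 0.25), seq(-1, 1, by = 0.25))
  expect_equal(compensator_iqr(c0, 1)$iqr, 0)
  # fewer than 4 samples in radius
  expect_error(compensator_iqr(comp, 0.05),
               class = "protoscatter_insufficient_data")
})

test_that("IQR is translation invariant and scales linearly in thickness", {
  comp <- make_rugged_compensator(2, base_cm = 1, field_radius_cm = 3,
                                  spacing_cm = 0.25, seed = 4)
  i0 <- compensator_iqr(comp, 2)$iqr
  shifted <- compensator_map(comp$thickness + 1.7, comp$x_cm, comp$y_cm)
  expect_equal(compensator_iqr(shifted, 2)$iqr, i0, tolerance = 1e-12)
  scaled <- compensator_map(comp$thickness * 2.5, comp$x_cm, comp$y_cm)
  expect_equal(compensator_iqr(scaled, 2)$iqr, 2.5 * i0, tolerance = 1e-12)
})

test_that("scatter radius grows with air gap and respects the thickness floor", {
  beam <- small_beam(range_cm = 15, modulation_cm = 5, air_gap_cm = 5)
  comp0 <- zero_compensator(3)
  r0 <- scatter_radius(beam, comp0, 10)
  # zero median thickness uses the 0.1 cm floor
  energy <- bragg_kleeman_energy(15)
  expect_equal(r0, 3 * highland_theta0(0.1 / 34.1, energy) * (5 + 10),
               tolerance = 1e-12)
  beam2 <- small_beam(range_cm = 15, modulation_cm = 5, air_gap_cm = 10)
  expect_gt(scatter_radius(beam2, comp0, 10), r0)
  # linear in the drift distance
  expect_equal(scatter_radius(beam2, comp0, 10) / r0, 20 / 15, tolerance = 1e-12)
})

test_that("scatter radius for a 4 cm median PMMA compensator is regression-locked", {
  beam <- small_beam(range_cm = 15, modulation_cm = 5, air_gap_cm = 5)
  comp <- compensator_map(matrix(4, 25, 25), seq(-3, 3, by = 0.25),
                          seq(-3, 3, by = 0.25))
  # frozen once from the closed form 3 * theta0(4/34.1, E(15 cm)) * 15 cm
  expect_equal(scatter_radius(beam, comp, 10), 0.71302, tolerance = 1e-4)
})

test_that("compensator CSV and STL exports round-trip / are well-formed", {
  comp <- make_rugged_compensator(1.5, base_cm = 1, field_radius_cm = 2,
                                  spacing_cm = 0.5, seed = 9)
  f <- tempfile(fileext = ".csv")
  write_compensator_csv(comp, f)
  back <- read_compensator_csv(f)
  expect_equal(back$thickness, comp$thickness, tolerance = 1e-9)
  expect_equal(back$x_cm, comp$x_cm)
  fs <- tempfile(fileext = ".stl")
  write_compensator_stl(comp, fs)
  stl <- readLines(fs)
  expect_equal(stl[1], "solid compensator")
  expect_equal(stl[length(stl)], "endsolid compensator")
  expect_equal(sum(grepl("^  facet", stl)),
               2 * (length(comp$x_cm) - 1) * (length(comp$y_cm) - 1))
  unlink(c(f, fs))
})
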