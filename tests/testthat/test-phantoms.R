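test_that("water box is uniform water with a central target", {
  wb <- make_water_box(c(50, 50, 50), 2)
  expect_true(all(wb$grid$values == 0L))
  cb <- composition_breakdown(wb$grid, wb$target$mask)
  expect_equal(unclass(cb)[["soft_tissue"]], 1)
  # 10 cm geometric path through water is 10 cm water-equivalent
  r <- ray(c(50, 50, -5), c(0, 0, 1))
  expect_equal(wed_along_ray(wb$grid, r, stop_cm = Inf), 10, tolerance = 1e-9)
  expect_error(make_water_box(c(5, 50, 50)), class = "protoscatter_invalid_input")
})

test_that("slab phantom WED matches the hand-computed layer sum", {
  # 5 cm water + 5 cm of HU 286 (rsp 1.1602 under the default calibration)
  slab <- make_slab_phantom(list(c(50, 0), c(50, 286)), c(40, 40), 2)
  r <- ray(c(40, 40, -5), c(0, 0, 1))
  expect_equal(wed_along_ray(slab$grid, r), 5 + 5 * 1.16016, tolerance = 1e-3)
  # leading air layer: WED of the first 3 cm is 3 * rsp(-800)
  slab2 <- make_slab_phantom(list(c(30, -800), c(60, 0)), c(30, 30), 2)
  rsp800 <- material_properties(-800)$rsp
  expect_equal(wed_along_ray(slab2$grid, ray(c(30, 30, 0), c(0, 0, 1)),
                             stop_cm = 3), 3 * rsp800, tolerance = 1e-9)
  expect_error(make_slab_phantom(list()), class = "protoscatter_invalid_input")
})

test_that("lung phantom hits the requested BEV air fraction and is deterministic", {
  ph <- make_lung_phantom(0.32, seed = 7, small_shape, small_spacing, 4)
  cb <- composition_breakdown(ph$grid, ph$bev)
  expect_gte(unclass(cb)[["air"]], 0.30)
  expect_lte(unclass(cb)[["air"]], 0.34)
  ph2 <- make_lung_phantom(0.32, seed = 7, small_shape, small_spacing, 4)
  expect_identical(ph$grid$values, ph2$grid$values)
  # different seed, different layout
  ph3 <- make_lung_phantom(0.32, seed = 8, small_shape, small_spacing, 4)
  expect_false(identical(ph$grid$values, ph3$grid$values))
  # zero air fraction: no air anywhere
  ph0 <- make_lung_phantom(0, seed = 7, small_shape, small_spacing, 4)
  expect_equal(unclass(composition_breakdown(ph0$grid, ph0$bev))[["air"]], 0)
  expect_error(make_lung_phantom(0.7, 1), class = "protoscatter_invalid_input")
})

test_that("lung families are nested in the air fraction at fixed seed", {
  lo <- make_lung_phantom(0.2, seed = 3, small_shape, small_spacing, 4)
  hi <- make_lung_phantom(0.4, seed = 3, small_shape, small_spacing, 4)
  air_lo <- lo$grid$values == -800L
  air_hi <- hi$grid$values == -800L
  expect_true(all(air_hi[air_lo]))
})

test_that("pelvis phantom hits the dense-bone fraction and spares the target", {
  ph <- make_pelvis_phantom(0.041, seed = 3, small_shape, small_spacing, 4)
  cb <- composition_breakdown(ph$grid, ph$bev)
  expect_gte(unclass(cb)[["dense_bone"]], 0.031)
  expect_lte(unclass(cb)[["dense_bone"]], 0.051)
  # bone voxels never intersect the target mask
  bone <- ph$grid$values >= 126L
  expect_false(any(bone & ph$target$mask))
  # zero fraction: no dense bone
  ph0 <- make_pelvis_phantom(0, seed = 3, small_shape, small_spacing, 4)
  expect_equal(unclass(composition_breakdown(ph0$grid, ph0$bev))[["dense_bone"]], 0)
  expect_error(make_pelvis_phantom(0.2, 1), class = "protoscatter_invalid_input")
})

test_that("grids round-trip losslessly through the MetaImage writer/reader", {
  ph <- make_lung_phantom(0.25, seed = 5, c(30, 30, 30), c(4, 4, 4), 3)
  f <- tempfile(fileext = ".mha")
  write_mha(ph$grid, f)
  back <- read_mha(f, as = "grid")
  expect_identical(back$values, ph$grid$values)
  expect_equal(back$spacing, ph$grid$spacing)
  expect_equal(back$origin, ph$grid$origin)
  # mask round trip
  fm <- tempfile(fileext = ".mha")
  write_mha(ph$target$mask, fm, ph$grid$spacing, ph$grid$origin)
  mback <- read_mha(fm, as = "mask")
  expect_identical(unname(mback[seq_along(mback)]), as.vector(ph$target$mask))
  unlink(c(f, fm))
})

test_that("grid constructor validates geometry and HU range", {
  expect_error(hu_grid(array(0L, c(2, 2)), 2), class = "protoscatter_invalid_input")
  expect_error(hu_grid(array(0L, c(2, 2, 2)), c(0, 2, 2)),
               class = "protoscatter_invalid_input")
  expect_error(hu_grid(array(5000L, c(2, 2, 2)), 2),
               class = "protoscatter_invalid_input")
})
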