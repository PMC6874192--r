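test_that("Bragg-Kleeman range relation and its inverse are consistent", {
  expect_equal(bragg_kleeman_range(100), 0.0022 * 100^1.77, tolerance = 1e-12)
  expect_equal(bragg_kleeman_range(100), 7.63, tolerance = 1e-3)
  for (E in c(10, 70, 160, 250)) {
    expect_equal(bragg_kleeman_energy(bragg_kleeman_range(E)), E,
                 tolerance = 1e-6)
  }
  E <- seq(5, 240, by = 5)
  expect_true(all(diff(bragg_kleeman_range(E)) > 0))
  expect_error(bragg_kleeman_range(1), class = "protoscatter_invalid_input")
  expect_error(bragg_kleeman_range(300), class = "protoscatter_invalid_input")
})

test_that("pristine Bragg curve has plateau, near-range peak, finite distal tail", {
  for (R in c(5, 10, 15, 20)) {
    z <- seq(0, R * 1.15, by = 0.002)
    d <- pristine_depth_dose(z, R)
    expect_equal(max(d), 1, tolerance = 1e-3)
    expect_lt(pristine_depth_dose(0.1 * R, R), 1)
    zmax <- z[which.max(d)]
    expect_gte(zmax, 0.95 * R)
    expect_lte(zmax, R)
    expect_equal(pristine_depth_dose(R + 5, R), 0)
  }
  expect_error(pristine_depth_dose(-1, 10), class = "protoscatter_invalid_input")
})

test_that("SOBP weights are nonnegative and give a flat plateau", {
  s1 <- sobp_weights(10, 5, n_peaks = 1)
  expect_equal(s1$weights, 1)
  expect_equal(sobp_dose(7, s1), pristine_depth_dose(7, 10))
  s <- sobp_weights(15, 5, n_peaks = 15)
  expect_true(all(s$weights >= 0))
  plat <- seq(10, 14.9, by = 0.01)
  v <- sobp_dose(plat, s)
  expect_lte(max(v) / min(v), 1.04)
  # default (denser) peak set is flat within 2%
  sd <- sobp_weights(15, 5)
  vd <- sobp_dose(plat, sd)
  expect_lte(max(vd) / min(vd), 1.02)
  expect_error(sobp_weights(10, 12), class = "protoscatter_invalid_input")
})

test_that("Highland angle follows the closed form and its scalings", {
  # frozen from the closed form: pv = E(E+2m)/(E+m) = 294.27 MeV at 158.6 MeV
  expect_equal(highland_theta0(1, 158.6), 0.0479156, tolerance = 1e-5)
  x <- 10^seq(-3, 0.5, length.out = 200)
  th <- highland_theta0(x, 150)
  expect_true(all(diff(th) > 0))
  # doubling pv halves theta0: find E2 with pv(E2) = 2 pv(E1)
  pv <- function(E) E * (E + 2 * 938.272) / (E + 938.272)
  E1 <- 100
  E2 <- uniroot(function(E) pv(E) - 2 * pv(E1), c(100, 500), tol = 1e-10)$root
  expect_equal(highland_theta0(0.3, E2) * 2, highland_theta0(0.3, E1),
               tolerance = 1e-6)
  expect_error(highland_theta0(0, 100), class = "protoscatter_invalid_input")
})

test_that("WED traversal is exact on water and agrees with the fine-step oracle", {
  wb <- small_water()
  expect_equal(wed_along_ray(wb$grid, ray(c(90, 90, -10), c(0, 0, 1)),
                             stop_cm = 11), 10, tolerance = 1e-9)
  expect_equal(wed_along_ray(wb$grid, ray(c(1000, 90, -10), c(0, 0, 1))), 0)
  set.seed(42)
  errs <- replicate(100, {
    nl <- sample(2:4, 1)
    layers <- lapply(seq_len(nl), function(i) {
      c(sample(seq(20, 60, by = 2), 1), sample(c(-800, -300, 0, 300, 700), 1))
    })
    slab <- make_slab_phantom(layers, c(30, 30), 2)
    org <- c(runif(2, 20, 40), -5)
    dir <- c(runif(2, -0.25, 0.25), 1)
    dir <- dir / sqrt(sum(dir^2))
    a <- wed_along_ray(slab$grid, ray(org, dir))
    b <- wed_oracle(slab$grid, org, dir)
    abs(a - b) / max(b, 1e-9)
  })
  expect_lt(max(errs), 0.005)
})

test_that("beam specification is validated and JSON round-trips", {
  expect_error(beam_spec(10, 12), class = "protoscatter_invalid_input")
  expect_error(beam_spec(10, 5, sad_cm = 8), class = "protoscatter_invalid_input")
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(range_cm = 15, modulation_cm = 8, field_radius_cm = 5,
                            sad_cm = 200, air_gap_cm = 5, beamlet_spacing_cm = 0.2,
                            source_sigma_cm = 0.4), f, auto_unbox = TRUE)
  b <- read_beam_json(f)
  expect_s3_class(b, "beam_spec")
  expect_equal(b$range_cm, 15)
  unlink(f)
})
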