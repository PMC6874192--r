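# End-to-end scenario runner: phantom -> beam fit -> compensator -> scatter
# factors -> composition -> IQR, producing rows of a runs table suitable for
# the empirical models.

# Choose range and modulation so the SOBP plateau covers the target (plus the
# compensator's pull-back) with margin, and the calculation point sits
# mid-plateau: R = deepest distal target WED + margin, M wide enough that the
# point's no-compensator WED is still on the plateau.
plan_beam <- function(grid, beam, target, cal = default_calibration()) {
  tabs <- build_material_tables(cal)
  beam <- set_beam_geometry(beam, grid, target)
  src <- c(beam$axis_mm, beam$iso_z_mm - beam$sad_cm * 10)
  # distal/proximal WED over a coarse ray fan through the target
  offs <- beamlet_offsets(beam$field_radius_cm, max(beam$beamlet_spacing_cm, 0.5))
  distal <- c(); proximal <- c()
  for (b in seq_len(nrow(offs))) {
    dir <- c(offs$u[b], offs$v[b], beam$sad_cm * 10)
    dir <- dir / sqrt(sum(dir^2))
    tr <- trace_ray(grid, src, dir)
    if (length(tr$idx) == 0L) next
    it <- which(target$mask[tr$idx])
    if (!length(it)) next
    t_d <- tr$t0s[max(it)] + tr$lens[max(it)]
    t_p <- tr$t0s[min(it)]
    distal <- c(distal, cumulative_path(grid, tr, tabs, t_d)[["wed_cm"]])
    proximal <- c(proximal, cumulative_path(grid, tr, tabs, t_p)[["wed_cm"]])
  }
  if (!length(distal)) stop_degenerate("target not covered by the beam")
  range_cm <- max(distal) + 0.3
  # point WED (to the isocenter plane on the axis)
  tr0 <- trace_ray(grid, src, c(0, 0, 1), t_max = beam$sad_cm * 10)
  wed_pt <- cumulative_path(grid, tr0, tabs, beam$sad_cm * 10)[["wed_cm"]]
  modulation_cm <- min(range_cm - 1, range_cm - min(proximal, wed_pt) + 1.5)
  modulation_cm <- max(modulation_cm, 2)
  beam$range_cm <- range_cm
  beam$modulation_cm <- modulation_cm
  beam
}

#' Run one end-to-end scenario
#'
#' Generates (or accepts) a phantom, fits the beam range/modulation to the
#' target, designs the range compensator, computes the scatter factors, the
#' field composition over the beam's-eye-view region, and the compensator IQR
#' within the Highland scattering radius. Deterministic for a fixed config.
#'
#' @param config List with elements: `kind` (`"water"`, `"lung"`, `"pelvis"`,
#'   or `"grid"`), `air_fraction` / `dense_bone_fraction` as applicable,
#'   `seed`, optional `shape`, `spacing` (mm), `field_radius_cm`,
#'   `beamlet_spacing_cm`, `source_sigma_cm`, `sad_cm`, `air_gap_cm`,
#'   `compensator` (`"designed"`, `"zero"`, or a `compensator_map`), and for
#'   `kind = "grid"` the `grid` and `target` objects.
#' @param cal Calibration.
#' @return List: `factors` (`scatter_factors`), `composition`
#'   (`composition_breakdown`), `iqr` (`iqr_metric`), `beam`, `comp`, and
#'   `row` (one-row data frame for a runs table).
#' @export
run_scenario <- function(config, cal = default_calibration()) {
  kind <- config$kind %||% "water"
  seed <- config$seed %||% 1L
  shape <- rep_len(config$shape %||% c(80, 80, 80), 3L)
  spacing <- rep_len(config$spacing %||% c(3, 3, 3), 3L)
  # aperture conforming to the central target (1/5 of each dimension) plus a
  # 1.2 cm lateral margin, unless the config pins the field radius
  half_w_cm <- max(round(shape[1:2] * 0.2) * spacing[1:2]) / 2 / 10
  frad <- config$field_radius_cm %||% (half_w_cm + 1.2)
  ph <- switch(kind,
    water = make_water_box(shape, spacing),
    lung = make_lung_phantom(config$air_fraction %||% 0.2, seed, shape, spacing, frad),
    pelvis = make_pelvis_phantom(config$dense_bone_fraction %||% 0.03, seed,
                                 shape, spacing, frad),
    grid = list(grid = config$grid, target = config$target),
    stop_invalid("unknown phantom kind: %s", kind)
  )
  beam <- beam_spec(range_cm = 15, modulation_cm = 8, field_radius_cm = frad,
                    sad_cm = config$sad_cm %||% 200,
                    air_gap_cm = config$air_gap_cm %||% 5,
                    beamlet_spacing_cm = config$beamlet_spacing_cm %||% 0.3,
                    source_sigma_cm = config$source_sigma_cm %||% 0.4)
  beam <- plan_beam(ph$grid, beam, ph$target, cal)
  comp_opt <- config$compensator %||% "designed"
  comp <- if (inherits(comp_opt, "compensator_map")) {
    # an imposed compensator is part of the delivered field: extend range and
    # modulation so the SOBP plateau still covers the target through it
    shift <- config$range_shift_cm %||%
      (max(comp_opt$thickness) * comp_opt$material_rsp)
    beam$range_cm <- beam$range_cm + shift
    beam$modulation_cm <- min(beam$modulation_cm + shift, beam$range_cm - 1)
    comp_opt
  } else if (identical(comp_opt, "zero")) {
    zero_compensator(frad)
  } else {
    design_compensator(ph$grid, beam, ph$target, cal,
                       lateral_spacing_cm = config$comp_spacing_cm %||%
                         max(beam$beamlet_spacing_cm, 0.3))
  }
  sf <- compute_scatter_factors(ph$grid, beam, comp, ph$target, cal)
  bev <- ph$bev %||% bev_mask(ph$grid, frad)
  comp_bd <- composition_breakdown(ph$grid, bev)
  depth_cm <- (ph$target$centroid[3] - ph$grid$origin[3]) / 10
  rad <- scatter_radius(beam, comp, depth_cm)
  iqr <- compensator_iqr(comp, max(rad, 2 * max(diff(comp$x_cm[1:2]), 0.2)))
  row <- data.frame(kind = kind, seed = seed,
                    air_pct = air_pct(comp_bd), dense_bone_pct = dense_bone_pct(comp_bd),
                    iqr_cm = iqr$iqr, scatter_radius_cm = rad,
                    psf = sf$psf, csf = sf$csf, cpsf = sf$cpsf, wed_cm = sf$wed_cm)
  list(factors = sf, composition = comp_bd, iqr = iqr, beam = beam, comp = comp,
       grid = ph$grid, target = ph$target, row = row)
}

#' Sweep a phantom family and collect a runs table
#'
#' @param kind `"lung"` or `"pelvis"`.
#' @param fractions Air fractions (lung) or dense-bone fractions (pelvis).
#' @param seed Seed shared across the family (the phantom family is nested in
#'   the fraction at fixed seed).
#' @param ... Further config entries passed to [run_scenario()].
#' @return Data frame with one row per fraction.
#' @export
sweep_scenarios <- function(kind = c("lung", "pelvis"), fractions, seed = 1L, ...) {
  kind <- match.arg(kind)
  extra <- list(...)
  rows <- lapply(fractions, function(f) {
    cfg <- c(list(kind = kind, seed = seed), extra)
    if (kind == "lung") cfg$air_fraction <- f else cfg$dense_bone_fraction <- f
    run_scenario(cfg)$row
  })
  do.call(rbind, rows)
}

#' Sweep compensator ruggedness and collect CSF versus IQR
#'
#' Runs a water-phantom field with generated compensators of increasing
#' ruggedness and records the CSF and the IQR within the Highland radius.
#'
#' @param ruggedness Vector of ruggedness scales (cm), one compensator each.
#' @param seed Seed for the ripple component.
#' @param ... Further config entries passed to [run_scenario()].
#' @return Data frame with `ruggedness`, `iqr_cm`, `csf`.
#' @export
sweep_compensators <- function(ruggedness = seq(0, 3.5, length.out = 8),
                               seed = 1L, ...) {
  extra <- list(...)
  shape <- rep_len(extra$shape %||% c(80, 80, 80), 3L)
  spacing <- rep_len(extra$spacing %||% c(3, 3, 3), 3L)
  frad <- extra$field_radius_cm %||%
    (max(round(shape[1:2] * 0.2) * spacing[1:2]) / 2 / 10 + 1.2)
  comps <- lapply(ruggedness, function(a) {
    make_rugged_compensator(a, base_cm = 1, field_radius_cm = frad,
                            spacing_cm = 0.25, seed = seed)
  })
  # one range extension for the whole family, so every member shares the
  # same SOBP and differences are purely compensator-driven
  shift <- max(vapply(comps, function(cm) max(cm$thickness) * cm$material_rsp, 0))
  rows <- lapply(seq_along(ruggedness), function(i) {
    cfg <- c(list(kind = "water", seed = seed, compensator = comps[[i]],
                  range_shift_cm = shift), extra)
    r <- run_scenario(cfg)$row
    r$ruggedness <- ruggedness[i]
    r
  })
  do.call(rbind, rows)
}
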