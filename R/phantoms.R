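# Synthetic voxel phantoms. Grids live in mm world coordinates; the beam axis
# is +z by convention. Voxel centers sit at origin + (index - 0.5) * spacing
# (half-voxel convention, 1-based indices).

#' Voxelized HU phantom
#'
#' @param values 3-D integer array of HU values in [-1024, 3000].
#' @param spacing Voxel spacing in mm, length 3, strictly positive.
#' @param origin World coordinate (mm) of the grid's lower corner, length 3.
#' @return An object of class `hu_grid`.
#' @export
hu_grid <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_invalid("values must be a 3-D array")
  }
  if (any(dim(values) < 1L)) stop_invalid("all grid dimensions must be >= 1")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(spacing <= 0)) stop_invalid("spacing must be strictly positive")
  rng <- range(values)
  if (rng[1] < -1024 || rng[2] > 3000) stop_invalid("HU values outside [-1024, 3000]")
  storage.mode(values) <- "integer"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "hu_grid")
}

#' @export
print.hu_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hu_grid> %d x %d x %d voxels, spacing %s mm, HU range [%d, %d]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

grid_upper <- function(grid) grid$origin + dim(grid$values) * grid$spacing

#' World coordinate (mm) of the grid center
#' @param grid An `hu_grid`.
#' @return Length-3 numeric vector.
#' @export
grid_center <- function(grid) grid$origin + dim(grid$values) * grid$spacing / 2

#' Target volume specification
#'
#' @param mask Logical 3-D array congruent with the owning grid.
#' @param spacing,origin Geometry copied from the owning grid.
#' @return An object of class `target_spec` with the mask and its centroid (mm).
#' @export
target_spec <- function(mask, spacing, origin) {
  if (!any(mask)) stop_invalid("target mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  centroid <- unname(origin + (colMeans(idx) - 0.5) * spacing)
  bb_lo <- origin + (apply(idx, 2, min) - 1) * spacing
  bb_hi <- origin + apply(idx, 2, max) * spacing
  stopifnot(all(centroid >= bb_lo & centroid <= bb_hi))
  structure(list(mask = mask, centroid = centroid), class = "target_spec")
}

central_target <- function(dims, spacing, origin, side_frac = 0.2) {
  side <- pmax(1L, round(dims * side_frac))
  lo <- pmax(1L, floor((dims - side) / 2) + 1L)
  hi <- pmin(dims, lo + side - 1L)
  mask <- array(FALSE, dims)
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  target_spec(mask, spacing, origin)
}

#' Homogeneous water phantom
#'
#' All voxels HU 0 (water/soft tissue); the target is a central cube one
#' fifth of each dimension.
#'
#' @param shape Voxel counts, length 3, each >= 10.
#' @param spacing Spacing in mm.
#' @return List with elements `grid` (`hu_grid`) and `target` (`target_spec`).
#' @export
make_water_box <- function(shape = c(150, 150, 150), spacing = c(2, 2, 2)) {
  shape <- rep_len(as.integer(shape), 3L)
  if (any(shape < 10L)) stop_invalid("water box needs shape >= (10,10,10)")
  spacing <- rep_len(as.numeric(spacing), 3L)
  grid <- hu_grid(array(0L, shape), spacing, c(0, 0, 0))
  list(grid = grid, target = central_target(shape, spacing, grid$origin))
}

#' Layered slab phantom
#'
#' Axis-aligned slabs stacked along +z (the beam axis); an oracle-friendly
#' geometry for water-equivalent-depth tests.
#'
#' @param layers List of `c(thickness_mm, hu)` pairs (or a 2-column matrix).
#' @param lateral_shape Voxel counts in x and y.
#' @param spacing Spacing in mm (z spacing is adapted per layer boundary by
#'   rounding layer thickness to whole voxels).
#' @return List with `grid` and `target` (central cube).
#' @export
make_slab_phantom <- function(layers, lateral_shape = c(40, 40), spacing = 2) {
  if (is.matrix(layers)) layers <- asplit(layers, 1)
  if (length(layers) == 0L) stop_invalid("at least one layer required")
  spacing <- as.numeric(spacing)[1]
  th <- vapply(layers, function(l) as.numeric(l[1]), 0)
  hu <- vapply(layers, function(l) as.numeric(l[2]), 0)
  if (any(th <= 0)) stop_invalid("layer thicknesses must be positive")
  nz_per <- pmax(1L, round(th / spacing))
  if (any(abs(nz_per * spacing - th) > 1e-6)) {
    warning("layer thicknesses rounded to whole voxels")
  }
  nz <- sum(nz_per)
  dims <- c(rep_len(as.integer(lateral_shape), 2L), nz)
  vals <- array(0L, dims)
  z0 <- 0L
  for (i in seq_along(nz_per)) {
    vals[, , (z0 + 1L):(z0 + nz_per[i])] <- as.integer(round(hu[i]))
    z0 <- z0 + nz_per[i]
  }
  grid <- hu_grid(vals, c(spacing, spacing, spacing), c(0, 0, 0))
  list(grid = grid, target = central_target(dims, grid$spacing, grid$origin))
}

#' Beam's-eye-view region mask
#'
#' Cylinder of the given radius about an axis parallel to +z, through the full
#' z extent of the grid. Used both by the phantom generators (to control
#' composition) and by the composition module (to measure it).
#'
#' @param grid An `hu_grid`.
#' @param field_radius_cm Cylinder radius in cm at the phantom.
#' @param axis_mm Lateral (x, y) world position of the axis; default grid center.
#' @return Logical array congruent with the grid.
#' @export
bev_mask <- function(grid, field_radius_cm, axis_mm = NULL) {
  dims <- dim(grid$values)
  ctr <- grid_center(grid)
  axis_mm <- axis_mm %||% ctr[1:2]
  x <- grid$origin[1] + (seq_len(dims[1]) - 0.5) * grid$spacing[1]
  y <- grid$origin[2] + (seq_len(dims[2]) - 0.5) * grid$spacing[2]
  r2 <- outer((x - axis_mm[1])^2, (y - axis_mm[2])^2, `+`)
  plane <- r2 <= (field_radius_cm * 10)^2
  array(rep(plane, dims[3]), dims)
}

# Deterministic voxel rasterisation of a sphere; returns linear indices of
# candidate voxels ordered by distance from the sphere center (innermost
# first) so that trimming removes the outermost shell first.
sphere_voxels <- function(dims, spacing, origin, center, radius) {
  lo <- pmax(1L, floor((center - radius - origin) / spacing) + 1L)
  hi <- pmin(dims, ceiling((center + radius - origin) / spacing))
  if (any(lo > hi)) return(integer(0))
  xs <- origin[1] + (lo[1]:hi[1] - 0.5) * spacing[1]
  ys <- origin[2] + (lo[2]:hi[2] - 0.5) * spacing[2]
  zs <- origin[3] + (lo[3]:hi[3] - 0.5) * spacing[3]
  g <- expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3])
  d2 <- (xs[g$ix - lo[1] + 1L] - center[1])^2 +
        (ys[g$iy - lo[2] + 1L] - center[2])^2 +
        (zs[g$iz - lo[3] + 1L] - center[3])^2
  keep <- d2 <= radius^2
  g <- g[keep, , drop = FALSE]
  d2 <- d2[keep]
  ord <- order(d2)
  lin <- (g$iz - 1L) * dims[1] * dims[2] + (g$iy - 1L) * dims[1] + g$ix
  lin[ord]
}

#' Lung-like phantom with controllable air content
#'
#' Soft-tissue body with air-filled bands (HU -800) occupying a requested
#' fraction of the beam's-eye-view cylinder. The heterogeneity pattern is
#' constant in x and y within the BEV (full-lateral bands at seeded z
#' positions), so every ray through the field sees the same air path and the
#' composition is controlled exactly. Band layers are drawn from a seeded
#' permutation and trimmed voxel-exactly: for a fixed seed, the air voxels at
#' a lower fraction are a subset of those at a higher fraction (nested
#' family). A soft-tissue shell and the target region stay air-free.
#'
#' @param air_fraction Requested air fraction of the BEV region, 0 to 0.6.
#' @param seed Integer RNG seed (generation is deterministic given the seed).
#' @param shape,spacing Grid geometry (voxel counts; spacing in mm).
#' @param field_radius_cm BEV cylinder radius used for composition control.
#' @return List with `grid`, `target`, and `bev` (the BEV mask used).
#' @export
make_lung_phantom <- function(air_fraction, seed,
                              shape = c(100, 100, 100), spacing = c(3, 3, 3),
                              field_radius_cm = 5) {
  if (!is.numeric(air_fraction) || length(air_fraction) != 1L ||
      air_fraction < 0 || air_fraction > 0.6) {
    stop_invalid("air_fraction must be in [0, 0.6]")
  }
  shape <- rep_len(as.integer(shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  vals <- array(0L, shape)
  grid <- hu_grid(vals, spacing, c(0, 0, 0))
  target <- central_target(shape, spacing, grid$origin)
  bev <- bev_mask(grid, field_radius_cm)
  n_target_air <- round(air_fraction * sum(bev))
  if (n_target_air > 0) {
    shell_vox <- max(1L, ceiling(10 / spacing[3]))  # 1 cm shell
    tz <- range(which(apply(target$mask, 3, any)))
    avail_z <- setdiff((shell_vox + 1L):(shape[3] - shell_vox),
                       (tz[1] - 1L):(tz[2] + 1L))
    per_layer <- sum(bev[, , 1])
    if (n_target_air > length(avail_z) * per_layer) {
      stop_invalid("requested air fraction does not fit outside the shell and target")
    }
    layer_order <- with_seed(seed, sample(avail_z))
    n_full <- n_target_air %/% per_layer
    rem <- n_target_air %% per_layer
    plane <- bev[, , 1]
    for (k in seq_len(n_full)) {
      z <- layer_order[k]
      vals[, , z][plane] <- -800L
    }
    if (rem > 0L) {
      # partial band: fill from the axis outward in a fixed order
      z <- layer_order[n_full + 1L]
      ctr <- grid_center(grid)
      x <- grid$origin[1] + (seq_len(shape[1]) - 0.5) * spacing[1]
      y <- grid$origin[2] + (seq_len(shape[2]) - 0.5) * spacing[2]
      r2 <- outer((x - ctr[1])^2, (y - ctr[2])^2, `+`)
      inplane <- which(plane)
      inplane <- inplane[order(r2[inplane])]
      sl <- vals[, , z]
      sl[inplane[seq_len(rem)]] <- -800L
      vals[, , z] <- sl
    }
    grid$values <- vals
  }
  list(grid = grid, target = target, bev = bev)
}

#' Pelvis-like phantom with controllable dense-bone content
#'
#' Soft-tissue body with a pair of lateral bone blocks meeting at the central
#' axis: a dense core (HU 700) wrapped in a bone shell (HU 300), upstream of
#' the central target. The core grows in a fixed deterministic voxel order
#' with the requested fraction, so families over increasing fractions are
#' nested and the bone never intersects the target.
#'
#' @param dense_bone_fraction Requested dense-bone fraction of the BEV region,
#'   0 to 0.10.
#' @param seed Integer seed (kept for interface symmetry; layout is
#'   deterministic).
#' @param shape,spacing Grid geometry.
#' @param field_radius_cm BEV cylinder radius used for composition control.
#' @return List with `grid`, `target`, and `bev`.
#' @export
make_pelvis_phantom <- function(dense_bone_fraction, seed = 1L,
                                shape = c(100, 100, 100), spacing = c(3, 3, 3),
                                field_radius_cm = 5) {
  if (!is.numeric(dense_bone_fraction) || length(dense_bone_fraction) != 1L ||
      dense_bone_fraction < 0 || dense_bone_fraction > 0.10) {
    stop_invalid("dense_bone_fraction must be in [0, 0.10]")
  }
  shape <- rep_len(as.integer(shape), 3L)
  spacing <- rep_len(as.numeric(spacing), 3L)
  vals <- array(0L, shape)
  grid <- hu_grid(vals, spacing, c(0, 0, 0))
  target <- central_target(shape, spacing, grid$origin)
  bev <- bev_mask(grid, field_radius_cm)
  n_core <- round(dense_bone_fraction * sum(bev))
  if (n_core > 0) {
    ext <- shape * spacing
    # bone band: upstream (low z) of the target, inside the BEV cylinder
    tidx <- which(target$mask, arr.ind = TRUE)
    z_target_lo <- min(tidx[, 3])
    z_band <- 6L:(z_target_lo - 4L)
    band <- array(FALSE, shape)
    band[, , z_band] <- TRUE
    cand <- which(band & bev)
    if (n_core + 1L > length(cand)) {
      stop_invalid("requested dense-bone fraction does not fit the bone band")
    }
    # fixed fill order: by z slab, then y, then |x - axis| outward from the
    # axis so the two half-blocks (x < axis, x >= axis) grow together
    ci <- arrayInd(cand, shape)
    axis_ix <- (shape[1] + 1) / 2
    ord <- order(ci[, 3], abs(ci[, 1] - axis_ix), ci[, 2], ci[, 1])
    core <- cand[ord][seq_len(n_core)]
    # one-voxel HU 300 shell wrapped around the dense core
    core_arr <- array(FALSE, shape)
    core_arr[core] <- TRUE
    shell_arr <- core_arr
    ii <- arrayInd(core, shape)
    for (ax in 1:3) {
      for (dd in c(-1L, 1L)) {
        jj <- ii
        jj[, ax] <- pmin(pmax(jj[, ax] + dd, 1L), shape[ax])
        shell_arr[jj] <- TRUE
      }
    }
    shell_arr <- shell_arr & !core_arr & band & bev & !target$mask
    vals[shell_arr] <- 300L
    vals[core] <- 700L
    grid$values <- vals
  }
  list(grid = grid, target = target, bev = bev)
}
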