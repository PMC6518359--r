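#' Voxel grid specification
#'
#' Defines the reconstruction grid.  The default mirrors a common
#' small-animal PET protocol: a 128 x 128 x 159 matrix with
#' 0.776 x 0.776 x 0.796 mm voxels.  Coordinates are taken relative to the
#' grid center, in mm.
#'
#' @param nx,ny,nz Voxel counts (>= 1).
#' @param dx,dy,dz Voxel sizes in mm (> 0).
#' @return A `grid_spec` object.
#' @export
#' @examples
#' g <- grid_spec()
#' voxel_volume_mm3(g)
grid_spec <- function(nx = 128, ny = 128, nz = 159,
                      dx = 0.776, dy = 0.776, dz = 0.796) {
  counts <- c(nx = nx, ny = ny, nz = nz)
  sizes <- c(dx = dx, dy = dy, dz = dz)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("voxel counts must be positive integers", class = "petiq_geometry_error")
  }
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    abort("voxel sizes must be positive and finite", class = "petiq_geometry_error")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
                 dx = dx, dy = dy, dz = dz),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @export
voxel_volume_mm3 <- function(grid) grid$dx * grid$dy * grid$dz

# centered voxel-center coordinates (mm)
grid_x <- function(grid) (seq_len(grid$nx) - (grid$nx + 1) / 2) * grid$dx
grid_y <- function(grid) (seq_len(grid$ny) - (grid$ny + 1) / 2) * grid$dy
grid_z <- function(grid) (seq_len(grid$nz) - (grid$nz + 1) / 2) * grid$dz

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels at %.3f x %.3f x %.3f mm\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz))
  invisible(x)
}

#' NU4 image-quality phantom specification
#'
#' Geometry and activity of the NEMA NU4-2008 image-quality phantom: a
#' 30 mm diameter cylinder whose bottom 20 mm is a solid section drilled
#' with five fillable rods (1-5 mm diameter), a middle uniform fillable
#' region, and a top section holding two cold chambers (8 mm inner /
#' 10 mm outer diameter, 15 mm long), one air- and one water-filled.
#' Total fillable activity defaults to 3.7 MBq.
#'
#' Linear attenuation coefficients are at 511 keV, in 1/mm.  The chamber
#' walls and the solid rod section attenuate like water and carry no
#' activity.
#'
#' @param body_diameter_mm Outer diameter of the phantom body.
#' @param rod_region_length_mm Axial length of the rod section.
#' @param uniform_region_length_mm Axial length of the uniform section.
#' @param rod_diameters_mm Strictly increasing rod diameters.
#' @param rod_pitch_radius_mm Radius of the circle on which rod centers sit.
#' @param cold_chamber_inner_mm,cold_chamber_outer_mm,cold_chamber_length_mm
#'   Cold-chamber geometry; inner < outer (1 mm walls by default).
#' @param cold_chamber_offset_mm Distance of each chamber center from the axis.
#' @param total_activity_MBq Total activity in the fillable volume.
#' @param uniform_activity_conc Activity concentration in Bq/mL; when `NULL`
#'   it is derived from `total_activity_MBq` and the analytic fillable volume.
#' @param mu_water_per_mm,mu_air_per_mm,mu_wall_per_mm Attenuation
#'   coefficients (1/mm) at 511 keV.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(body_diameter_mm = 30,
                         rod_region_length_mm = 20,
                         uniform_region_length_mm = 15,
                         rod_diameters_mm = c(1, 2, 3, 4, 5),
                         rod_pitch_radius_mm = 7,
                         cold_chamber_inner_mm = 8,
                         cold_chamber_outer_mm = 10,
                         cold_chamber_length_mm = 15,
                         cold_chamber_offset_mm = 7.5,
                         total_activity_MBq = 3.7,
                         uniform_activity_conc = NULL,
                         mu_water_per_mm = 0.0096,
                         mu_air_per_mm = 1e-5,
                         mu_wall_per_mm = 0.0096) {
  if (is.unsorted(rod_diameters_mm, strictly = TRUE)) {
    abort("rod diameters must be strictly increasing", class = "petiq_geometry_error")
  }
  if (cold_chamber_inner_mm >= cold_chamber_outer_mm) {
    abort("cold chamber inner diameter must be smaller than outer",
          class = "petiq_geometry_error")
  }
  if (total_activity_MBq <= 0) {
    abort("total activity must be positive", class = "petiq_validation_error")
  }
  if (any(c(mu_water_per_mm, mu_air_per_mm, mu_wall_per_mm) < 0)) {
    abort("attenuation coefficients must be non-negative",
          class = "petiq_validation_error")
  }
  structure(list(body_diameter_mm = body_diameter_mm,
                 rod_region_length_mm = rod_region_length_mm,
                 uniform_region_length_mm = uniform_region_length_mm,
                 rod_diameters_mm = rod_diameters_mm,
                 rod_pitch_radius_mm = rod_pitch_radius_mm,
                 cold_chamber_inner_mm = cold_chamber_inner_mm,
                 cold_chamber_outer_mm = cold_chamber_outer_mm,
                 cold_chamber_length_mm = cold_chamber_length_mm,
                 cold_chamber_offset_mm = cold_chamber_offset_mm,
                 total_activity_MBq = total_activity_MBq,
                 uniform_activity_conc = uniform_activity_conc,
                 mu_water_per_mm = mu_water_per_mm,
                 mu_air_per_mm = mu_air_per_mm,
                 mu_wall_per_mm = mu_wall_per_mm),
            class = "phantom_spec")
}

# analytic fillable (hot) volume in mm^3
phantom_hot_volume_mm3 <- function(spec) {
  rb <- spec$body_diameter_mm / 2
  v_uniform <- pi * rb^2 * spec$uniform_region_length_mm
  v_cold_section <- pi * rb^2 * spec$cold_chamber_length_mm -
    2 * pi * (spec$cold_chamber_outer_mm / 2)^2 * spec$cold_chamber_length_mm
  v_rods <- sum(pi * (spec$rod_diameters_mm / 2)^2) * spec$rod_region_length_mm
  v_uniform + v_cold_section + v_rods
}

phantom_length_mm <- function(spec) {
  spec$rod_region_length_mm + spec$uniform_region_length_mm +
    spec$cold_chamber_length_mm
}

# axial section boundaries, phantom centered at z = 0; rods at the bottom
phantom_sections <- function(spec) {
  half <- phantom_length_mm(spec) / 2
  z0 <- -half
  list(
    rod = c(z0, z0 + spec$rod_region_length_mm),
    uniform = c(z0 + spec$rod_region_length_mm,
                z0 + spec$rod_region_length_mm + spec$uniform_region_length_mm),
    cold = c(half - spec$cold_chamber_length_mm, half)
  )
}

# rod center positions on the pitch circle
phantom_rod_centers <- function(spec, dx = Inf) {
  k <- seq_along(spec$rod_diameters_mm)
  ang <- pi / 2 + (k - 1) * 2 * pi / length(k)
  tibble::tibble(
    rod_mm = spec$rod_diameters_mm,
    x_mm = spec$rod_pitch_radius_mm * cos(ang),
    y_mm = spec$rod_pitch_radius_mm * sin(ang),
    sub_resolution = spec$rod_diameters_mm / dx < 2
  )
}

#' Activity / attenuation volume container
#'
#' A light S3 wrapper around a 3D numeric array (x, y, slice) carrying its
#' grid, the axial position (mm) of each stored slice, and units.  Slices
#' need not be contiguous: a reduced axial stack covering only the
#' metric-relevant portions of the phantom is a supported representation.
#'
#' @param values 3D numeric array `[nx, ny, n_slices]`.
#' @param grid A `grid_spec` describing the in-plane geometry.
#' @param z_mm Axial coordinate of each stored slice (mm, grid-centered).
#' @param units Unit string recorded in metadata.
#' @return A `volume_3d` object.
#' @export
volume_3d <- function(values, grid, z_mm, units = "Bq/mL") {
  values <- as.array(values)
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(z_mm))
  structure(list(values = values, grid = grid, z_mm = z_mm, units = units),
            class = "volume_3d")
}

#' @export
print.volume_3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_3d> %d x %d x %d slices [%s], z in [%.1f, %.1f] mm\n",
              d[1], d[2], d[3], x$units, min(x$z_mm), max(x$z_mm)))
  invisible(x)
}

NU4_LABELS <- c("background", "uniform", "rod_1", "rod_2", "rod_3", "rod_4",
                "rod_5", "cold_air", "cold_water", "wall")

#' Build the digital NU4 image-quality phantom
#'
#' Voxelizes the phantom onto a grid by voxel-center membership and returns
#' the true activity map, the 511 keV attenuation map, and a region label
#' volume.  The fillable volume (uniform region, rods, and the hot surround
#' of the cold chambers) carries one activity concentration, chosen so that
#' the analytic fillable volume holds `total_activity_MBq`; cold chambers,
#' walls, and the solid rod section carry none.
#'
#' @param spec A [phantom_spec()].
#' @param grid A [grid_spec()].
#' @param slices Optional integer vector of slice indices (along z) to
#'   materialize; default all `grid$nz` slices.  [nu4_metric_slices()]
#'   returns the reduced stack covering the NU/RC/SOR VOIs.
#' @return An object of class `nu4_phantom`: a list with elements
#'   `activity`, `mu`, `labels` (all `volume_3d`; labels hold integer codes
#'   indexing the `levels` attribute), `rods` (tibble of rod centers with a
#'   sub-resolution flag), `sections`, `uniform_conc` (Bq/mL), `grid`,
#'   `z_mm`, and `spec`.
#' @export
#' @examples
#' ph <- build_nu4_phantom(phantom_spec(), grid_spec(nz = 65))
#' ph$uniform_conc
build_nu4_phantom <- function(spec = phantom_spec(), grid = grid_spec(),
                              slices = NULL) {
  rb <- spec$body_diameter_mm / 2
  if (spec$body_diameter_mm > min(grid$nx * grid$dx, grid$ny * grid$dy)) {
    abort("grid is too small to contain the phantom body",
          class = "petiq_geometry_error")
  }
  if (phantom_length_mm(spec) > grid$nz * grid$dz) {
    abort("grid is too short to contain the phantom axially",
          class = "petiq_geometry_error")
  }
  slices <- slices %||% seq_len(grid$nz)
  z <- grid_z(grid)[slices]
  x <- grid_x(grid)
  y <- grid_y(grid)
  X <- matrix(x, grid$nx, grid$ny)
  Y <- matrix(y, grid$nx, grid$ny, byrow = TRUE)
  R2 <- X^2 + Y^2
  in_body <- R2 <= rb^2

  sections <- phantom_sections(spec)
  rods <- phantom_rod_centers(spec, dx = max(grid$dx, grid$dy))

  conc <- spec$uniform_activity_conc %||%
    (spec$total_activity_MBq * 1e6 / (phantom_hot_volume_mm3(spec) / 1e3))

  nsl <- length(z)
  lab <- array(1L, dim = c(grid$nx, grid$ny, nsl))  # 1 = background

  code <- function(name) match(name, NU4_LABELS)
  r_in <- spec$cold_chamber_inner_mm / 2
  r_out <- spec$cold_chamber_outer_mm / 2
  off <- spec$cold_chamber_offset_mm
  air2 <- (X - off)^2 + Y^2
  wat2 <- (X + off)^2 + Y^2

  for (k in seq_len(nsl)) {
    zk <- z[k]
    plane <- matrix(1L, grid$nx, grid$ny)
    if (zk >= sections$rod[1] && zk < sections$rod[2]) {
      plane[in_body] <- code("wall")
      for (r in seq_len(nrow(rods))) {
        inrod <- (X - rods$x_mm[r])^2 + (Y - rods$y_mm[r])^2 <=
          (rods$rod_mm[r] / 2)^2
        plane[inrod & in_body] <- code(paste0("rod_", r))
      }
    } else if (zk >= sections$uniform[1] && zk < sections$uniform[2]) {
      plane[in_body] <- code("uniform")
    } else if (zk >= sections$cold[1] && zk <= sections$cold[2]) {
      plane[in_body] <- code("uniform")
      plane[air2 <= r_out^2 & in_body] <- code("wall")
      plane[wat2 <= r_out^2 & in_body] <- code("wall")
      plane[air2 <= r_in^2 & in_body] <- code("cold_air")
      plane[wat2 <= r_in^2 & in_body] <- code("cold_water")
    }
    lab[, , k] <- plane
  }

  hot <- lab %in% c(code("uniform"), vapply(seq_len(nrow(rods)),
                                            function(r) code(paste0("rod_", r)), 1L))
  act <- array(0, dim = dim(lab))
  act[hot] <- conc

  mu <- array(spec$mu_air_per_mm, dim = dim(lab))
  mu[lab != code("background") & lab != code("cold_air")] <- spec$mu_water_per_mm
  mu[lab == code("wall")] <- spec$mu_wall_per_mm
  # water-filled cold chamber attenuates like water
  mu[lab == code("cold_water")] <- spec$mu_water_per_mm

  labels <- volume_3d(lab, grid, z, units = "label")
  attr(labels, "levels") <- NU4_LABELS
  structure(list(
    activity = volume_3d(act, grid, z, units = "Bq/mL"),
    mu = volume_3d(mu, grid, z, units = "1/mm"),
    labels = labels,
    rods = rods,
    sections = sections,
    uniform_conc = conc,
    grid = grid,
    z_mm = z,
    slices = slices,
    spec = spec
  ), class = "nu4_phantom")
}

#' @export
print.nu4_phantom <- function(x, ...) {
  cat(sprintf(paste0("<nu4_phantom> %d slices, uniform concentration ",
                     "%.0f Bq/mL, total %.3f MBq (voxelized)\n"),
              length(x$z_mm), x$uniform_conc,
              sum(x$activity$values) * voxel_volume_mm3(x$grid) / 1e3 / 1e6))
  invisible(x)
}

#' Slice stack covering the NU4 metric VOIs
#'
#' Returns the slice indices whose centers fall inside the axial extent of
#' the three metric VOIs: the central 10 mm of the rod section (RC), the
#' 10 mm uniformity VOI centered in the uniform section (NU), and the
#' 7.5 mm spill-over VOIs centered in the cold chambers (SOR).  Simulating
#' only this reduced stack is the supported fast mode; every NU4 metric is
#' computable from it.
#'
#' @inheritParams build_nu4_phantom
#' @param nu_length_mm,sor_length_mm,rc_length_mm Axial VOI extents.
#' @return Sorted integer vector of slice indices.
#' @export
nu4_metric_slices <- function(spec = phantom_spec(), grid = grid_spec(),
                              nu_length_mm = 10, sor_length_mm = 7.5,
                              rc_length_mm = 10) {
  s <- phantom_sections(spec)
  z <- grid_z(grid)
  inside <- function(zc, len) which(abs(z - zc) <= len / 2)
  sort(unique(c(
    inside(mean(s$rod), rc_length_mm),
    inside(mean(s$uniform), nu_length_mm),
    inside(mean(s$cold), sor_length_mm)
  )))
}

#' Caliper tumor volume
#'
#' The standard caliper formula for subcutaneous xenografts:
#' width^2 x length x 0.4, in mm^3 for mm inputs.
#'
#' @param width_mm,length_mm Caliper width and length in mm (> 0).
#' @return Volume in mm^3.
#' @export
#' @examples
#' tumor_volume_caliper(5, 8)  # 80
tumor_volume_caliper <- function(width_mm, length_mm) {
  if (any(width_mm <= 0) || any(length_mm <= 0)) {
    abort("caliper dimensions must be positive", class = "petiq_validation_error")
  }
  width_mm^2 * length_mm * 0.4
}
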