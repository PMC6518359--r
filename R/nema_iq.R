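#' Cylindrical VOI mask
#'
#' Voxel mask of a z-axis-aligned cylinder, by voxel-center inclusion (no
#' partial-volume weighting).  Works on reduced slice stacks: the mask
#' covers whichever stored slices fall inside the axial extent.
#'
#' @param grid A [grid_spec()].
#' @param z_mm Axial coordinates of the stored slices.
#' @param center_xy In-plane center (mm), length 2.
#' @param diameter_mm,length_mm Cylinder diameter and length (mm, > 0).
#' @param z_center_mm Axial center (mm).
#' @return A logical array `[nx, ny, n_slices]`.
#' @export
cylinder_voi_mask <- function(grid, z_mm, center_xy = c(0, 0),
                              diameter_mm, length_mm, z_center_mm = 0) {
  if (diameter_mm <= 0 || length_mm <= 0) {
    abort("VOI diameter and length must be positive",
          class = "petiq_validation_error")
  }
  r <- diameter_mm / 2
  half_x <- grid$nx * grid$dx / 2
  half_y <- grid$ny * grid$dy / 2
  if (abs(center_xy[1]) + r > half_x || abs(center_xy[2]) + r > half_y) {
    abort("VOI extends beyond the image bounds", class = "petiq_geometry_error")
  }
  x <- grid_x(grid); y <- grid_y(grid)
  in_plane <- outer((x - center_xy[1])^2, (y - center_xy[2])^2, `+`) <= r^2
  in_z <- abs(z_mm - z_center_mm) <= length_mm / 2
  mask <- array(FALSE, c(grid$nx, grid$ny, length(z_mm)))
  for (k in which(in_z)) mask[, , k] <- in_plane
  if (!any(mask)) {
    abort("VOI selects no voxels on this slice stack",
          class = "petiq_geometry_error")
  }
  mask
}

# population SD (divide by N) -- fixed convention so %SD examples reproduce
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Non-uniformity (percent standard deviation) in a VOI
#'
#' NU is the percent SD of the voxel values in a uniform-region VOI:
#' `100 * SD / mean`, with the population SD convention (divide by N).
#' Mean, max and min are returned alongside.  A non-positive mean makes
#' the percent SD unreliable; the result is then flagged rather than
#' silently divided.
#'
#' @param img A [volume_3d()].
#' @param mask Logical voxel mask (e.g. from [cylinder_voi_mask()]).
#' @return A one-row tibble: `mean`, `sd`, `percent_sd`, `max`, `min`,
#'   `flagged`.
#' @export
non_uniformity <- function(img, mask) {
  v <- img$values[mask]
  if (length(v) == 0) abort("empty VOI", class = "petiq_validation_error")
  m <- mean(v)
  s <- sd_pop(v)
  flagged <- m <= 0
  tibble::tibble(mean = m, sd = s,
                 percent_sd = if (flagged) NA_real_ else 100 * s / m,
                 max = max(v), min = min(v), flagged = flagged)
}

#' Recovery coefficients of the hot rods
#'
#' RC = measured peak activity concentration / true activity concentration.
#' The peak is the maximum voxel value over a cylindrical ROI of twice the
#' physical rod diameter around each rod center, spanning the central
#' portion of the rod section axially (no axial pre-averaging: the peak is
#' taken over the ROI voxels themselves, so it carries the positive noise
#' bias of a maximum statistic, which is what makes high-iteration
#' reconstructions overshoot well above 1).  Rods below `min_rod_mm`
#' (1 mm by default excluded: not discernible at this resolution) are
#' skipped.  Values are not clamped.
#'
#' @param img A [volume_3d()] in the same units as `true_conc`.
#' @param rods Tibble with `rod_mm`, `x_mm`, `y_mm` (see
#'   [build_nu4_phantom()]'s `rods` element).
#' @param true_conc True activity concentration (> 0).
#' @param z_range Axial window (mm, length 2) of the ROI.
#' @param min_rod_mm Smallest rod diameter analyzed.
#' @return A tibble with `rod_mm` and `rc`.
#' @export
recovery_coefficients <- function(img, rods, true_conc, z_range,
                                  min_rod_mm = 2) {
  if (true_conc <= 0) {
    abort("true concentration must be positive", class = "petiq_validation_error")
  }
  sel <- img$z_mm >= z_range[1] & img$z_mm <= z_range[2]
  if (!any(sel)) abort("no slices in z_range", class = "petiq_geometry_error")
  sub <- img$values[, , sel, drop = FALSE]
  x <- grid_x(img$grid); y <- grid_y(img$grid)
  rods <- dplyr::filter(rods, .data$rod_mm >= min_rod_mm)
  rc <- purrr::pmap_dbl(rods[c("rod_mm", "x_mm", "y_mm")],
    function(rod_mm, x_mm, y_mm) {
      roi <- outer((x - x_mm)^2, (y - y_mm)^2, `+`) <= rod_mm^2  # (2d/2)^2
      if (!any(roi)) abort("rod ROI selects no voxels", class = "petiq_geometry_error")
      max(sub[array(roi, dim(sub))]) / true_conc
    })
  tibble::tibble(rod_mm = rods$rod_mm, rc = rc)
}

#' Spill-over ratio into the cold chambers
#'
#' SOR = mean value in a cold-chamber VOI divided by the mean value in the
#' uniform-region VOI.  Negative means (possible for analytic
#' reconstructions) pass through unclamped.
#'
#' @param img A [volume_3d()].
#' @param air_mask,water_mask,uniform_mask Logical voxel masks.
#' @return A one-row tibble: `sor_air`, `sor_water`, `uniform_mean`,
#'   `flagged` (uniform mean non-positive).
#' @export
spill_over_ratio <- function(img, air_mask, water_mask, uniform_mask) {
  um <- mean(img$values[uniform_mask])
  flagged <- um <= 0
  tibble::tibble(
    sor_air = if (flagged) NA_real_ else mean(img$values[air_mask]) / um,
    sor_water = if (flagged) NA_real_ else mean(img$values[water_mask]) / um,
    uniform_mean = um, flagged = flagged
  )
}

#' Standard NU4 VOI masks for a phantom geometry
#'
#' Builds the three metric VOIs on a given slice stack: the 22.5 x 10 mm
#' uniformity VOI centered in the uniform section, and the two 4 x 7.5 mm
#' spill-over VOIs centered in the cold chambers.  The same uniform VOI
#' serves as NU numerator and SOR denominator.
#'
#' @param phantom An `nu4_phantom`.
#' @param grid,z_mm Grid and slice stack of the image the masks will index
#'   (default: the phantom's own).
#' @param nu_diameter_mm,nu_length_mm Uniformity VOI size.
#' @param sor_diameter_mm,sor_length_mm Spill-over VOI size.
#' @return A list of logical masks `uniform`, `air`, `water`, plus the RC
#'   axial window `rc_z_range` (central 10 mm of the rod section).
#' @export
nu4_vois <- function(phantom, grid = phantom$grid, z_mm = phantom$z_mm,
                     nu_diameter_mm = 22.5, nu_length_mm = 10,
                     sor_diameter_mm = 4, sor_length_mm = 7.5) {
  s <- phantom$sections
  off <- phantom$spec$cold_chamber_offset_mm
  list(
    uniform = cylinder_voi_mask(grid, z_mm, c(0, 0), nu_diameter_mm,
                                nu_length_mm, mean(s$uniform)),
    air = cylinder_voi_mask(grid, z_mm, c(off, 0), sor_diameter_mm,
                            sor_length_mm, mean(s$cold)),
    water = cylinder_voi_mask(grid, z_mm, c(-off, 0), sor_diameter_mm,
                              sor_length_mm, mean(s$cold)),
    rc_z_range = mean(s$rod) + c(-5, 5)
  )
}

#' One-row NU4 image-quality report
#'
#' Computes NU, RC per rod, and SOR for one reconstructed volume and
#' returns them as a single tibble row keyed by the configuration label,
#' ready to stack across configurations and feed to
#' [apply_rc_nu_criterion()].
#'
#' @param img A reconstructed [volume_3d()] in the units of
#'   `phantom$uniform_conc`.
#' @param phantom The `nu4_phantom` that generated the data.
#' @param config Configuration label.
#' @param correction Correction level label (e.g. `"partial"`, `"AC"`,
#'   `"AC_SC"`).
#' @param vois Optional precomputed [nu4_vois()] list.
#' @return A one-row tibble with `config`, `correction`, `nu_percent`,
#'   `nu_mean`, `rc_<d>mm` columns, `sor_air`, `sor_water`.
#' @export
nu4_iq_report <- function(img, phantom, config = "recon",
                          correction = "partial", vois = NULL) {
  vois <- vois %||% nu4_vois(phantom, img$grid, img$z_mm)
  nu <- non_uniformity(img, vois$uniform)
  rc <- recovery_coefficients(img, phantom$rods, phantom$uniform_conc,
                              vois$rc_z_range)
  sor <- spill_over_ratio(img, vois$air, vois$water, vois$uniform)
  rc_wide <- tidyr::pivot_wider(rc, names_from = "rod_mm", values_from = "rc",
                                names_glue = "rc_{rod_mm}mm")
  dplyr::bind_cols(
    tibble::tibble(config = config, correction = correction,
                   nu_percent = nu$percent_sd, nu_mean = nu$mean),
    rc_wide,
    tibble::tibble(sor_air = sor$sor_air, sor_water = sor$sor_water)
  )
}
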