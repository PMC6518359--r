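#' Gaussian post-reconstruction smoothing
#'
#' In-plane separable Gaussian smoothing of a reconstructed volume with a
#' stated full width at half maximum in mm
#' (\eqn{\sigma = \mathrm{FWHM}/2.3548}).  The kernel is applied as a
#' mass-conserving redistribution (out-of-range mass folded back by
#' reflection), so the image total is preserved to within floating-point
#' round-off.  Smoothing is applied within each slice only, so that
#' reduced, non-contiguous slice stacks smooth identically to full ones.
#'
#' @param img A [volume_3d()].
#' @param fwhm_mm Kernel FWHM in mm; `0` is the identity.
#' @return The smoothed [volume_3d()].
#' @export
gaussian_postfilter <- function(img, fwhm_mm) {
  if (fwhm_mm < 0) abort("fwhm must be non-negative", class = "petiq_validation_error")
  if (fwhm_mm == 0) return(img)
  sig_x <- fwhm_mm / 2.3548 / img$grid$dx
  sig_y <- fwhm_mm / 2.3548 / img$grid$dy
  Mx <- gaussian_redistribution_matrix(img$grid$nx, sig_x)
  My <- gaussian_redistribution_matrix(img$grid$ny, sig_y)
  out <- img
  for (k in seq_len(dim(img$values)[3])) {
    out$values[, , k] <- Mx %*% img$values[, , k] %*% t(My)
  }
  out
}

#' Attenuation correction factors from an attenuation map
#'
#' Per-bin multiplicative correction \eqn{\mathrm{ACF} = \exp(+\int\mu\,dl)}
#' along each ray.  Applying [apply_attenuation()] and then multiplying by
#' these factors is the identity on expected data.
#'
#' @param mu A [volume_3d()] of linear attenuation coefficients (1/mm).
#' @param geom A [scan_geometry()].
#' @param z_mm Slices for which to compute factors (default: all stored).
#' @return A `sinogram_stack`-shaped object of factors (>= 1).
#' @export
attenuation_correction_factors <- function(mu, geom = scan_geometry(),
                                           z_mm = NULL) {
  z_mm <- z_mm %||% mu$z_mm
  fac <- 1 / attenuation_survival(mu, geom, z_mm)
  structure(list(values = fac, geom = geom, z_mm = z_mm, kind = "acf"),
            class = "sinogram_stack")
}

#' Subtract a scatter estimate from a sinogram
#'
#' Plain subtraction of an additive scatter estimate.  By default negative
#' residuals are preserved (appropriate ahead of FBP); `clamp_floor = 0`
#' clamps for algorithms that require non-negative input.
#'
#' @param sino A [sinogram_stack()].
#' @param scatter_estimate A `sinogram_stack` of the same shape.
#' @param clamp_floor Lower clamp applied after subtraction, or `NULL` for
#'   none.
#' @return The corrected `sinogram_stack` (kind `"expected"`).
#' @export
scatter_correct <- function(sino, scatter_estimate, clamp_floor = NULL) {
  if (!identical(dim(sino$values), dim(scatter_estimate$values))) {
    abort("scatter estimate shape does not match sinogram",
          class = "petiq_validation_error")
  }
  out <- sino
  out$kind <- "expected"
  out$values <- sino$values - scatter_estimate$values
  if (!is.null(clamp_floor)) out$values <- pmax(out$values, clamp_floor)
  out
}

#' Scale a reconstruction to activity-concentration units
#'
#' Linear rescaling recording the resulting units; used to undo the count
#' scaling applied by [sample_counts()] (factor `1/count_scale`).
#'
#' @param img A [volume_3d()].
#' @param calibration_factor Positive multiplicative factor.
#' @param units Units after calibration.
#' @return The calibrated [volume_3d()].
#' @export
calibrate_to_concentration <- function(img, calibration_factor,
                                       units = "Bq/mL") {
  if (calibration_factor <= 0) {
    abort("calibration factor must be positive", class = "petiq_validation_error")
  }
  out <- img
  out$values <- img$values * calibration_factor
  out$units <- units
  out
}
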