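APODIZATION_WINDOWS <- c("ramp", "butterworth", "hamming", "hanning",
                         "parzen", "shepp_logan")

# window weight at normalized frequency f (cycles/sample) with cutoff f_c;
# every window is truncated to zero beyond f_c (documented convention, also
# applied to the Butterworth response)
window_weight <- function(name, f, f_c, butterworth_order = 4) {
  u <- abs(f) / f_c
  w <- switch(name,
    ramp = rep(1, length(f)),
    hanning = 0.5 * (1 + cos(pi * u)),
    hamming = 0.54 + 0.46 * cos(pi * u),
    parzen = ifelse(u <= 0.5, 1 - 6 * u^2 + 6 * u^3, 2 * (1 - u)^3),
    shepp_logan = ifelse(u == 0, 1, sin(pi * u / 2) / (pi * u / 2)),
    butterworth = 1 / sqrt(1 + u^(2 * butterworth_order)),
    abort(paste0("unknown apodization window '", name, "'"),
          class = "petiq_enum_error")
  )
  w[abs(f) > f_c] <- 0
  pmin(pmax(w, 0), 1)
}

#' Apodized ramp filter weights
#'
#' Frequency response of the FBP reconstruction filter: the ramp `|f|`
#' multiplied by a named apodization window with cutoff `cutoff` as a
#' fraction of the Nyquist frequency.  Frequencies are in cycles/sample on
#' `[0, 0.5]`; weights vanish beyond the cutoff.
#'
#' Window formulas (with \eqn{f_c} = cutoff x Nyquist):
#' Hanning \eqn{0.5(1 + \cos(\pi f/f_c))}; Hamming
#' \eqn{0.54 + 0.46\cos(\pi f/f_c)}; Parzen, the cubic B-spline window on
#' \eqn{|f|/f_c}; Shepp-Logan \eqn{\mathrm{sinc}(f/(2f_c))}; Butterworth
#' \eqn{1/\sqrt{1 + (f/f_c)^{2n}}} of order `n` (default 4); ramp, no
#' tapering.
#'
#' @param name One of `"ramp"`, `"butterworth"`, `"hamming"`, `"hanning"`,
#'   `"parzen"`, `"shepp_logan"`.
#' @param cutoff Cutoff as a fraction of Nyquist, in `(0, 1]` (default 0.5).
#' @param n_freqs Number of evaluation frequencies on `[0, 0.5]`.
#' @param butterworth_order Butterworth order.
#' @return A tibble with columns `freq` (cycles/sample), `window` (the
#'   apodization weight) and `weight` (ramp x window).
#' @export
#' @examples
#' apodization_window("hamming", cutoff = 0.5, n_freqs = 5)
apodization_window <- function(name, cutoff = 0.5, n_freqs = 65,
                               butterworth_order = 4) {
  name <- match.arg(name, APODIZATION_WINDOWS)
  if (cutoff <= 0 || cutoff > 1) {
    abort("cutoff must be in (0, 1]", class = "petiq_validation_error")
  }
  f <- seq(0, 0.5, length.out = n_freqs)
  f_c <- cutoff * 0.5
  w <- window_weight(name, f, f_c, butterworth_order)
  tibble::tibble(freq = f, window = w, weight = abs(f) * w)
}

#' Filtered back projection of a sinogram stack
#'
#' Classic 2D FBP: each projection is ramp-filtered in the frequency
#' domain under the chosen apodization window (zero-padded to the next
#' power of two at least twice the bin count to suppress circular
#' wraparound), then backprojected.  The output is linear in the input and
#' may contain negative values, particularly in and around cold regions --
#' this is expected analytic-reconstruction behavior and is preserved.
#'
#' @param sino A [sinogram_stack()] (counts or expected; corrections are
#'   applied beforehand, see [scatter_correct()] and
#'   [attenuation_correction_factors()]).
#' @param grid Target [grid_spec()] for the reconstructed slices.
#' @param filter_name Apodization window name (see [apodization_window()]).
#' @param cutoff Cutoff as a fraction of Nyquist.
#' @param butterworth_order Butterworth order.
#' @return A [volume_3d()] in sinogram units per mm.
#' @export
fbp2d <- function(sino, grid = grid_spec(), filter_name = "ramp",
                  cutoff = 0.5, butterworth_order = 4) {
  filter_name <- match.arg(filter_name, APODIZATION_WINDOWS)
  geom <- sino$geom
  nb <- geom$n_bins
  npad <- 2^ceiling(log2(2 * nb))
  ds <- geom$bin_width_mm
  # band-limited ramp from its discrete spatial kernel (keeps the correct
  # small positive DC term instead of zeroing it), then apodized
  pos <- c(0:(npad / 2), -(npad / 2 - 1):-1)
  h <- ifelse(pos == 0, 1 / (4 * ds^2),
              ifelse(pos %% 2 != 0, -1 / (pi^2 * pos^2 * ds^2), 0))
  ramp <- Re(fft(h)) * ds              # ~ |nu| in cycles/mm
  f_norm <- pos / npad                 # cycles/sample
  f_c <- cutoff * 0.5
  H <- ramp * window_weight(filter_name, f_norm, f_c, butterworth_order)

  M <- radon_matrix(grid, geom)
  nsl <- n_slices(sino)
  out <- array(0, dim = c(grid$nx, grid$ny, nsl))
  scale <- pi / (geom$n_angles * grid$dx * grid$dy / ds)
  for (s in seq_len(nsl)) {
    p <- rbind(sino$values[, , s], matrix(0, npad - nb, geom$n_angles))
    q <- Re(stats::mvfft(stats::mvfft(p) * H, inverse = TRUE)) / npad
    img <- as.numeric(M$At %*% as.vector(q[seq_len(nb), ]))
    out[, , s] <- matrix(img, grid$nx, grid$ny) * scale
  }
  volume_3d(out, grid, sino$z_mm, units = "arb")
}
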