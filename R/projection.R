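#' Parallel-beam scan geometry
#'
#' 2D parallel-beam acquisition geometry used for all per-slice forward
#' and back projection: `n_angles` views uniformly spaced over 0-180
#' degrees and `n_bins` radial bins of width `bin_width_mm` centered on the
#' grid axis.
#'
#' @param n_angles Number of projection angles (>= 1).
#' @param n_bins Number of radial bins.
#' @param bin_width_mm Radial bin width in mm (conventionally the in-plane
#'   voxel size).
#' @return A `scan_geometry` object.
#' @export
scan_geometry <- function(n_angles = 192, n_bins = 128, bin_width_mm = 0.776) {
  if (n_angles < 1 || n_bins < 1 || bin_width_mm <= 0) {
    abort("invalid scan geometry", class = "petiq_geometry_error")
  }
  structure(list(n_angles = as.integer(n_angles), n_bins = as.integer(n_bins),
                 bin_width_mm = bin_width_mm),
            class = "scan_geometry")
}

geometry_angles <- function(geom) (seq_len(geom$n_angles) - 1) * pi / geom$n_angles

geometry_bins_mm <- function(geom) {
  (seq_len(geom$n_bins) - (geom$n_bins + 1) / 2) * geom$bin_width_mm
}

# Sparse pixel-driven projector with linear interpolation between the two
# nearest radial bins.  Row i indexes (angle, bin), column j a pixel; the
# weight is the pixel footprint dx*dy/bin_width so that A %*% x
# approximates the line integral (units: x-units times mm).  Backprojection
# is the exact transpose.  Cached per (grid, geometry).
radon_matrix <- function(grid, geom) {
  key <- paste("radon", grid$nx, grid$ny, signif(grid$dx, 10), signif(grid$dy, 10),
               geom$n_angles, geom$n_bins, signif(geom$bin_width_mm, 10), sep = "_")
  hit <- .petiq_cache[[key]]
  if (!is.null(hit)) return(hit)

  x <- grid_x(grid)
  y <- grid_y(grid)
  X <- rep(x, times = grid$ny)
  Y <- rep(y, each = grid$nx)
  npix <- grid$nx * grid$ny
  wgt <- grid$dx * grid$dy / geom$bin_width_mm
  th <- geometry_angles(geom)
  ctr <- (geom$n_bins + 1) / 2

  ii <- vector("list", geom$n_angles)
  jj <- vector("list", geom$n_angles)
  ww <- vector("list", geom$n_angles)
  for (a in seq_len(geom$n_angles)) {
    s <- X * cos(th[a]) + Y * sin(th[a])
    tb <- s / geom$bin_width_mm + ctr
    i0 <- floor(tb)
    w1 <- tb - i0
    row0 <- (a - 1L) * geom$n_bins + i0
    keep0 <- i0 >= 1 & i0 <= geom$n_bins
    keep1 <- i0 + 1 >= 1 & i0 + 1 <= geom$n_bins
    ii[[a]] <- c(row0[keep0], (row0 + 1L)[keep1])
    jj[[a]] <- c(seq_len(npix)[keep0], seq_len(npix)[keep1])
    ww[[a]] <- c(((1 - w1) * wgt)[keep0], (w1 * wgt)[keep1])
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(ww),
    dims = c(geom$n_angles * geom$n_bins, npix)
  )
  out <- list(A = A, At = Matrix::t(A))
  .petiq_cache[[key]] <- out
  out
}

# round-robin angular subsets; returns list of list(A, At, rows)
radon_subsets <- function(grid, geom, n_subsets) {
  if (geom$n_angles %% n_subsets != 0) {
    abort("n_subsets must divide n_angles", class = "petiq_validation_error")
  }
  key <- paste("subsets", grid$nx, grid$ny, signif(grid$dx, 10), geom$n_angles,
               geom$n_bins, signif(geom$bin_width_mm, 10), n_subsets, sep = "_")
  hit <- .petiq_cache[[key]]
  if (!is.null(hit)) return(hit)
  M <- radon_matrix(grid, geom)
  subs <- lapply(seq_len(n_subsets), function(s) {
    ang <- which((seq_len(geom$n_angles) - 1L) %% n_subsets == (s - 1L))
    rows <- as.vector(outer(seq_len(geom$n_bins), (ang - 1L) * geom$n_bins, `+`))
    As <- M$A[rows, , drop = FALSE]
    list(A = As, At = Matrix::t(As), rows = rows)
  })
  .petiq_cache[[key]] <- subs
  subs
}

#' Sinogram stack container
#'
#' Per-slice parallel-beam projection data: an array
#' `[n_bins, n_angles, n_slices]` with its [scan_geometry()], the axial
#' position of each slice, and a `kind` distinguishing expected (real,
#' non-negative) from sampled (integer count) data.
#'
#' @param values Numeric array `[n_bins, n_angles, n_slices]` (a matrix is
#'   treated as one slice).
#' @param geom A `scan_geometry`.
#' @param z_mm Axial slice positions in mm.
#' @param kind `"expected"` or `"counts"`.
#' @return A `sinogram_stack` object.
#' @export
sinogram_stack <- function(values, geom, z_mm, kind = "expected") {
  values <- as.array(values)
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1L)
  stopifnot(dim(values)[1] == geom$n_bins, dim(values)[2] == geom$n_angles,
            dim(values)[3] == length(z_mm))
  if (any(!is.finite(values))) {
    abort("sinogram values must be finite", class = "petiq_validation_error")
  }
  if (kind == "counts" && any(values < 0 | values != round(values))) {
    abort("sampled counts must be non-negative integers",
          class = "petiq_validation_error")
  }
  structure(list(values = values, geom = geom, z_mm = z_mm, kind = kind),
            class = "sinogram_stack")
}

#' @export
print.sinogram_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<sinogram_stack> %d bins x %d angles x %d slices (%s), total %.4g\n",
              d[1], d[2], d[3], x$kind, sum(x$values)))
  invisible(x)
}

n_slices <- function(x) dim(x$values)[3]

#' Forward project an activity volume into sinograms
#'
#' Computes the discretized line integral of the activity concentration
#' along every (angle, bin) ray of each stored slice.  The operation is
#' linear; units are input units times mm (Bq/mL volumes yield
#' Bq/mL x mm line integrals).
#'
#' @param map A [volume_3d()] of activity concentration.
#' @param geom A [scan_geometry()].
#' @param slices Indices into the stored slices (default all).
#' @return A `sinogram_stack` of kind `"expected"`.
#' @export
forward_project <- function(map, geom = scan_geometry(), slices = NULL) {
  v <- map$values
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("activity map must be finite and non-negative",
          class = "petiq_validation_error")
  }
  slices <- slices %||% seq_len(dim(v)[3])
  M <- radon_matrix(map$grid, geom)
  flat <- matrix(v[, , slices, drop = FALSE],
                 nrow = map$grid$nx * map$grid$ny, ncol = length(slices))
  P <- as.matrix(M$A %*% flat)
  sinogram_stack(array(P, dim = c(geom$n_bins, geom$n_angles, length(slices))),
                 geom, map$z_mm[slices], kind = "expected")
}

#' Apply photon attenuation to an expected sinogram
#'
#' Multiplies each bin by the survival probability
#' \eqn{\exp(-\int \mu \, dl)} along its ray, computed from a 511 keV
#' attenuation map on the same grid and slice stack.
#'
#' @param sino A `sinogram_stack` of expected data.
#' @param mu A [volume_3d()] of linear attenuation coefficients (1/mm).
#' @return The attenuated `sinogram_stack`.
#' @export
apply_attenuation <- function(sino, mu) {
  if (any(mu$values < 0)) {
    abort("attenuation coefficients must be non-negative",
          class = "petiq_validation_error")
  }
  fac <- attenuation_survival(mu, sino$geom, sino$z_mm)
  out <- sino
  out$values <- sino$values * fac
  out
}

# exp(-line integral of mu) as an [angles, bins, slices] array
attenuation_survival <- function(mu, geom, z_mm) {
  idx <- match(z_mm, mu$z_mm)
  if (any(is.na(idx))) {
    abort("attenuation map does not cover the requested slices",
          class = "petiq_geometry_error")
  }
  M <- radon_matrix(mu$grid, geom)
  flat <- matrix(mu$values[, , idx, drop = FALSE],
                 nrow = mu$grid$nx * mu$grid$ny, ncol = length(idx))
  L <- as.matrix(M$A %*% flat)
  array(exp(-L), dim = c(geom$n_bins, geom$n_angles, length(idx)))
}

# mass-conserving 1D Gaussian redistribution matrix along bins (columns sum
# to 1; out-of-range mass folded back by reflection)
gaussian_redistribution_matrix <- function(n, sigma_bins) {
  key <- paste("gredist", n, signif(sigma_bins, 10), sep = "_")
  hit <- .petiq_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- max(1L, ceiling(4 * sigma_bins))
  off <- -half:half
  k <- exp(-off^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    dest <- j + off
    dest <- ifelse(dest < 1, 2 - dest, dest)       # reflect low edge
    dest <- ifelse(dest > n, 2 * n - dest, dest)   # reflect high edge
    for (m in seq_along(dest)) M[dest[m], j] <- M[dest[m], j] + k[m]
  }
  .petiq_cache[[key]] <- M
  M
}

#' Add a convolution scatter component to an expected sinogram
#'
#' Emulates scattered coincidences by adding a broad-Gaussian radial
#' convolution of the true sinogram, scaled so that scatter makes up
#' `scatter_fraction` of the total output counts.  The scatter term is also
#' returned separately so that scatter correction can be exercised against
#' a known truth.
#'
#' @param sino A `sinogram_stack` of expected true coincidences.
#' @param scatter_fraction Scatter fraction of total prompts, in `[0, 1)`.
#' @param kernel_fwhm_mm FWHM of the radial scatter kernel in mm.
#' @return A list with elements `sinogram` (trues + scatter) and
#'   `scatter_estimate` (the scatter term alone).
#' @export
add_scatter <- function(sino, scatter_fraction = 0.15, kernel_fwhm_mm = 12) {
  if (scatter_fraction < 0 || scatter_fraction >= 1) {
    abort("scatter_fraction must be in [0, 1)", class = "petiq_validation_error")
  }
  out <- sino
  sc <- sino
  if (scatter_fraction == 0) {
    sc$values[] <- 0
    return(list(sinogram = out, scatter_estimate = sc))
  }
  sigma <- kernel_fwhm_mm / 2.3548 / sino$geom$bin_width_mm
  M <- gaussian_redistribution_matrix(sino$geom$n_bins, sigma)
  f <- scatter_fraction / (1 - scatter_fraction)
  for (k in seq_len(n_slices(sino))) {
    sc$values[, , k] <- f * (M %*% sino$values[, , k])
  }
  out$values <- sino$values + sc$values
  list(sinogram = out, scatter_estimate = sc)
}

#' Draw Poisson counts from an expected sinogram
#'
#' Scales the expectation so that it sums to `target_total_counts` over the
#' whole stack, then draws independent Poisson counts per bin.  The applied
#' scale factor (counts per expected unit) is attached as attribute
#' `"count_scale"`; dividing a reconstruction by it restores concentration
#' units (see [calibrate_to_concentration()]).
#'
#' @param sino A `sinogram_stack` of expected data.
#' @param target_total_counts Desired expected total count (> 0).
#' @param seed Integer seed; the draw is reproducible under a fixed seed
#'   and does not disturb the caller's RNG state.
#' @return A `sinogram_stack` of kind `"counts"`.
#' @export
sample_counts <- function(sino, target_total_counts, seed = 1L) {
  if (target_total_counts <= 0) {
    abort("target_total_counts must be positive", class = "petiq_validation_error")
  }
  tot <- sum(sino$values)
  if (tot <= 0) abort("expected sinogram is empty", class = "petiq_validation_error")
  scale <- target_total_counts / tot
  lam <- sino$values * scale
  counts <- withr::with_seed(as.integer(seed), rpois(length(lam), lam))
  out <- sinogram_stack(array(as.numeric(counts), dim = dim(lam)),
                        sino$geom, sino$z_mm, kind = "counts")
  attr(out, "count_scale") <- scale
  out
}
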