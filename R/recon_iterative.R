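#' Ordered-subset expectation maximization (2D)
#'
#' Standard OSEM with round-robin angular subsets and the multiplicative
#' Poisson update.  The forward model for bin \eqn{i} is
#' \eqn{\bar y_i = a_i (Ax)_i + r_i}, where \eqn{a_i = 1/\mathrm{ACF}_i}
#' is the attenuation survival factor and \eqn{r_i} an additive scatter
#' expectation, so attenuation and scatter enter the statistical model
#' rather than being pre-subtracted.  The iterate starts from a uniform
#' positive image and stays non-negative throughout; voxels with zero
#' sensitivity are masked, never divided by.  With `n_subsets = 1` the
#' update is exactly MLEM.
#'
#' @param sino A [sinogram_stack()] of counts (or noiseless expectations).
#' @param grid Target [grid_spec()].
#' @param n_subsets Number of angular subsets; must divide `n_angles`.
#' @param n_iterations Number of full passes over all subsets.
#' @param acf Optional attenuation correction factors
#'   (`[n_bins, n_angles, n_slices]`, values >= 1) as returned by
#'   [attenuation_correction_factors()].
#' @param scatter_estimate Optional additive scatter `sinogram_stack` in
#'   the same units as `sino`.
#' @param keep_iterations If `TRUE`, return the image after every full
#'   iteration (a list of [volume_3d()]), otherwise only the final one.
#' @return A [volume_3d()], or a list of them when `keep_iterations`.
#' @export
osem2d <- function(sino, grid = grid_spec(), n_subsets = 16, n_iterations = 1,
                   acf = NULL, scatter_estimate = NULL,
                   keep_iterations = FALSE) {
  if (any(sino$values < 0)) {
    abort("OSEM input counts must be non-negative", class = "petiq_validation_error")
  }
  subs <- radon_subsets(grid, sino$geom, n_subsets)
  nsl <- n_slices(sino)
  npix <- grid$nx * grid$ny
  eps <- .Machine$double.eps
  iters <- if (keep_iterations) {
    lapply(seq_len(n_iterations), function(i) array(0, c(grid$nx, grid$ny, nsl)))
  }
  final <- array(0, c(grid$nx, grid$ny, nsl))

  for (s in seq_len(nsl)) {
    y <- sino$values[, , s]
    a <- if (is.null(acf)) NULL else 1 / acf$values[, , s]
    r <- if (is.null(scatter_estimate)) NULL else scatter_estimate$values[, , s]
    x <- rep(1, npix)
    sens <- lapply(subs, function(sb) {
      av <- if (is.null(a)) rep(1, length(sb$rows)) else as.vector(a)[sb$rows]
      as.numeric(sb$At %*% av)
    })
    x[Reduce(`+`, sens) == 0] <- 0  # voxels no subset ever sees
    for (it in seq_len(n_iterations)) {
      for (k in seq_along(subs)) {
        sb <- subs[[k]]
        ys <- as.vector(y)[sb$rows]
        av <- if (is.null(a)) 1 else as.vector(a)[sb$rows]
        rs <- if (is.null(r)) 0 else as.vector(r)[sb$rows]
        ybar <- av * as.numeric(sb$A %*% x) + rs
        ratio <- ys / pmax(ybar, eps)
        back <- as.numeric(sb$At %*% (av * ratio))
        ok <- sens[[k]] > 0
        x[ok] <- x[ok] * back[ok] / sens[[k]][ok]
      }
      if (keep_iterations) iters[[it]][, , s] <- matrix(x, grid$nx, grid$ny)
    }
    final[, , s] <- matrix(x, grid$nx, grid$ny)
  }
  if (keep_iterations) {
    lapply(iters, volume_3d, grid = grid, z_mm = sino$z_mm, units = "arb")
  } else {
    volume_3d(final, grid, sino$z_mm, units = "arb")
  }
}

# quadratic-prior gradient over the 8-neighborhood (2D, per slice);
# diagonal neighbors down-weighted by 1/sqrt(2)
quadratic_prior_gradient <- function(xmat) {
  nx <- nrow(xmat); ny <- ncol(xmat)
  pad <- matrix(0, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- xmat
  # replicate edges so boundary voxels see their own value (zero penalty)
  pad[1, ] <- pad[2, ]; pad[nx + 2, ] <- pad[nx + 1, ]
  pad[, 1] <- pad[, 2]; pad[, ny + 2] <- pad[, ny + 1]
  g <- matrix(0, nx, ny)
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  for (m in seq_len(nrow(offs))) {
    w <- if (abs(offs$di[m]) + abs(offs$dj[m]) == 2) 1 / sqrt(2) else 1
    nb <- pad[(2:(nx + 1)) + offs$di[m], (2:(ny + 1)) + offs$dj[m]]
    g <- g + w * (xmat - nb)
  }
  g
}

#' One-step-late MAP-EM with a quadratic smoothing prior
#'
#' Penalized-likelihood EM reconstruction: the MLEM update divided by
#' `sensitivity + beta * dU(x)`, with `U` the quadratic penalty over the
#' 8-neighborhood evaluated at the previous iterate (one-step-late).
#' `beta = 0` reproduces MLEM exactly; larger `beta` buys smoother images
#' at the cost of lower peak values.
#'
#' @inheritParams osem2d
#' @param beta Smoothing-prior strength (>= 0).
#' @param n_iterations Number of EM iterations (default 18).
#' @return A [volume_3d()].
#' @export
mapem2d <- function(sino, grid = grid_spec(), beta = 0.1, n_iterations = 18,
                    acf = NULL, scatter_estimate = NULL) {
  if (beta < 0) abort("beta must be non-negative", class = "petiq_validation_error")
  if (any(sino$values < 0)) {
    abort("MAP-EM input counts must be non-negative",
          class = "petiq_validation_error")
  }
  M <- radon_matrix(grid, sino$geom)
  nsl <- n_slices(sino)
  npix <- grid$nx * grid$ny
  eps <- .Machine$double.eps
  out <- array(0, c(grid$nx, grid$ny, nsl))
  for (s in seq_len(nsl)) {
    y <- as.vector(sino$values[, , s])
    a <- if (is.null(acf)) rep(1, length(y)) else 1 / as.vector(acf$values[, , s])
    r <- if (is.null(scatter_estimate)) 0 else as.vector(scatter_estimate$values[, , s])
    sens <- as.numeric(M$At %*% a)
    x <- rep(1, npix)
    for (it in seq_len(n_iterations)) {
      ybar <- a * as.numeric(M$A %*% x) + r
      back <- as.numeric(M$At %*% (a * (y / pmax(ybar, eps))))
      denom <- sens + beta * as.vector(quadratic_prior_gradient(
        matrix(x, grid$nx, grid$ny)))
      ok <- denom > 0 & sens > 0
      xn <- x
      xn[ok] <- x[ok] * back[ok] / denom[ok]
      xn[!ok] <- 0
      if (any(!is.finite(xn))) {
        abort(sprintf("MAP-EM diverged at iteration %d (non-finite update)", it),
              class = "petiq_divergence_error")
      }
      x <- xn
    }
    out[, , s] <- matrix(x, grid$nx, grid$ny)
  }
  volume_3d(out, grid, sino$z_mm, units = "arb")
}
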