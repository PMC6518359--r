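#' Write / read a volume as NIfTI
#'
#' Stores a [volume_3d()] as NIfTI with mm voxel sizes in the header.  The
#' axial coordinate of each stored slice and the units travel in a YAML
#' sidecar (`<path>.yaml`), since reduced slice stacks are not contiguous.
#'
#' @param vol A `volume_3d`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly (writer); a `volume_3d` (reader).
#' @export
write_volume_nifti <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- c(vol$grid$dx, vol$grid$dy, vol$grid$dz)
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(z_mm = as.numeric(vol$z_mm), units = vol$units,
                        grid = unclass(vol$grid)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- paste0(path, ".yaml")
  if (!file.exists(side)) {
    abort("missing YAML sidecar for NIfTI volume", class = "petiq_io_error")
  }
  meta <- yaml::read_yaml(side)
  g <- meta$grid
  grid <- grid_spec(g$nx, g$ny, g$nz, g$dx, g$dy, g$dz)
  volume_3d(array(as.numeric(img), dim = dim(img)), grid,
            as.numeric(meta$z_mm), units = meta$units)
}

#' Write / read a sinogram stack as raw binary + YAML sidecar
#'
#' The raw file holds little-endian doubles in `[bin, angle, slice]` order;
#' the sidecar documents shape, dtype, geometry, slice positions, and kind.
#'
#' @param sino A [sinogram_stack()].
#' @param path_prefix Output prefix; writes `<prefix>.raw` and
#'   `<prefix>.yaml`.
#' @return The prefix, invisibly (writer); a `sinogram_stack` (reader).
#' @export
write_sinogram_raw <- function(sino, path_prefix) {
  con <- file(paste0(path_prefix, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.vector(sino$values), con, size = 8, endian = "little")
  yaml::write_yaml(list(
    shape = dim(sino$values), order = c("bin", "angle", "slice"),
    dtype = "float64", endian = "little", kind = sino$kind,
    z_mm = as.numeric(sino$z_mm),
    geometry = list(n_angles = sino$geom$n_angles, n_bins = sino$geom$n_bins,
                    bin_width_mm = sino$geom$bin_width_mm)
  ), paste0(path_prefix, ".yaml"))
  invisible(path_prefix)
}

#' @rdname write_sinogram_raw
#' @export
read_sinogram_raw <- function(path_prefix) {
  meta <- yaml::read_yaml(paste0(path_prefix, ".yaml"))
  n <- prod(unlist(meta$shape))
  con <- file(paste0(path_prefix, ".raw"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n, size = 8, endian = meta$endian)
  geom <- scan_geometry(meta$geometry$n_angles, meta$geometry$n_bins,
                        meta$geometry$bin_width_mm)
  sinogram_stack(array(v, dim = unlist(meta$shape)), geom,
                 as.numeric(meta$z_mm), kind = meta$kind)
}

#' Load a YAML configuration file
#'
#' Thin wrapper used by the command-line scripts: reads a YAML file and
#' returns it as a named list, erroring on missing files.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_yaml_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "petiq_io_error")
  }
  yaml::read_yaml(path)
}
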