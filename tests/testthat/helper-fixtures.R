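# Small geometries shared across tests.  96 angles keeps 16 subsets exactly
# balanced; 64 x 64 at 1 mm resolves every phantom feature used here.

tiny_grid <- function(nz = 1) grid_spec(64, 64, nz, 1, 1, 1)

tiny_geom <- function() scan_geometry(n_angles = 96, n_bins = 64,
                                      bin_width_mm = 1)

# uniform disc of radius r_mm and concentration conc, centered
tiny_disc <- function(conc = 5, r_mm = 20, nz = 1) {
  g <- tiny_grid(nz)
  x <- (seq_len(g$nx) - (g$nx + 1) / 2) * g$dx
  disc <- outer(x^2, x^2, `+`) <= r_mm^2
  volume_3d(array(rep(disc * conc, nz), c(g$nx, g$ny, nz)), g,
            ((seq_len(nz) - (nz + 1) / 2) * g$dz))
}

# small-but-complete NU4 phantom: 30 mm body fits a 64 x 64 grid at the
# default in-plane voxel size; 65 slices cover the 50 mm phantom
small_phantom <- function() {
  build_nu4_phantom(phantom_spec(), grid_spec(64, 64, 65))
}

small_phantom_geom <- function() {
  g <- grid_spec(64, 64, 65)
  scan_geometry(n_angles = 96, n_bins = g$nx, bin_width_mm = g$dx)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
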