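test_that("cylindrical VOI volume matches the analytic cylinder", {
  grid <- grid_spec()
  z <- (seq_len(grid$nz) - (grid$nz + 1) / 2) * grid$dz
  mask <- cylinder_voi_mask(grid, z, c(0, 0), diameter_mm = 22.5,
                            length_mm = 10, z_center_mm = 0)
  vol <- sum(mask) * voxel_volume_mm3(grid)
  expect_rel_equal(vol, pi * 11.25^2 * 10, 0.05)
})

test_that("VOI construction rejects degenerate and out-of-bounds cylinders", {
  grid <- grid_spec(64, 64, 9)
  z <- (seq_len(9) - 5) * grid$dz
  expect_error(cylinder_voi_mask(grid, z, c(0, 0), 0, 10),
               class = "petiq_validation_error")
  expect_error(cylinder_voi_mask(grid, z, c(0, 0), 200, 10),
               class = "petiq_geometry_error")
  expect_error(cylinder_voi_mask(grid, z, c(0, 0), 10, 10, z_center_mm = 500),
               class = "petiq_geometry_error")
})

test_that("centered VOI mask is invariant under 90-degree grid rotation", {
  grid <- grid_spec(64, 64, 5)
  z <- (seq_len(5) - 3) * grid$dz
  mask <- cylinder_voi_mask(grid, z, c(0, 0), 20, 3)
  rotated <- aperm(mask, c(2, 1, 3))[, rev(seq_len(64)), ]
  expect_identical(mask, rotated)
})

test_that("non-uniformity uses the population %SD convention", {
  grid <- grid_spec(3, 1, 1, 1, 1, 1)
  img <- volume_3d(array(c(90, 100, 110), c(3, 1, 1)), grid, 0)
  mask <- array(TRUE, c(3, 1, 1))
  nu <- non_uniformity(img, mask)
  # population SD of {90,100,110} = sqrt(200/3)
  expect_equal(nu$percent_sd, 100 * sqrt(200 / 3) / 100)
  expect_equal(nu$mean, 100)
  expect_equal(nu$max, 110)
  expect_equal(nu$min, 90)

  img$values[] <- 7
  expect_equal(non_uniformity(img, mask)$percent_sd, 0)

  img$values <- c(90, 100, 110) * 3.7
  expect_equal(non_uniformity(img, mask)$percent_sd,
               100 * sqrt(200 / 3) / 100)

  img$values <- c(-1, 0, 1)
  flagged <- non_uniformity(img, mask)
  expect_true(flagged$flagged)
  expect_true(is.na(flagged$percent_sd))
})

test_that("the identity reconstruction is the fixed point of the IQ chain", {
  ph <- small_phantom()
  rep <- nu4_iq_report(ph$activity, ph, config = "identity")
  expect_equal(rep$nu_percent, 0)
  for (col in c("rc_2mm", "rc_3mm", "rc_4mm", "rc_5mm")) {
    expect_equal(rep[[col]], 1)
  }
  expect_equal(rep$sor_air, 0)
  expect_equal(rep$sor_water, 0)
  expect_false("rc_1mm" %in% names(rep))  # sub-resolution rod excluded
})

test_that("all IQ metrics are invariant under positive rescaling", {
  ph <- small_phantom()
  noisy <- ph$activity
  set.seed(5)
  noisy$values <- noisy$values + abs(rnorm(length(noisy$values), 0, 1e3))
  r1 <- nu4_iq_report(noisy, ph)
  scaled <- noisy; scaled$values <- noisy$values * 3.14
  ph2 <- ph; ph2$uniform_conc <- ph$uniform_conc * 3.14
  r2 <- nu4_iq_report(scaled, ph2)
  for (col in c("nu_percent", "rc_2mm", "rc_3mm", "rc_5mm", "sor_air",
                "sor_water")) {
    expect_equal(r1[[col]], r2[[col]], tolerance = 1e-12)
  }
})

test_that("recovery coefficients report unclamped peaks and zero images", {
  ph <- small_phantom()
  vois <- nu4_vois(ph)
  zero <- ph$activity; zero$values[] <- 0
  rc0 <- recovery_coefficients(zero, ph$rods, ph$uniform_conc, vois$rc_z_range)
  expect_true(all(rc0$rc == 0))

  hot <- ph$activity
  lev <- attr(ph$labels, "levels")
  r3 <- ph$labels$values == match("rod_3", lev)
  hot$values[r3] <- 1.5 * ph$uniform_conc  # overshoot is reported as-is
  rc <- recovery_coefficients(hot, ph$rods, ph$uniform_conc, vois$rc_z_range)
  expect_equal(rc$rc[rc$rod_mm == 3], 1.5)
  expect_error(recovery_coefficients(hot, ph$rods, 0, vois$rc_z_range),
               class = "petiq_validation_error")
})

test_that("spill-over ratio handles cold, uniform, and flagged cases", {
  ph <- small_phantom()
  vois <- nu4_vois(ph)
  sor <- spill_over_ratio(ph$activity, vois$air, vois$water, vois$uniform)
  expect_equal(sor$sor_air, 0)
  expect_equal(sor$sor_water, 0)

  flat <- ph$activity; flat$values[] <- 42
  sor1 <- spill_over_ratio(flat, vois$air, vois$water, vois$uniform)
  expect_equal(sor1$sor_air, 1)
  expect_equal(sor1$sor_water, 1)

  neg <- ph$activity; neg$values <- -ph$activity$values
  sorf <- spill_over_ratio(neg, vois$air, vois$water, vois$uniform)
  expect_true(sorf$flagged)
})
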