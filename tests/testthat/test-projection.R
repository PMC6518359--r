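test_that("central bin of a uniform disc equals the 2R chord integral", {
  conc <- 5; R <- 20
  sino <- forward_project(tiny_disc(conc, R), tiny_geom())
  ctr <- (tiny_geom()$n_bins + 1) / 2
  for (b in c(floor(ctr), ceiling(ctr))) {
    expect_rel_equal(sino$values[b, 1, 1], 2 * R * conc, 0.02)
  }
})

test_that("forward projection is linear and zero maps project to zero", {
  g <- tiny_geom()
  v1 <- tiny_disc(5, 20)
  v2 <- tiny_disc(2, 10)
  s1 <- forward_project(v1, g)
  s2 <- forward_project(v2, g)
  both <- v1
  both$values <- 3 * v1$values + 2 * v2$values
  expect_equal(forward_project(both, g)$values,
               3 * s1$values + 2 * s2$values, tolerance = 1e-12)
  zero <- v1; zero$values[] <- 0
  expect_true(all(forward_project(zero, g)$values == 0))
})

test_that("rotationally symmetric objects give angle-invariant sinograms", {
  sino <- forward_project(tiny_disc(5, 15), tiny_geom())
  per_angle <- apply(sino$values[, , 1], 2, sum)
  expect_lt(diff(range(per_angle)) / mean(per_angle), 0.01)
  # per-bin profiles agree across angles within the discretization ripple
  # of a pixel-driven projector (worst at oblique angles)
  prof <- sino$values[, c(1, 25, 49, 73), 1]
  expect_lt(max(abs(prof - rowMeans(prof))) / max(prof), 0.08)
})

test_that("attenuation multiplies bins by exp(-mu integral)", {
  g <- tiny_geom()
  disc <- tiny_disc(5, 20)
  sino <- forward_project(disc, g)
  mu0 <- disc; mu0$values[] <- 0; mu0$units <- "1/mm"
  expect_equal(apply_attenuation(sino, mu0)$values, sino$values)

  mu <- disc; mu$values <- (disc$values > 0) * 0.0096; mu$units <- "1/mm"
  att <- apply_attenuation(sino, mu)
  ctr <- floor((g$n_bins + 1) / 2)
  expect_rel_equal(att$values[ctr, 1, 1],
                   sino$values[ctr, 1, 1] * exp(-0.0096 * 40), 0.02)
  fac <- att$values / pmax(sino$values, .Machine$double.eps)
  expect_true(all(fac[sino$values > 0] <= 1 + 1e-12))

  mu2 <- mu; mu2$values <- 2 * mu$values
  att2 <- apply_attenuation(sino, mu2)
  expect_true(all(att2$values <= att$values + 1e-12))
  expect_error(apply_attenuation(sino, { m <- mu; m$values[1] <- -1; m }),
               class = "petiq_validation_error")
})

test_that("scatter addition conserves the prescribed scatter fraction", {
  sino <- forward_project(tiny_disc(5, 12), tiny_geom())
  none <- add_scatter(sino, 0)
  expect_equal(none$sinogram$values, sino$values)
  expect_true(all(none$scatter_estimate$values == 0))

  sf <- 0.23
  out <- add_scatter(sino, sf, kernel_fwhm_mm = 12)
  expect_equal(sum(out$scatter_estimate$values) / sum(out$sinogram$values),
               sf, tolerance = 1e-6)
  expect_equal(out$sinogram$values,
               sino$values + out$scatter_estimate$values)
  # bins with no true counts near the object edge gain scattered counts
  empty_true <- sino$values == 0
  expect_gt(sum(out$scatter_estimate$values[empty_true] > 0), 0)
  expect_error(add_scatter(sino, 1), class = "petiq_validation_error")
})

test_that("Poisson sampling is seeded, unbiased, and Poisson-dispersed", {
  sino <- forward_project(tiny_disc(5, 15), tiny_geom())
  a <- sample_counts(sino, 2e4, seed = 11)
  b <- sample_counts(sino, 2e4, seed = 11)
  expect_identical(a$values, b$values)
  expect_true(all(a$values[sino$values == 0] == 0))
  expect_true(all(a$values >= 0 & a$values == round(a$values)))

  target <- 2e4
  n_rep <- 100
  totals <- vapply(seq_len(n_rep),
                   function(s) sum(sample_counts(sino, target, seed = s)$values),
                   numeric(1))
  expect_lt(abs(mean(totals) - target), 3 * sqrt(target / n_rep))

  # per-bin variance ~ mean (Poisson) over replicates
  n_rep2 <- 300
  draws <- vapply(seq_len(n_rep2),
                  function(s) as.vector(sample_counts(sino, 2e5, seed = 1000 + s)$values),
                  numeric(length(sino$values)))
  mu_hat <- rowMeans(draws)
  keep <- mu_hat >= 20
  ratio <- apply(draws[keep, ], 1, var) / mu_hat[keep]
  expect_gt(mean(abs(ratio - 1) <= 0.2), 0.95)
  expect_lt(abs(median(ratio) - 1), 0.05)
})

test_that("sinogram container validates counts and shapes", {
  g <- tiny_geom()
  expect_error(sinogram_stack(array(-1, c(g$n_bins, g$n_angles, 1)), g, 0,
                              kind = "counts"),
               class = "petiq_validation_error")
  expect_error(sinogram_stack(array(Inf, c(g$n_bins, g$n_angles, 1)), g, 0),
               class = "petiq_validation_error")
  expect_error(forward_project({ d <- tiny_disc(); d$values[1] <- -1; d }, g),
               class = "petiq_validation_error")
})
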