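test_that("ROI peak extraction returns the maximum and its position", {
  g <- grid_spec(8, 8, 3, 1, 1, 1)
  img <- volume_3d(array(2, c(8, 8, 3)), g, -1:1)
  mask <- array(TRUE, c(8, 8, 3))
  expect_equal(roi_max_concentration(img, mask)$value, 2)

  img$values[5, 3, 2] <- 99
  hit <- roi_max_concentration(img, mask)
  expect_equal(hit$value, 99)
  expect_equal(as.vector(hit$position), c(5, 3, 2))

  submask <- mask; submask[5, 3, 2] <- FALSE
  expect_lte(roi_max_concentration(img, submask)$value, hit$value)
  expect_error(roi_max_concentration(img, array(FALSE, c(8, 8, 3))),
               class = "petiq_validation_error")
})

test_that("%ID/g follows its defining ratio", {
  expect_equal(percent_id_per_gram(1e6, 1e6), 100)
  expect_equal(percent_id_per_gram(0, 5e6), 0)
  expect_equal(percent_id_per_gram(1e5, 1e6) * 2,
               percent_id_per_gram(1e5, 5e5))
  expect_equal(percent_id_per_gram(1e5, 1e6, density_g_per_mL = 2),
               percent_id_per_gram(1e5, 2e6))
  expect_error(percent_id_per_gram(1, 0), class = "petiq_validation_error")
})

test_that("cumulated activity matches closed-form integrals", {
  lam <- cu64_lambda()
  # dense mono-exponential: integral = A0 / lambda
  tt <- seq(0, 300, by = 0.05)
  tac <- tibble::tibble(time_h = tt, value = 10 * exp(-lam * tt))
  expect_rel_equal(cumulated_activity(tac, lam), 10 / lam, 0.01)

  # two equal points: c*t1 (backfill) + c*(t2-t1) (trapezoid) + c/lambda (tail)
  c0 <- 4; t1 <- 2; t2 <- 9
  tac2 <- tibble::tibble(time_h = c(t1, t2), value = c(c0, c0))
  expect_equal(cumulated_activity(tac2, lam),
               c0 * t1 + c0 * (t2 - t1) + c0 / lam, tolerance = 1e-12)

  zero <- tibble::tibble(time_h = c(1, 2), value = c(0, 0))
  expect_equal(cumulated_activity(zero, lam), 0)

  expect_error(cumulated_activity(
    tibble::tibble(time_h = c(1, 2), value = c(-1, 1)), lam),
    class = "petiq_validation_error")
  expect_error(cumulated_activity(
    tibble::tibble(time_h = 1, value = 1), lam),
    class = "petiq_validation_error")
  expect_error(cumulated_activity(
    tibble::tibble(time_h = c(1, 2), value = c(1, 1),
                   decay_corrected = TRUE), lam),
    class = "petiq_validation_error")
})

test_that("residence time is cumulated activity over injected activity", {
  expect_equal(residence_time(14.8, 14.8), 1)
  expect_equal(residence_time(2 * 14.8, 14.8), 2)
  expect_error(residence_time(1, 0), class = "petiq_validation_error")

  # all injected activity decaying in place: tau = 1/lambda = 12.7/ln(2)
  lam <- cu64_lambda()
  tt <- seq(0, 400, by = 0.02)
  tac <- tibble::tibble(time_h = tt, value = 14.8 * exp(-lam * tt))
  tau <- residence_time(cumulated_activity(tac, lam), 14.8)
  expect_rel_equal(tau, 12.7 / log(2), 0.001)
})

test_that("power-law S-value fits recover exact generating parameters", {
  m <- c(0.05, 0.1, 0.5, 1, 2, 5)
  tab <- tibble::tibble(mass_g = m, s_mGy_per_MBq_h = 2 * m^-0.9)
  fit <- fit_sphere_svalue(tab)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, -0.9, tolerance = 1e-6)
  expect_equal(s_value(fit, 0.37), 2 * 0.37^-0.9, tolerance = 1e-6)

  td <- tidy(fit)
  expect_equal(td$estimate, c(2, -0.9), tolerance = 1e-6)
  expect_equal(glance(fit)$r.squared, 1, tolerance = 1e-9)

  expect_error(fit_sphere_svalue(tab[1, ]), class = "petiq_validation_error")
  bad <- tab; bad$s_mGy_per_MBq_h[3] <- 100
  expect_error(fit_sphere_svalue(bad), class = "petiq_validation_error")
})

test_that("power-law interpolation lies below linear interpolation", {
  tab <- readr::read_csv(petiq_extdata("svalues_cu64_sphere_synthetic.csv"),
                         show_col_types = FALSE)
  fit <- fit_sphere_svalue(tab)
  m <- tab$mass_g
  s <- tab$s_mGy_per_MBq_h
  for (i in seq_len(nrow(tab) - 1)) {
    mid <- sqrt(m[i] * m[i + 1]) * 1.01  # interior point of each bracket
    lin <- s[i] + (s[i + 1] - s[i]) * (mid - m[i]) / (m[i + 1] - m[i])
    expect_lte(s_value(fit, mid), lin + 1e-9)
  }
})

test_that("tumor absorbed dose is the tau x S(m) product", {
  tab <- tibble::tibble(mass_g = c(0.05, 0.2, 1, 5),
                        s_mGy_per_MBq_h = 70 * c(0.05, 0.2, 1, 5)^-0.95)
  fit <- fit_sphere_svalue(tab)
  expect_equal(tumor_absorbed_dose(0, 0.2, fit), 0)
  expect_equal(tumor_absorbed_dose(2 * 1.3, 0.2, fit),
               2 * tumor_absorbed_dose(1.3, 0.2, fit))
  expect_equal(tumor_absorbed_dose(1.3, 0.2, fit),
               1.3 * 70 * 0.2^-0.95, tolerance = 1e-6)
  expect_warning(s_value(fit, 50), "outside")
  expect_error(tumor_absorbed_dose(1, -1, fit),
               class = "petiq_validation_error")
})

test_that("organ dose assembly is linear with a weighted effective dose", {
  smat <- read_organ_smatrix()
  expect_equal(sum(smat$weights), 1, tolerance = 1e-9)
  for (o in rownames(smat$S)) expect_equal(names(which.max(smat$S[o, ])), o)

  res0 <- tibble::tibble(region = c("liver", "kidneys"), tau_h = c(0, 0))
  d0 <- organ_dose(res0, smat)
  expect_true(all(d0$dose_mSv_per_MBq == 0))
  expect_equal(attr(d0, "effective_dose_mSv_per_MBq"), 0)

  res <- tibble::tibble(region = c("liver", "kidneys"), tau_h = c(2, 0.5))
  d1 <- organ_dose(res, smat)
  d2 <- organ_dose(dplyr::mutate(res, tau_h = 2 * tau_h), smat)
  expect_equal(d2$dose_mSv_per_MBq, 2 * d1$dose_mSv_per_MBq)
  expect_equal(attr(d2, "effective_dose_mSv_per_MBq"),
               2 * attr(d1, "effective_dose_mSv_per_MBq"))

  single <- tibble::tibble(region = "liver", tau_h = 3)
  ds <- organ_dose(single, smat)
  expect_equal(ds$dose_mSv_per_MBq[ds$target == "liver"],
               3 * smat$S["liver", "liver"])
  expect_equal(attr(ds, "effective_dose_mSv_per_MBq"),
               sum(smat$weights * ds$dose_mSv_per_MBq))

  expect_error(organ_dose(tibble::tibble(region = "tail", tau_h = 1), smat),
               class = "petiq_lookup_error")
})

test_that("mouse-to-human scaling follows relative organ mass", {
  mouse <- tibble::tibble(region = c("liver", "total_body"),
                          mass_g = c(1.3, 25))
  human <- tibble::tibble(region = c("liver", "total_body"),
                          mass_g = c(1800, 73000))
  res <- tibble::tibble(region = c("liver", "total_body"), tau_h = c(2, 10))
  scaled <- scale_mouse_to_human(res, mouse, human)
  expect_equal(scaled$tau_h[2], 10)  # total body invariant
  expect_equal(scaled$tau_h[1], 2 * (1800 / 73000) / (1.3 / 25))

  # identical relative masses: identity
  human2 <- tibble::tibble(region = c("liver", "total_body"),
                           mass_g = c(1.3, 25) * 2920)
  expect_equal(scale_mouse_to_human(res, mouse, human2)$tau_h, res$tau_h)

  expect_error(scale_mouse_to_human(
    tibble::tibble(region = "spleen", tau_h = 1), mouse, human),
    class = "petiq_lookup_error")
})

test_that("the TAC chain recovers analytic residence times", {
  kin <- mouse_kinetics_spec()
  for (reg in kin$regions$region) {
    truth <- analytic_residence_time(kin, reg)
    # paper-style sparse 4-point schedule
    tac4 <- generate_organ_tac(kin, timepoint_schedule(), reg)
    tau4 <- residence_time_from_tac(tac4)
    expect_rel_equal(tau4, truth, 0.15)
    # dense sampling
    tacd <- generate_organ_tac(kin, timepoint_schedule(seq(0.1, 200, by = 0.1)),
                               reg)
    taud <- residence_time_from_tac(tacd)
    expect_rel_equal(taud, truth, 0.02)
  }
})

test_that("residence times respect the physical whole-body bound", {
  kin <- mouse_kinetics_spec()
  taus <- vapply(kin$regions$region, function(r) {
    residence_time_from_tac(generate_organ_tac(kin, timepoint_schedule(), r))
  }, numeric(1))
  expect_true(all(taus >= 0))
  expect_lt(sum(taus), 1 / kin$lambda_phys)
})

test_that("residence time is invariant to the TAC time unit after conversion", {
  kin <- mouse_kinetics_spec()
  tac <- generate_organ_tac(kin, timepoint_schedule(), "tumor")
  tac_min <- tac
  tac_min$time_h <- tac$time_h * 60          # now minutes
  tac_min$time_h <- tac_min$time_h / 60      # convert back before integrating
  expect_equal(residence_time_from_tac(tac_min), residence_time_from_tac(tac))
})
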