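test_that("percent difference matches the printed anchor cells", {
  expect_equal(round(percent_difference(1830, 1320), 1), 32.4)
  expect_equal(round(percent_difference(923, 1320), 1), -35.4)
  expect_equal(round(percent_difference(1.41, 0.18), 1), 154.7)
  expect_equal(percent_difference(7, 7), 0)
  expect_error(percent_difference(1, -1), class = "petiq_validation_error")
})

test_that("percent difference is antisymmetric, bounded, and monotone", {
  set.seed(12)
  x <- runif(200, 0.001, 100)
  r <- runif(200, 0.001, 100)
  pd <- percent_difference(x, r)
  expect_equal(pd, -percent_difference(r, x))
  expect_true(all(pd > -200 & pd < 200))
  ord <- sort(runif(50, 0.1, 10))
  expect_false(is.unsorted(percent_difference(ord, 3)))
})

test_that("the packaged dose table has the printed layout", {
  t1 <- read_dose_table()
  expect_equal(nrow(t1), 24)
  expect_length(attr(t1, "config_columns"), 19)
  expect_equal(t1$region[1], "Tumor")
  expect_true("osem2d_it1" %in% attr(t1, "config_columns"))
})

test_that("the full percent-difference table reproduces cell-by-cell", {
  t1 <- read_dose_table()
  printed <- readr::read_csv(petiq_extdata("table2_percent_diff.csv"),
                             show_col_types = FALSE)
  cmp <- compare_to_reference(t1, "osem2d_it1", rounded = TRUE)
  expect_false("osem2d_it1" %in% names(cmp))
  expect_equal(names(cmp), names(printed))
  for (cc in setdiff(names(printed), "region")) {
    expect_true(all(abs(cmp[[cc]] - printed[[cc]]) <= 0.1 + 1e-9),
                label = paste("column", cc))
  }
  expect_equal(cmp$osem2d_it10[cmp$region == "Tumor"], 32.4)
  expect_equal(cmp$fbp_butterworth[cmp$region == "Tumor"], -35.4)
  expect_equal(cmp$osem2d_it10[cmp$region == "Kidneys"], 154.7)
  expect_equal(cmp$fbp_butterworth[cmp$region == "Kidneys"], -20.9)
  expect_equal(cmp$osem2d_it10[cmp$region == "Brain"], 169.6)
})

test_that("comparison against the reference column itself is zero", {
  t1 <- read_dose_table()
  expect_true(all(percent_difference(t1$osem2d_it1, t1$osem2d_it1) == 0))
  expect_error(compare_to_reference(t1, "nonexistent"),
               class = "petiq_lookup_error")
})

test_that("comparison tables render at one decimal and round-trip", {
  t1 <- read_dose_table()
  cmp <- compare_to_reference(t1)
  path <- tempfile(fileext = ".csv")
  write_comparison(cmp, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$osem2d_it10[back$region == "Tumor"], 32.4)
  expect_equal(dim(back), c(24, 19))
})

test_that("range and spread reproduce the tumor-row claims", {
  t1 <- read_dose_table()
  tumor <- as.numeric(t1[t1$region == "Tumor",
                         attr(t1, "config_columns")])
  rs <- range_spread(tumor)
  expect_equal(rs$min, 923)
  expect_equal(rs$max, 1830)
  expect_gte(rs$rel_spread_percent, 98)

  expect_equal(range_spread(c(5, 5, 5))$rel_spread_percent, 0)
  expect_equal(range_spread(c(1, 2))$rel_spread_percent, 100)
  expect_error(range_spread(numeric(0)), class = "petiq_validation_error")
  expect_error(range_spread(c(1, -2)), class = "petiq_validation_error")
})

test_that("max-normalization maps the maximum to one and keeps order", {
  x <- c(3, 1, 2)
  nx <- normalize_by_max(x)
  expect_equal(max(nx), 1)
  expect_equal(order(nx), order(x))
  expect_equal(normalize_by_max(c(4, 4)), c(1, 1))
  expect_error(normalize_by_max(c(-1, -2)), class = "petiq_validation_error")
})

test_that("r-squared behaves as a squared Pearson correlation", {
  x <- 1:10
  expect_equal(coefficient_of_determination(x, 2 * x), 1)
  # designed zero-covariance pairs
  x0 <- c(-1, 0, 1, 0)
  y0 <- c(0, 1, 0, -1)
  expect_equal(coefficient_of_determination(x0, y0), 0, tolerance = 1e-12)
  # affine invariance
  y <- c(2, 5, 3, 8, 7, 1, 9, 4, 6, 10)
  expect_equal(coefficient_of_determination(x, y),
               coefficient_of_determination(10 + 3 * x, -2 * y + 1),
               tolerance = 1e-12)
  expect_error(coefficient_of_determination(1:2, 1:2),
               class = "petiq_validation_error")
  expect_error(coefficient_of_determination(rep(1, 5), 1:5),
               class = "petiq_validation_error")
})

test_that("malformed dose tables are rejected with located errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("region,cfg_a,cfg_b", "Tumor,100,200", "Liver,-5,80"), path)
  expect_error(read_dose_table(path), regexp = "cfg_a.*line",
               class = "petiq_io_error")
  writeLines(c("organ,cfg_a", "Tumor,100"), path)
  expect_error(read_dose_table(path), class = "petiq_io_error")
})
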