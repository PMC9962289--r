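test_that("identity resampling returns the input bit-for-bit", {
  set.seed(5)
  m <- parametric_map(array(rnorm(60), c(5, 4, 3)), "fraction",
                      spacing = c(2, 2, 6))
  out <- resample_to_reference(m, c(5L, 4L, 3L), m$affine)
  expect_identical(out$values, m$values)
  expect_identical(out$valid, m$valid)
})

test_that("linear interpolation of a constant map is that constant", {
  m <- parametric_map(array(3.25, c(6, 6, 4)), "mL/100g/min",
                      spacing = c(2, 2, 2))
  ref_aff <- diag(c(1, 1, 1, 1))  # 2x finer grid inside the source extent
  out <- resample_to_reference(m, c(8L, 8L, 5L), ref_aff, "linear")
  expect_true(any(out$valid))
  expect_true(all(out$values[out$valid] == 3.25))
})

test_that("2x upsampling a ramp interpolates midpoint averages", {
  # ramp along x: value = x index; reference voxels land at integer and
  # half-integer source positions
  ramp <- array(rep(1:8, times = 4 * 2), c(8, 4, 2))
  m <- parametric_map(ramp, "fraction", spacing = c(2, 2, 2))
  ref_aff <- diag(c(1, 2, 2, 1))
  out <- resample_to_reference(m, c(15L, 4L, 2L), ref_aff, "linear")
  # closed-form oracle: position x_mm/2 + 1 in voxel units
  expected <- 1 + (0:14) / 2
  got <- out$values[, 1, 1]
  expect_equal(got[out$valid[, 1, 1]], expected[out$valid[, 1, 1]],
               tolerance = 1e-12)
  # midpoints really are averages of neighbours
  expect_equal(got[2], (ramp[1, 1, 1] + ramp[2, 1, 1]) / 2)
})

test_that("nearest-neighbour resampling picks the closest voxel", {
  vals <- array(1:4, c(4, 1, 1)) * 10
  m <- parametric_map(array(vals, c(4, 1, 1)), "fraction", spacing = c(4, 4, 4))
  ref_aff <- diag(c(1, 4, 4, 1))
  out <- resample_to_reference(m, c(13L, 1L, 1L), ref_aff, "nearest")
  expect_equal(out$values[5, 1, 1], 20)  # 4 mm -> source voxel 2
})

test_that("validity propagates conservatively through interpolation", {
  vals <- array(1, c(4, 4, 2))
  valid <- array(TRUE, c(4, 4, 2)); valid[2, 2, 1] <- FALSE
  m <- parametric_map(vals, "fraction", spacing = c(1, 1, 1), valid = valid)
  out <- resample_to_reference(m, c(4L, 4L, 2L),
                               m$affine %*% rbind(cbind(diag(3) , c(0.5, 0, 0)),
                                                  c(0, 0, 0, 1)),
                               "linear")
  # any target voxel whose 8-neighbourhood touches the invalid voxel is invalid
  expect_false(out$valid[1, 2, 1])
  expect_false(out$valid[2, 2, 1])
  expect_true(out$valid[3, 3, 1])
})

test_that("singular affines are rejected", {
  m <- parametric_map(array(1, c(2, 2, 2)), "fraction")
  bad <- diag(c(1, 1, 0, 1))
  expect_error(resample_to_reference(m, c(2L, 2L, 2L), bad), "singular")
  expect_error(resample_to_reference(m, c(2L, 2L, 2L), diag(4),
                                     src_affine = bad), "singular")
})

test_that("histogram features match the stated conventions on {1..5}", {
  m <- parametric_map(array(c(1, 2, 3, 4, 5), c(5, 1, 1)), "fraction")
  f <- extract_histogram_features(m, array(TRUE, c(5, 1, 1)))
  expect_equal(f$mean, 3)
  expect_equal(f$min, 1)
  expect_equal(f$max, 5)
  expect_equal(f$p50, 3)
  expect_equal(f$p10, 1.4)
  expect_equal(f$skewness, 0)
  expect_equal(f$kurtosis, -1.3)
  expect_identical(f$n_voxels, 5L)
  expect_false(f$degenerate)
})

test_that("constant ROIs report the degenerate flag and zero shape stats", {
  m <- parametric_map(array(7.5, c(3, 3, 1)), "mL/100g/min")
  f <- extract_histogram_features(m, array(TRUE, c(3, 3, 1)))
  expect_true(f$degenerate)
  expect_equal(f$skewness, 0)
  expect_equal(f$kurtosis, 0)
  expect_true(all(c(f$mean, f$min, f$max, f$p10, f$p25, f$p50, f$p75,
                    f$p90) == 7.5))
})

test_that("features are order-invariant and exclude invalid voxels", {
  set.seed(14)
  x <- rnorm(40)
  m1 <- parametric_map(array(x, c(40, 1, 1)), "fraction")
  m2 <- parametric_map(array(sample(x), c(40, 1, 1)), "fraction")
  mask <- array(TRUE, c(40, 1, 1))
  f1 <- extract_histogram_features(m1, mask)
  f2 <- extract_histogram_features(m2, mask)
  for (s in histogram_stat_names()) expect_equal(f1[[s]], f2[[s]])

  valid <- array(TRUE, c(40, 1, 1)); valid[1:10] <- FALSE
  m3 <- parametric_map(array(x, c(40, 1, 1)), "fraction", valid = valid)
  f3 <- extract_histogram_features(m3, mask)
  o <- oracle_features(x[11:40])
  expect_equal(f3$mean, o$mean)
  expect_identical(f3$n_voxels, 30L)
  expect_error(extract_histogram_features(m3, array(c(rep(TRUE, 5),
                                                      rep(FALSE, 35)),
                                                    c(40, 1, 1))),
               "empty effective ROI")
})

test_that("features agree with the sorting oracle on random ROIs", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    x <- rnorm(n, sd = sample(c(0.01, 1, 50), 1))
    m <- parametric_map(array(x, c(n, 1, 1)), "fraction")
    f <- extract_histogram_features(m, array(TRUE, c(n, 1, 1)))
    o <- oracle_features(x)
    for (s in histogram_stat_names())
      expect_lt(abs(f[[s]] - o[[s]]), 1e-12 * max(1, abs(o[[s]])))
    expect_true(f$min <= f$p10 && f$p10 <= f$p25 && f$p25 <= f$p50 &&
                  f$p50 <= f$p75 && f$p75 <= f$p90 && f$p90 <= f$max)
  }
})

test_that("relative features subtract statistic-by-statistic", {
  m1 <- parametric_map(array(c(10, 20, 30, 40), c(4, 1, 1)), "mL/100g/min")
  m2 <- parametric_map(array(c(5, 10, 15, 20), c(4, 1, 1)), "mL/100g/min")
  mask <- array(TRUE, c(4, 1, 1))
  a <- extract_histogram_features(m1, mask)
  b <- extract_histogram_features(m2, mask)
  r <- relative_features(a, b, "rASL")
  expect_equal(r$mean, 25 - 12.5)
  expect_equal(r$max, 20)
  # identical inputs -> all-zero
  z <- relative_features(a, a, "rASL")
  for (s in histogram_stat_names()) expect_equal(z[[s]], 0)
  # antisymmetry
  r2 <- relative_features(b, a, "rASL")
  for (s in histogram_stat_names()) expect_equal(r[[s]], -r2[[s]])
  # hypoperfused lesion -> negative relative mean
  r3 <- relative_features(b, a, "rASL")
  expect_lt(r3$mean, 0)
})

test_that("unit mismatches between ROI feature sets are rejected", {
  mask <- array(TRUE, c(4, 1, 1))
  a <- extract_histogram_features(
    parametric_map(array(1:4, c(4, 1, 1)), "fraction"), mask)
  b <- extract_histogram_features(
    parametric_map(array(1:4, c(4, 1, 1)), "mL/100g/min"), mask)
  expect_error(relative_features(a, b, "rAPT"), "unit mismatch")
})

test_that("feature rows use documented names and report rAPT in percent", {
  mask <- array(TRUE, c(4, 1, 1))
  a <- extract_histogram_features(
    parametric_map(array(c(.01, .02, .03, .04), c(4, 1, 1)), "fraction"), mask)
  b <- extract_histogram_features(
    parametric_map(array(c(.005, .01, .015, .02), c(4, 1, 1)), "fraction"),
    mask)
  row <- relative_features_row(relative_features(a, b, "rAPT"))
  expect_identical(names(row), paste0("rAPT_", histogram_stat_names()))
  expect_equal(unname(row["rAPT_mean"]), (0.025 - 0.0125) * 100)
  # dimensionless shape stats are not rescaled
  r <- relative_features(a, b, "rAPT")
  expect_equal(unname(row["rAPT_skewness"]), r$skewness)
})
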