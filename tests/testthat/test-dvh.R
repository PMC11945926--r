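test_that("cumulative DVH matches hand-counted histograms", {
  shp <- c(2, 1, 1)
  d <- array(c(10, 30), shp); m <- array(TRUE, shp)
  dvh <- compute_dvh(d, m, bin_Gy = 0.1)
  # half the volume receives at least 20 Gy
  i20 <- which.min(abs(dvh$dose_Gy - 20))
  expect_equal(dvh$volume_fraction[i20], 0.5)
  expect_equal(dvh$volume_fraction[1], 1)
  expect_equal(dvh$volume_fraction[length(dvh$volume_fraction)], 0)
  # uniform dose: a step function at the dose level
  du <- array(60, c(3, 3, 3))
  dvhu <- compute_dvh(du, array(TRUE, c(3, 3, 3)), bin_Gy = 0.1)
  expect_true(all(dvhu$volume_fraction[dvhu$dose_Gy <= 60] == 1))
  expect_true(all(dvhu$volume_fraction[dvhu$dose_Gy > 60] == 0))
  expect_error(compute_dvh(d, array(FALSE, shp)), "empty mask")
})

test_that("DVH curves are monotone and bounded for arbitrary dose maps", {
  set.seed(9)
  for (i in 1:5) {
    d <- array(rexp(4^3, 1 / 30), c(4, 4, 4))
    dvh <- compute_dvh(d, array(TRUE, c(4, 4, 4)), bin_Gy = 0.5)
    expect_true(all(diff(dvh$volume_fraction) <= 0))
    expect_true(all(dvh$volume_fraction >= 0 & dvh$volume_fraction <= 1))
    v <- as.numeric(d)
    expect_lte(dose_at_volume(v, 0.99), dose_at_volume(v, 0.95))
  }
})

test_that("coverage dose follows the at-least-p convention", {
  expect_equal(dose_at_volume(c(10, 30), 0.5), 30)
  expect_equal(dose_at_volume(c(10, 30), 1), 10)
  du <- compute_dvh(array(60, c(2, 2, 2)), array(TRUE, c(2, 2, 2)))
  expect_equal(dose_at_volume(du, 0.95), 60, tolerance = 0.1)
  expect_equal(dose_at_volume(du, 0.5), 60, tolerance = 0.1)
  expect_error(dose_at_volume(c(1, 2), 0), "in \\(0, 1]")
  expect_error(dose_at_volume(du, 1.5), "in \\(0, 1]")
})

test_that("activity prescription is the exact linear rescale", {
  shp <- c(5, 5, 5)
  set.seed(13)
  d <- array(rexp(prod(shp), 1 / 100), shp)
  m <- array(TRUE, shp)
  # identity: if D95 already equals the prescription, keep the activity
  d60 <- d * 60 / dose_at_volume(as.numeric(d), 0.95)
  expect_equal(prescribe_activity(d60, m, 60, 0.95, 1000), 1000,
               tolerance = 1e-12)
  # linear rescale formula at the cohort-median magnitude
  d1 <- d * 222.9 / dose_at_volume(as.numeric(d), 0.95)
  expect_equal(prescribe_activity(d1, m, 60, 0.95, 1000), 1000 * 60 / 222.9,
               tolerance = 1e-12)
  expect_equal(1000 * 60 / 222.9, 269.18, tolerance = 1e-4)
  # closed loop: recomputing D95 at the prescribed activity gives 60 Gy
  A95 <- prescribe_activity(d, m, 60, 0.95, 1000)
  expect_equal(dose_at_volume(as.numeric(d * A95 / 1000), 0.95), 60,
               tolerance = 1e-6)
  expect_error(prescribe_activity(d * 0, m, 60, 0.95, 1000), "zero PTV")
})

test_that("BED matching inverts the permanent-implant quadratic", {
  p <- bed_params("tumor")
  shp <- c(4, 4, 4); m <- array(TRUE, shp)
  # uniform dose: solver must agree with the closed-form inversion
  d <- array(150, shp)
  target <- 90
  A <- prescribe_activity_bed_matched(d, m, target, p,
                                      nominal_activity_MBq = 1000)
  D_wanted <- invert_bed_y90(target, p)
  expect_equal(A, 1000 * D_wanted / 150, tolerance = 1e-6)
  # fixed point: target already achieved at the nominal activity
  set.seed(3)
  dh <- array(rexp(prod(shp), 1 / 80), shp)
  t0 <- mean(bed_y90(dh, p))
  expect_equal(prescribe_activity_bed_matched(dh, m, t0, p,
                                              nominal_activity_MBq = 400),
               400, tolerance = 1e-6)
  # monotone: a higher target needs more activity
  A1 <- prescribe_activity_bed_matched(dh, m, t0, p, nominal_activity_MBq = 400)
  A2 <- prescribe_activity_bed_matched(dh, m, 2 * t0, p,
                                       nominal_activity_MBq = 400)
  expect_gt(A2, A1)
  # D95-level matching statistic is supported
  A3 <- prescribe_activity_bed_matched(dh, m, t0, p, statistic = "D95",
                                       nominal_activity_MBq = 400)
  d95 <- dose_at_volume(as.numeric(dh * A3 / 400), 0.95)
  expect_equal(bed_y90(d95, p), t0, tolerance = 1e-6)
})

test_that("paired plan comparison handles regular and degenerate input", {
  r <- compare_plans(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_false(r$degenerate)
  # antisymmetry under label swap
  r2 <- compare_plans(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-12)
  # all-equal differences: flagged, not NaN
  rd <- compare_plans(c(2, 3, 4), c(1, 2, 3))
  expect_true(rd$degenerate)
  expect_true(is.na(rd$statistic) && is.na(rd$p_value))
  expect_equal(rd$mean_difference, 1)
  expect_error(compare_plans(1, 2), "length")
})
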