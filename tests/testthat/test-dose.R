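test_that("FFT convolution equals the brute-force direct sum", {
  set.seed(31)
  a <- array(runif(9^3), c(9, 9, 9))
  kv <- array(runif(5^3), c(5, 5, 5))
  am <- build_activity_map(a, array(TRUE, c(9, 9, 9)), 100, voxel_mm = 1)
  dm <- convolve_dose(am, fake_kernel(kv))
  atil <- cumulated_activity(am)
  oracle <- direct_convolve(atil, kv) / 1000
  expect_lt(max(abs(dm$voxel_dose - oracle)) / max(oracle), 1e-10)
})

test_that("a point source reproduces the translated kernel", {
  k <- small_kernel()
  shp <- c(25, 25, 25)
  img <- array(0, shp); msk <- array(FALSE, shp)
  img[13, 13, 13] <- 1; msk[13, 13, 13] <- TRUE
  am <- build_activity_map(img, msk, 50, voxel_mm = 1.6)
  dm <- convolve_dose(am, k)
  atil <- 50 / (log(2) / 64 / 3600)
  expected <- array(0, shp)
  expected[13 + (-8:8), 13 + (-8:8), 13 + (-8:8)] <- k$values * atil / 1000
  expect_equal(dm$voxel_dose, expected, tolerance = 1e-9)
})

test_that("convolution is linear and translation-equivariant", {
  set.seed(5)
  kv <- array(runif(3^3), c(3, 3, 3))
  mk <- array(TRUE, c(7, 7, 7))
  a1 <- array(runif(7^3), c(7, 7, 7)); a2 <- array(runif(7^3), c(7, 7, 7))
  d1 <- convolve_dose(build_activity_map(a1, mk, 10, voxel_mm = 1),
                      fake_kernel(kv))$voxel_dose
  d2 <- convolve_dose(build_activity_map(a2, mk, 20, voxel_mm = 1),
                      fake_kernel(kv))$voxel_dose
  # same voxelwise activity pattern summed: 10*a1/sum(a1) + 20*a2/sum(a2)
  w <- 10 * a1 / sum(a1) + 20 * a2 / sum(a2)
  d12 <- convolve_dose(build_activity_map(w, mk, 30, voxel_mm = 1),
                       fake_kernel(kv))$voxel_dose
  expect_equal(d12, d1 + d2, tolerance = 1e-9)
  # shift the activity one voxel along x: interior dose shifts identically
  a <- array(0, c(9, 9, 9)); a[4, 5, 5] <- 1
  b <- array(0, c(9, 9, 9)); b[5, 5, 5] <- 1
  mk9 <- array(TRUE, c(9, 9, 9))
  da <- convolve_dose(build_activity_map(a, mk9, 1, voxel_mm = 1),
                      fake_kernel(kv))$voxel_dose
  db <- convolve_dose(build_activity_map(b, mk9, 1, voxel_mm = 1),
                      fake_kernel(kv))$voxel_dose
  expect_equal(db[3:9, , ], da[2:8, , ], tolerance = 1e-12)
})

test_that("uniform activity reaches the analytic equilibrium dose", {
  k <- fixture("eq_kernel",
               generate_dvk(grid = kernel_grid(17, 1.6), n_primaries = 2e6,
                            n_batches = 8, seed = 21))
  kb <- k; kb$values <- k$beta_component   # beta only: fully contained
  shp <- c(33, 33, 33)
  conc_MBq <- 2 / prod(shp)                # 2 MBq spread uniformly
  am <- uniform_activity(shp, total = 2, voxel_mm = 1.6)
  dm <- convolve_dose(am, kb)
  ctr <- dm$voxel_dose[17, 17, 17]
  # closed form: cumulated activity concentration x energy per decay / mass
  atil <- conc_MBq / (log(2) / 64 / 3600)              # MBq s per voxel
  mass_kg <- (1.6^3 / 1000) / 1000
  sp <- beta_spectrum()
  d_eq <- atil * 1e6 * (1 - k$brems_yield) * sp$mean_MeV * 1.602176634e-13 /
    mass_kg
  expect_equal(ctr, d_eq, tolerance = 1e-3)
  # equilibrium region is uniform
  core <- dm$voxel_dose[13:21, 13:21, 13:21]
  expect_lt(diff(range(core)) / mean(core), 1e-3)
})

test_that("mismatched kernels and bad inputs are refused", {
  k <- small_kernel()           # 1.6 mm kernel
  am <- uniform_activity(c(9, 9, 9), voxel_mm = 0.8)
  expect_error(convolve_dose(am, k), "voxel size")
  am2 <- uniform_activity(c(9, 9, 9), voxel_mm = 1.6)
  am2$voxel_activity[1] <- NaN
  expect_error(convolve_dose(am2, k), "non-finite")
})

test_that("dose maps survive a file round trip, including the DVH", {
  ph <- small_phantom()
  k <- small_kernel()
  am <- build_activity_map(ph$intensity, ph$structures$PTV, 1000,
                           voxel_mm = 1.6)
  dm <- convolve_dose(am, k)
  pre <- file.path(withr::local_tempdir(), "dose")
  write_dose(dm, pre)
  dm2 <- read_dose(pre)
  expect_equal(dm2$voxel_dose, dm$voxel_dose, tolerance = 1e-6)
  expect_equal(dm2$voxel_mm, dm$voxel_mm)
  expect_identical(dm2$source, "convolution")
  dvh1 <- compute_dvh(dm, ph$structures$PTV)
  dvh2 <- compute_dvh(dm2, ph$structures$PTV)
  # 32-bit storage may push single voxels across bin edges, nothing more
  nshare <- min(length(dvh1$volume_fraction), length(dvh2$volume_fraction))
  expect_lt(max(abs(dvh2$volume_fraction[seq_len(nshare)] -
                      dvh1$volume_fraction[seq_len(nshare)])),
            2.5 / dvh1$n_voxels)
  expect_equal(dose_at_volume(dvh2, 0.95), dose_at_volume(dvh1, 0.95),
               tolerance = 1e-6)
})
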