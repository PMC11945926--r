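test_that("energy-to-dose unit conversion matches hand arithmetic", {
  g <- kernel_grid(1, c(0.8, 0.8, 0.78))
  e <- array(1, c(1, 1, 1))  # 1 MeV per decay in one voxel
  # hand chain: 1 MeV = 1.602176634e-13 J; voxel mass 4.992e-7 kg at 1 g/cm3;
  # 1 MBq s = 1e6 decays; Gy -> mGy
  expected <- 1.602176634e-13 / 4.992e-7 * 1e6 * 1e3
  expect_equal(as.numeric(energy_to_dose_rate_units(e, g)), expected,
               tolerance = 1e-9)
  expect_equal(as.numeric(energy_to_dose_rate_units(e * 0, g)), 0)
  expect_equal(as.numeric(energy_to_dose_rate_units(e, g, density_g_cm3 = 2)),
               expected / 2, tolerance = 1e-9)
  expect_error(energy_to_dose_rate_units(e, g, density_g_cm3 = 0), "positive")
})

test_that("kernel satisfies its structural invariants", {
  k <- small_kernel()
  expect_equal(k$values, k$beta_component + k$photon_component,
               tolerance = 1e-12)
  expect_true(all(k$values >= 0))
  ctr <- k$grid$center; d <- k$grid$shape
  expect_equal(which.max(k$values),
               ((ctr[3] - 1L) * d[2] + (ctr[2] - 1L)) * d[1] + ctr[1])
  # determinism: identical configuration and seed => bitwise identical values
  k2 <- generate_dvk(grid = kernel_grid(17, 1.6), n_primaries = 4e4,
                     n_batches = 8, seed = 11)
  expect_identical(k$values, k2$values)
})

test_that("beta transport conserves the spectrum's energy per decay", {
  k <- small_kernel()
  sp <- beta_spectrum()
  vol_cm3 <- prod(k$grid$voxel_mm) / 1000
  mass_kg <- vol_cm3 / 1000
  # sum(dose x mass), undoing the per-MBq-s and mGy scalings, in MeV/decay
  beta_MeV <- sum(k$beta_component) * mass_kg / 1.602176634e-13 / 1e9
  sd_E <- sqrt(sum(diff(sp$energy_MeV) *
                     (head(sp$energy_MeV^2 * sp$density, -1) +
                        tail(sp$energy_MeV^2 * sp$density, -1)) / 2) -
                 sp$mean_MeV^2)
  tol3se <- 3 * sd_E / sqrt(k$n_primaries)
  expect_lt(abs(beta_MeV / (1 - k$brems_yield) - sp$mean_MeV), tol3se)
  # the grid fully contains the beta range: nothing escaped
  expect_equal(unname(k$energy_MeV_per_decay["beta_escaped"]), 0)
})

test_that("kernel is isotropic and radially decreasing within noise", {
  k <- small_kernel()
  d <- k$grid$shape
  v <- k$beta_component
  rv <- v[d[1]:1, d[2]:1, d[3]:1]
  comb <- sqrt(k$se^2 + (k$se[d[1]:1, d[2]:1, d[3]:1])^2)
  sel <- comb > 0
  # reflection symmetry: deviations consistent with batch noise
  # (a <1% tail beyond 3 combined SE is the Gaussian expectation)
  expect_lt(mean(abs(v - rv)[sel] > 3 * comb[sel]), 0.01)
  # spherically averaged profile decreases monotonically in rank
  prof <- radial_profile(v, k$grid)
  prof <- prof[prof$r_mm < 10 & prof$n > 5, ]
  expect_lt(cor(prof$r_mm, prof$mean, method = "spearman"), -0.95)
})

test_that("central-voxel self-dose agrees with a higher-statistics rerun", {
  k <- small_kernel()
  kh <- fixture("small_kernel_hi",
                generate_dvk(grid = kernel_grid(17, 1.6), n_primaries = 4e5,
                             n_batches = 8, seed = 12))
  ctr <- k$grid$center
  dev <- abs(k$beta_component[ctr[1], ctr[2], ctr[3]] -
               kh$beta_component[ctr[1], ctr[2], ctr[3]])
  comb <- sqrt(k$se[ctr[1], ctr[2], ctr[3]]^2 + kh$se[ctr[1], ctr[2], ctr[3]]^2)
  expect_lt(dev, 2 * comb)
})

test_that("batch uncertainty follows the 1/sqrt(N) Monte Carlo law", {
  ns <- c(5e3, 2e4, 8e4)
  med_unc <- vapply(seq_along(ns), function(i) {
    ki <- generate_dvk(grid = kernel_grid(9, 1.6), n_primaries = ns[i],
                       n_batches = 5, seed = 100 + i)
    # well-sampled core, so the voxel population is identical across runs
    core <- .radius_grid_mm_test(ki$grid) <= 5
    median(ki$rel_uncertainty[core], na.rm = TRUE)
  }, numeric(1))
  slope <- coef(lm(log(med_unc) ~ log(ns)))[2]
  expect_lt(abs(unname(slope) + 0.5), 0.15)
})

test_that("uncertainty radius queries behave and extrapolate by sqrt(N)", {
  k <- small_kernel()
  u_ctr <- estimate_kernel_uncertainty(k, min(k$grid$voxel_mm) / 2)
  u_all <- estimate_kernel_uncertainty(k, 10)
  expect_lte(u_ctr, u_all)   # max over nested sets is monotone
  expect_equal(estimate_kernel_uncertainty(k, 5, n_primaries = 4 * k$n_primaries),
               estimate_kernel_uncertainty(k, 5) / 2, tolerance = 1e-12)
  expect_error(estimate_kernel_uncertainty(k, -1), "no voxels")
})

test_that("invalid kernel configurations are refused", {
  expect_error(kernel_grid(10), "odd")
  expect_error(kernel_grid(53, c(0, 0.8, 0.8)), "positive")
  expect_error(generate_dvk(n_primaries = 5, n_batches = 10), ">=")
})

test_that("kernel file round trip preserves values and metadata", {
  k <- small_kernel()
  pre <- file.path(withr::local_tempdir(), "kern")
  write_kernel(k, pre)
  k2 <- read_kernel(pre)
  expect_equal(k2$values, k$values, tolerance = 1e-6)
  expect_equal(k2$beta_component, k$beta_component, tolerance = 1e-6)
  expect_identical(k2$grid$shape, k$grid$shape)
  expect_equal(k2$grid$voxel_mm, k$grid$voxel_mm, tolerance = 1e-6)
  expect_equal(k2$n_primaries, k$n_primaries)
})
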