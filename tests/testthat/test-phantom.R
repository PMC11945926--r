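test_that("requested tumor volume is achieved to the voxel", {
  ph <- generate_phantom(phantom_spec(tumor_volume_cm3 = 15, seed = 3))
  # 15 cm^3 at 0.8 mm isotropic voxels: 15000 / 0.512 = 29296.875
  expect_equal(sum(ph$structures$PTV), 29297)
  expect_lt(abs(ph$ptv_volume_cm3 - 15), 0.512 / 1000)
})

test_that("zero heterogeneity gives perfectly uniform enhancement", {
  ph <- generate_phantom(phantom_spec(grid_shape = 48, voxel_mm = 1.6,
                                      tumor_volume_cm3 = 4, heterogeneity = 0,
                                      oars = list(), seed = 2))
  vals <- ph$intensity[ph$structures$PTV]
  expect_equal(length(unique(vals)), 1L)
})

test_that("structure set invariants hold", {
  ph <- generate_phantom(phantom_spec(seed = 9))
  st <- ph$structures
  expect_identical(st$BrainMinusPTV, st$Brain & !st$PTV)
  expect_false(any(st$PTV & !st$Brain))             # PTV inside brain
  for (nm in setdiff(names(st), c("PTV", "Brain", "BrainMinusPTV")))
    expect_false(any(st[[nm]] & st$PTV))            # OARs disjoint from PTV
  expect_true(all(ph$intensity >= 0))
  expect_gt(mean(ph$intensity[st$PTV]), mean(ph$intensity[st$BrainMinusPTV]))
})

test_that("the tumor is one contiguous volume", {
  ph <- small_phantom()
  expect_true(mask_is_connected(ph$structures$PTV))
  sphere <- generate_phantom(phantom_spec(grid_shape = 48, voxel_mm = 1.6,
                                          tumor_volume_cm3 = 4,
                                          tumor_shape = "sphere",
                                          oars = list(), seed = 2))
  expect_true(mask_is_connected(sphere$structures$PTV))
})

test_that("phantom generation is reproducible and fails loudly", {
  s <- phantom_spec(grid_shape = 48, voxel_mm = 1.6, tumor_volume_cm3 = 4,
                    oars = list(), seed = 5)
  expect_identical(generate_phantom(s)$intensity, generate_phantom(s)$intensity)
  expect_error(generate_phantom(phantom_spec(tumor_volume_cm3 = 500)),
               "too large")
  big <- phantom_spec(grid_shape = 48, voxel_mm = 1.6, tumor_volume_cm3 = 30,
                      tumor_centroid_mm = c(-5, -8, -14), tumor_shape = "sphere")
  expect_error(generate_phantom(big), "collides")
})

test_that("cohorts span log-spaced ratios with distinct seeds", {
  base <- phantom_spec(grid_shape = 48, voxel_mm = 1.6, oars = list())
  co <- generate_cohort(n = 5, ratio_range = c(0.01, 0.1), seed = 4,
                        base_spec = base)
  ratios <- vapply(co, `[[`, numeric(1), "ptv_brain_ratio")
  seeds <- vapply(co, function(p) p$spec$seed, numeric(1))
  expect_equal(length(co), 5)
  expect_true(all(diff(ratios) > 0))
  expect_equal(anyDuplicated(seeds), 0)
  # achieved ratios track the requested log-spaced grid
  target <- exp(seq(log(0.01), log(0.1), length.out = 5))
  expect_equal(ratios, target, tolerance = 0.02)
  # reproducibility of the whole cohort
  co2 <- generate_cohort(n = 5, ratio_range = c(0.01, 0.1), seed = 4,
                         base_spec = base)
  expect_identical(co[[3]]$intensity, co2[[3]]$intensity)
  # degenerate cohort and bad ranges
  expect_equal(length(generate_cohort(n = 1, base_spec = base)), 1)
  expect_error(generate_cohort(ratio_range = c(0.1, 0.01)), "increasing")
})
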