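# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small kernel on a coarse grid that still contains the full beta range
small_kernel <- function() fixture("small_kernel",
  generate_dvk(grid = kernel_grid(17, 1.6), n_primaries = 4e4,
               n_batches = 8, seed = 11))

# small phantom matched to the small kernel's voxel size
small_phantom <- function() fixture("small_phantom",
  generate_phantom(phantom_spec(grid_shape = 48, voxel_mm = 1.6,
                                tumor_volume_cm3 = 4, oars = list(),
                                seed = 7)))

# a synthetic "kernel" with arbitrary values, for convolution algebra tests
fake_kernel <- function(values, voxel_mm = 1) {
  grid <- kernel_grid(dim(values), voxel_mm)
  structure(list(values = values, beta_component = values,
                 photon_component = array(0, dim(values)),
                 grid = grid, n_primaries = 1, n_batches = 2, seed = 0),
            class = "dose_kernel")
}

uniform_activity <- function(shape, total = 1000, voxel_mm = 1,
                             T_phys_h = 64) {
  mask <- array(TRUE, shape)
  build_activity_map(array(1, shape), mask, total, T_phys_h, voxel_mm)
}

# voxel-centre radii (mm) for a kernel grid, recomputed independently
.radius_grid_mm_test <- function(grid) {
  ax <- lapply(1:3, function(i)
    (seq_len(grid$shape[i]) - (grid$shape[i] + 1) / 2) * grid$voxel_mm[i])
  sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`))
}
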