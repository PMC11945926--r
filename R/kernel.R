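#' Kernel calculation grid
#'
#' Describes the odd-shaped voxel grid on which the dose voxel kernel is
#' tallied.  The default reproduces the reference configuration: 53 x 53 x 53
#' voxels of 0.8 x 0.8 x 0.78 mm.  When the kernel is destined for
#' convolution with an activity map it must be generated with exactly the
#' activity map's voxel size (use `voxel_mm = c(0.8, 0.8, 0.8)` for the
#' default phantoms); mismatched kernels are refused by [convolve_dose()]
#' rather than resampled.
#'
#' @param shape voxel counts per axis; a scalar is recycled.  Every axis must
#'   be odd so a unique central voxel exists.
#' @param voxel_mm voxel edge lengths in mm per axis; a scalar is recycled.
#' @return object of class `kernel_grid` with fields `shape`, `voxel_mm`,
#'   `center` (1-based index of the central voxel).
#' @examples
#' kernel_grid(53, c(0.8, 0.8, 0.78))
#' @export
kernel_grid <- function(shape = 53, voxel_mm = c(0.8, 0.8, 0.78)) {
  if (length(shape) == 1) shape <- rep(shape, 3)
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1) || any(shape %% 2 == 0))
    stop("'shape' must be three odd positive voxel counts")
  if (length(voxel_mm) != 3 || any(!is.finite(voxel_mm)) || any(voxel_mm <= 0))
    stop("'voxel_mm' must be three positive voxel sizes")
  structure(list(shape = shape, voxel_mm = voxel_mm,
                 center = (shape + 1L) %/% 2L),
            class = "kernel_grid")
}

#' @export
print.kernel_grid <- function(x, ...) {
  cat(sprintf("Kernel grid: %s voxels of %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(format(x$voxel_mm), collapse = " x ")))
  invisible(x)
}

#' Generate the Y-90 dose voxel kernel by Monte Carlo simulation
#'
#' Simulates decays originating uniformly within the central voxel of the
#' grid.  Beta particles are transported along straightened condensed-history
#' tracks using the continuous-slowing-down range--energy relation in
#' unit-density water-equivalent medium ([csda_range_table()]); energy is
#' deposited at segment midpoints and tallied per voxel.  A fixed radiative
#' yield `brems_yield` of the beta energy is diverted to a photon
#' (bremsstrahlung) component, deposited deterministically through an
#' exponentially attenuated isotropic point kernel
#' \eqn{\mu e^{-\mu r}/(4\pi r^2)} with effective attenuation coefficient
#' `mu_photon_cm`.  Primaries are split into `n_batches` equal batches and
#' the per-voxel relative uncertainty is estimated from the batch-to-batch
#' variance of the mean.  Energy escaping the grid (beta and photon) is
#' tallied and reported, not redistributed.
#'
#' @param spectrum a [beta_spectrum()].
#' @param grid a [kernel_grid()].
#' @param n_primaries number of simulated decays; rounded down to a multiple
#'   of `n_batches`.
#' @param n_batches number of uncertainty batches (>= 2).
#' @param seed integer master seed; all batch sampling derives from it.
#' @param brems_yield fraction of beta energy converted to photons
#'   (radiative yield; default 0.008 for the Y-90 spectrum in water).
#' @param mu_photon_cm effective photon attenuation coefficient in water,
#'   1/cm.
#' @param density_g_cm3 medium density (water-equivalent default 1).
#' @param step_mm condensed-history step length; defaults to a quarter of the
#'   smallest voxel edge.
#' @param cutoff_MeV electrons below this kinetic energy deposit locally.
#' @return object of class `dose_kernel` with fields
#'   \describe{
#'     \item{values}{total dose per unit cumulated activity,
#'       mGy MBq^-1 s^-1, `values = beta_component + photon_component`.}
#'     \item{beta_component, photon_component}{the two components, same
#'       units.}
#'     \item{rel_uncertainty}{per-voxel relative standard error (from the
#'       stochastic beta component; `NA` where the value is zero).}
#'     \item{energy_MeV_per_decay}{bookkeeping: beta deposited, photon
#'       deposited, beta escaped, photon escaped, per decay.}
#'   }
#' @examples
#' \donttest{
#' k <- generate_dvk(n_primaries = 2e4, grid = kernel_grid(21, 1.6), seed = 1)
#' k
#' }
#' @export
generate_dvk <- function(spectrum = beta_spectrum(), grid = kernel_grid(),
                         n_primaries = 1e6, n_batches = 10, seed = 1,
                         brems_yield = 0.008, mu_photon_cm = 0.12,
                         density_g_cm3 = 1, step_mm = NULL,
                         cutoff_MeV = 0.01) {
  .validate_spectrum(spectrum)
  if (!inherits(grid, "kernel_grid")) stop("'grid' must be a kernel_grid")
  .check_scalar(density_g_cm3, "density_g_cm3")
  if (n_batches < 2) stop("'n_batches' must be at least 2")
  if (n_primaries < n_batches) stop("'n_primaries' must be >= 'n_batches'")
  m <- floor(n_primaries / n_batches)
  if (m < 1) stop("zero primaries per batch")
  n_primaries <- m * n_batches

  vox_cm <- grid$voxel_mm / 10
  tab <- csda_range_table(E_max_MeV = max(3, 1.2 * spectrum$endpoint_MeV))
  step_cm <- (step_mm %||% (min(grid$voxel_mm) / 4)) / 10

  set.seed(seed)
  nv <- prod(grid$shape)
  sum_k <- numeric(nv)
  sum_k2 <- numeric(nv)
  escaped_beta <- 0
  sum_E <- 0
  for (b in seq_len(n_batches)) {
    E0 <- sample_beta_energies(spectrum, m)
    pos <- cbind(runif(m, -0.5, 0.5) * vox_cm[1],
                 runif(m, -0.5, 0.5) * vox_cm[2],
                 runif(m, -0.5, 0.5) * vox_cm[3])
    cost <- runif(m, -1, 1)
    phi <- runif(m, 0, 2 * pi)
    sint <- sqrt(pmax(0, 1 - cost^2))
    dir <- cbind(sint * cos(phi), sint * sin(phi), cost)
    res <- cpp_transport_beta(E0, pos, dir, grid$shape, vox_cm,
                              tab$energy_MeV, tab$range_cm,
                              cutoff_MeV, step_cm)
    kb <- res$deposit * (1 - brems_yield) / m   # MeV per decay, this batch
    sum_k <- sum_k + kb
    sum_k2 <- sum_k2 + kb^2
    escaped_beta <- escaped_beta + res$escaped * (1 - brems_yield) / m
    sum_E <- sum_E + sum(E0)
  }
  beta_E <- array(sum_k / n_batches, grid$shape)   # MeV per decay per voxel
  escaped_beta <- escaped_beta / n_batches
  mean_E_sampled <- sum_E / n_primaries

  # batch standard error of the mean, per voxel
  var_b <- pmax(0, sum_k2 / n_batches - (sum_k / n_batches)^2) *
    n_batches / (n_batches - 1)
  se_E <- array(sqrt(var_b / n_batches), grid$shape)

  # deterministic attenuated point-kernel photon tail
  ph <- .photon_point_kernel(grid, mu_photon_cm)
  E_photon_total <- brems_yield * mean_E_sampled
  photon_E <- E_photon_total * ph$weight
  escaped_photon <- E_photon_total * (1 - sum(ph$weight))

  beta_dvk <- energy_to_dose_rate_units(beta_E, grid, density_g_cm3)
  photon_dvk <- energy_to_dose_rate_units(photon_E, grid, density_g_cm3)
  se_dvk <- energy_to_dose_rate_units(se_E, grid, density_g_cm3)
  values <- beta_dvk + photon_dvk
  rel_unc <- ifelse(values > 0, se_dvk / values, NA_real_)

  structure(list(
    values = values,
    beta_component = beta_dvk,
    photon_component = photon_dvk,
    rel_uncertainty = array(rel_unc, grid$shape),
    se = se_dvk,
    grid = grid,
    n_primaries = n_primaries,
    n_batches = n_batches,
    seed = seed,
    density_g_cm3 = density_g_cm3,
    brems_yield = brems_yield,
    mu_photon_cm = mu_photon_cm,
    spectrum_label = spectrum$label,
    spectrum_mean_MeV = spectrum$mean_MeV,
    sampled_mean_MeV = mean_E_sampled,
    energy_MeV_per_decay = c(
      beta_deposited = sum(beta_E),
      photon_deposited = sum(photon_E),
      beta_escaped = escaped_beta,
      photon_escaped = escaped_photon)
  ), class = "dose_kernel")
}

# voxelised attenuated isotropic point kernel: fraction of emitted photon
# energy absorbed per voxel, mu*exp(-mu r)/(4 pi r^2) * voxel volume, with the
# central voxel integrated over its volume-equivalent sphere
.photon_point_kernel <- function(grid, mu_cm) {
  r_cm <- .radius_grid_mm(grid$shape, grid$voxel_mm) / 10
  vol_cm3 <- prod(grid$voxel_mm) / 1000
  w <- mu_cm * exp(-mu_cm * r_cm) / (4 * pi * r_cm^2) * vol_cm3
  r_eq <- (3 * vol_cm3 / (4 * pi))^(1 / 3)
  w[grid$center[1], grid$center[2], grid$center[3]] <- 1 - exp(-mu_cm * r_eq)
  list(weight = w)
}

#' Convert an energy-deposition map to dose per unit cumulated activity
#'
#' Per voxel: dose = energy x (J per MeV) / (voxel mass), expressed per
#' 10^6 decays (1 MBq s) in mGy, i.e. the reference kernel unit
#' mGy MBq^-1 s^-1.
#'
#' @param energy_map array of deposited energy, MeV per voxel per decay.
#' @param grid the [kernel_grid()] the map lives on.
#' @param density_g_cm3 medium density.
#' @return array of the same shape, mGy MBq^-1 s^-1.
#' @examples
#' g <- kernel_grid(1, c(0.8, 0.8, 0.78))
#' energy_to_dose_rate_units(array(1, c(1, 1, 1)), g)  # about 320.9
#' @export
energy_to_dose_rate_units <- function(energy_map, grid, density_g_cm3 = 1) {
  .check_scalar(density_g_cm3, "density_g_cm3")
  vol_cm3 <- prod(grid$voxel_mm) / 1000
  if (vol_cm3 <= 0) stop("non-positive voxel volume")
  mass_kg <- vol_cm3 * density_g_cm3 / 1000
  # Gy/decay = E * J_per_MeV / mass; * 1e6 decay/(MBq s) * 1e3 mGy/Gy
  energy_map * (.MeV_J / mass_kg * 1e9)
}

#' Maximum Monte Carlo uncertainty within a radius of the kernel centre
#'
#' Returns the maximum per-voxel relative standard error among voxels whose
#' centres lie within `radius_mm` of the central voxel.  With `n_primaries`
#' the estimate is extrapolated by the 1/sqrt(N) Monte Carlo scaling law to a
#' different number of primaries.
#'
#' @param kernel a [generate_dvk()] result.
#' @param radius_mm radius of the evaluation ball, mm.
#' @param n_primaries optional primary count to extrapolate to.
#' @return maximum relative uncertainty (fraction).
#' @export
estimate_kernel_uncertainty <- function(kernel, radius_mm, n_primaries = NULL) {
  stopifnot(inherits(kernel, "dose_kernel"))
  r <- .radius_grid_mm(kernel$grid$shape, kernel$grid$voxel_mm)
  sel <- r <= radius_mm & is.finite(kernel$rel_uncertainty)
  if (!any(sel)) stop("radius smaller than one voxel: no voxels selected")
  u <- max(kernel$rel_uncertainty[sel])
  if (!is.null(n_primaries))
    u <- u * sqrt(kernel$n_primaries / n_primaries)
  u
}

#' Spherically averaged radial profile of a kernel component
#'
#' Averages voxel values in concentric shells about the central voxel.
#'
#' @param x 3-D array (e.g. `kernel$beta_component`).
#' @param grid the matching [kernel_grid()].
#' @param dr_mm shell thickness; defaults to the smallest voxel edge.
#' @return data.frame with shell mid-radius `r_mm`, shell mean `mean`,
#'   shell sum `total` and voxel count `n`.
#' @export
radial_profile <- function(x, grid, dr_mm = NULL) {
  dr <- dr_mm %||% min(grid$voxel_mm)
  r <- .radius_grid_mm(grid$shape, grid$voxel_mm)
  bin <- as.integer(floor(r / dr)) + 1L
  nb <- max(bin)
  n <- tabulate(bin, nb)
  s <- as.numeric(rowsum(as.numeric(x), bin, reorder = TRUE))
  keep <- n > 0
  data.frame(r_mm = (which(keep) - 0.5) * dr,
             mean = s / n[keep],
             total = s,
             n = n[keep],
             row.names = NULL)
}

#' Radius enclosing a given fraction of the beta energy
#'
#' Sorts voxels by distance from the kernel centre and reports the smallest
#' radius whose enclosed cumulative beta-component energy reaches `fraction`
#' of the total (the practical beta range for `fraction = 0.999`).
#'
#' @param kernel a [generate_dvk()] result.
#' @param fraction enclosed energy fraction in (0, 1).
#' @return radius in mm.
#' @export
beta_range <- function(kernel, fraction = 0.999) {
  stopifnot(inherits(kernel, "dose_kernel"), fraction > 0, fraction < 1)
  r <- as.numeric(.radius_grid_mm(kernel$grid$shape, kernel$grid$voxel_mm))
  v <- as.numeric(kernel$beta_component)
  o <- order(r)
  cf <- cumsum(v[o]) / sum(v)
  r[o][which(cf >= fraction)[1]]
}

#' Radius up to which the beta component dominates the photon component
#'
#' Compares spherically averaged radial profiles of the beta and photon
#' components and returns the outer edge of the last contiguous shell (from
#' the centre) in which the beta profile exceeds the photon profile.
#'
#' @param kernel a [generate_dvk()] result.
#' @param dr_mm shell thickness for the radial profiles.
#' @return crossover radius in mm.
#' @export
beta_dominance_radius <- function(kernel, dr_mm = NULL) {
  stopifnot(inherits(kernel, "dose_kernel"))
  pb <- radial_profile(kernel$beta_component, kernel$grid, dr_mm)
  pp <- radial_profile(kernel$photon_component, kernel$grid, dr_mm)
  m <- merge(pb, pp, by = "r_mm", suffixes = c("_beta", "_photon"))
  m <- m[order(m$r_mm), ]
  ok <- m$mean_beta > m$mean_photon
  if (!ok[1]) return(0)
  first_cross <- which(!ok)[1]
  last <- if (is.na(first_cross)) nrow(m) else first_cross - 1L
  dr <- dr_mm %||% min(kernel$grid$voxel_mm)
  m$r_mm[last] + dr / 2
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat(sprintf("Y-90 dose voxel kernel (%s)\n", x$spectrum_label))
  print(x$grid)
  cat(sprintf("  %s primaries in %d batches, seed %d\n",
              format(x$n_primaries, big.mark = ","), x$n_batches, x$seed))
  cat(sprintf("  central value: %.4g mGy/(MBq s); beta energy in grid: %.4f MeV/decay (escaped %.2e)\n",
              x$values[x$grid$center[1], x$grid$center[2], x$grid$center[3]],
              x$energy_MeV_per_decay["beta_deposited"],
              x$energy_MeV_per_decay["beta_escaped"]))
  cat(sprintf("  practical beta range (99.9%% energy): %.1f mm; beta dominates to %.1f mm\n",
              beta_range(x), beta_dominance_radius(x)))
  invisible(x)
}

#' @export
plot.dose_kernel <- function(x, ...) {
  pb <- radial_profile(x$beta_component, x$grid)
  pp <- radial_profile(x$photon_component, x$grid)
  plot(pb$r_mm, pb$mean, log = "y", type = "l", col = "firebrick",
       xlab = "radius (mm)", ylab = "dose per cumulated activity (mGy/MBq/s)",
       main = "Dose voxel kernel radial profile", ...)
  lines(pp$r_mm, pp$mean, col = "steelblue")
  legend("topright", c("beta", "photon"), lty = 1,
         col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}
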