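#' Electron collision stopping power in water
#'
#' Berger--Seltzer (Bethe) collision stopping power for electrons in liquid
#' water: mean excitation energy I = 75 eV, Z/A = 0.55509, no density-effect
#' correction (negligible below ~2 MeV at unit density).  Radiative losses
#' are not included here; the kernel generator accounts for them through a
#' fixed radiative-yield fraction.
#'
#' @param E_MeV electron kinetic energy, MeV (vectorised).
#' @return stopping power in MeV cm^2/g.
#' @examples
#' electron_stopping_power(1)  # about 1.87 MeV cm^2/g
#' @export
electron_stopping_power <- function(E_MeV) {
  I <- 75e-6   # MeV
  ZA <- 0.55509
  tau <- E_MeV / .me_MeV
  beta2 <- 1 - 1 / (1 + tau)^2
  Fm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  0.153536 * ZA / beta2 * (log(tau^2 * (tau + 2) / 2 / (I / .me_MeV)^2) + Fm)
}

#' Continuous-slowing-down range--energy table for electrons in water
#'
#' Integrates the reciprocal collision stopping power on a logarithmic energy
#' grid to give the CSDA range at unit density.  Used by the condensed-history
#' transport to convert path length travelled into residual energy.
#'
#' @param E_max_MeV upper end of the table (should exceed the spectrum
#'   endpoint).
#' @param E_min_MeV lower end; electrons below this are considered stopped.
#' @param n number of grid points.
#' @return list with increasing vectors `energy_MeV` and `range_cm`.
#' @examples
#' tab <- csda_range_table()
#' approx(tab$energy_MeV, tab$range_cm, 2.2801)$y  # about 1.1 cm
#' @export
csda_range_table <- function(E_max_MeV = 3, E_min_MeV = 1e-3, n = 600) {
  E <- exp(seq(log(E_min_MeV), log(E_max_MeV), length.out = n))
  invS <- 1 / electron_stopping_power(E)
  R <- .cumtrapz(E, invS)
  # drop the zero-range head so both columns are strictly positive
  # (the transport interpolates the table in log-log space)
  list(energy_MeV = E[-1], range_cm = R[-1])
}
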