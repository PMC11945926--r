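#' Specification of the external-beam surrogate plan
#'
#' Parametric stand-in for an optimised arc-therapy comparator plan: uniform
#' coverage of the PTV at the prescription (within a small homogeneity
#' band), a Gaussian penumbra falloff outside the target, and a low
#' out-of-field base dose representing beam entry/exit through the brain.
#'
#' @param prescription_Gy prescribed total dose to the PTV.
#' @param n_fractions number of fractions.
#' @param homogeneity half-width of the in-target dose band, as a fraction
#'   of the prescription.
#' @param penumbra_sigma_mm Gaussian penumbra standard deviation.
#' @param base_fraction out-of-field dose floor as a fraction of the
#'   prescription.
#' @return object of class `vmat_plan_spec`.
#' @export
vmat_plan_spec <- function(prescription_Gy = 60, n_fractions = 30,
                           homogeneity = 0.02, penumbra_sigma_mm = 6,
                           base_fraction = 0.10) {
  .check_scalar(prescription_Gy, "prescription_Gy")
  .check_scalar(penumbra_sigma_mm, "penumbra_sigma_mm")
  if (n_fractions < 1) stop("'n_fractions' must be >= 1")
  structure(list(prescription_Gy = prescription_Gy,
                 n_fractions = as.integer(n_fractions),
                 homogeneity = homogeneity,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 base_fraction = base_fraction),
            class = "vmat_plan_spec")
}

#' Generate the external-beam-like comparator dose map
#'
#' Builds a dose distribution from the PTV mask alone: the PTV indicator is
#' blurred with an isotropic Gaussian of `penumbra_sigma_mm`, compressed so
#' that the bulk of the PTV sits at the prescription, floored at the
#' out-of-field base level, given a small seeded in-target homogeneity
#' ripple, and finally rescaled so the mean PTV dose equals the prescription
#' exactly.  No organ-at-risk sparing is modelled.
#'
#' @param structures a `structure_set` with a non-empty `PTV` mask.
#' @param spec a [vmat_plan_spec()].
#' @param seed integer seed for the homogeneity ripple.
#' @return a `dose_map` with `source = "vmat_surrogate"` and the plan's
#'   fractionation.
#' @export
generate_vmat_like_dose <- function(structures, spec = vmat_plan_spec(),
                                    seed = 1) {
  stopifnot(inherits(spec, "vmat_plan_spec"))
  ptv <- structures$PTV
  if (is.null(ptv) || !any(ptv)) stop("empty PTV")
  voxel_mm <- attr(structures, "voxel_mm")
  sigma_vox <- rep(spec$penumbra_sigma_mm, 3) / voxel_mm
  G <- .gaussian_blur3d(ptv * 1, sigma_vox)
  # shoulder level: all but the deepest-penumbra fringe of the PTV reaches it
  q <- quantile(G[ptv], 0.05, names = FALSE)
  S <- pmin(G / q, 1)
  rx <- spec$prescription_Gy
  dose <- rx * (spec$base_fraction + (1 - spec$base_fraction) * S)
  set.seed(seed)
  ripple <- 1 + runif(sum(ptv), -spec$homogeneity, spec$homogeneity)
  dose[ptv] <- dose[ptv] * ripple
  dose <- dose * (rx / mean(dose[ptv]))
  structure(list(voxel_dose = dose, voxel_mm = voxel_mm,
                 source = "vmat_surrogate",
                 n_fractions = spec$n_fractions,
                 prescription_Gy = rx,
                 total_activity_MBq = NULL, lost_fraction = 0),
            class = "dose_map")
}
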