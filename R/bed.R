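#' Radiobiological parameters for BED calculation
#'
#' Linear-quadratic model parameters.  Defaults follow standard brain
#' radiotherapy practice: tumor alpha/beta = 10 Gy with sublethal-damage
#' repair half-time 1.5 h; normal tissue alpha/beta = 2.5 Gy with 2.5 h; the
#' Y-90 physical half-life is 64 h.  Derived rates are
#' \eqn{\mu = \ln 2 / T_{rep}} and \eqn{\lambda = \ln 2 / T_{phys}} (1/h).
#'
#' @param tissue `"tumor"` or `"normal"`; sets the defaults.
#' @param alpha_beta_Gy alpha/beta ratio, Gy.
#' @param T_rep_h repair half-time of sublethal damage, h.
#' @param T_phys_h physical half-life of the radionuclide, h.
#' @return object of class `bed_params` with fields `alpha_beta_Gy`,
#'   `T_rep_h`, `T_phys_h`, `mu_h`, `lambda_h`, `tissue`.
#' @examples
#' bed_params("tumor")
#' bed_params("normal")
#' @export
bed_params <- function(tissue = c("tumor", "normal"), alpha_beta_Gy = NULL,
                       T_rep_h = NULL, T_phys_h = 64) {
  tissue <- match.arg(tissue)
  alpha_beta_Gy <- alpha_beta_Gy %||% switch(tissue, tumor = 10, normal = 2.5)
  T_rep_h <- T_rep_h %||% switch(tissue, tumor = 1.5, normal = 2.5)
  .check_scalar(alpha_beta_Gy, "alpha_beta_Gy")
  .check_scalar(T_rep_h, "T_rep_h")
  .check_scalar(T_phys_h, "T_phys_h")
  structure(list(alpha_beta_Gy = alpha_beta_Gy, T_rep_h = T_rep_h,
                 T_phys_h = T_phys_h,
                 mu_h = log(2) / T_rep_h, lambda_h = log(2) / T_phys_h,
                 tissue = tissue),
            class = "bed_params")
}

#' @export
print.bed_params <- function(x, ...) {
  cat(sprintf("BED parameters (%s): alpha/beta = %.2f Gy, Trep = %.2f h, Tphys = %.1f h\n",
              x$tissue, x$alpha_beta_Gy, x$T_rep_h, x$T_phys_h))
  invisible(x)
}

#' Biologically effective dose of a fractionated external-beam course
#'
#' \deqn{BED = D \,\bigl(1 + d / (\alpha/\beta)\bigr)} for total dose `D`
#' delivered in fractions of size `d` (full sublethal-damage repair between
#' fractions).
#'
#' @param D total dose, Gy (vectorised).
#' @param d dose per fraction, Gy (scalar or vector recycled against `D`).
#' @param params a [bed_params()] object.
#' @return BED in Gy.
#' @examples
#' bed_ebrt(60, 2, bed_params("tumor"))   # 72
#' bed_ebrt(60, 2, bed_params("normal"))  # 108
#' @export
bed_ebrt <- function(D, d, params) {
  stopifnot(inherits(params, "bed_params"))
  if (any(D < 0)) stop("'D' must be non-negative")
  if (any(d < 0)) stop("'d' must be non-negative")
  D * (1 + d / params$alpha_beta_Gy)
}

#' Biologically effective dose of a Y-90 permanent implant
#'
#' Single-administration continuously decaying irradiation with sublethal-
#' damage repair:
#' \deqn{BED = D\,\Bigl(1 + \frac{\lambda}{\lambda+\mu}\,
#'   \frac{D}{\alpha/\beta}\Bigr)}
#' with \eqn{\lambda = \ln 2 / T_{phys}} and \eqn{\mu = \ln 2 / T_{rep}}.
#' In the instant-repair limit (\eqn{T_{rep}\to 0}) the BED reduces to the
#' physical dose.
#'
#' @param D total physical dose, Gy (vectorised).
#' @param params a [bed_params()] object.
#' @return BED in Gy.
#' @examples
#' bed_y90(120, bed_params("tumor"))  # about 152.97
#' @export
bed_y90 <- function(D, params) {
  stopifnot(inherits(params, "bed_params"))
  if (any(D < 0)) stop("'D' must be non-negative")
  g <- params$lambda_h / (params$lambda_h + params$mu_h)
  D * (1 + g * D / params$alpha_beta_Gy)
}

#' Voxelwise BED map for a dose distribution
#'
#' Applies [bed_y90()] (for convolution dose maps, single-administration
#' regime) or [bed_ebrt()] (for the external-beam surrogate, with per-voxel
#' fraction size `d = D / n_fractions`) voxel by voxel, using tumor
#' parameters inside the PTV and normal-tissue parameters elsewhere.
#'
#' @param dose a `dose_map`.
#' @param structures a `structure_set` containing a `PTV` mask of the dose
#'   map's shape.
#' @param tumor_params,normal_params [bed_params()] objects.
#' @return 3-D array of BED, Gy.
#' @export
bed_map <- function(dose, structures,
                    tumor_params = bed_params("tumor"),
                    normal_params = bed_params("normal")) {
  stopifnot(inherits(dose, "dose_map"))
  ptv <- structures$PTV
  if (is.null(ptv) || !identical(dim(ptv), dim(dose$voxel_dose)))
    stop("structures must carry a PTV mask matching the dose map")
  D <- dose$voxel_dose
  out <- array(0, dim(D))
  if (dose$source == "vmat_surrogate") {
    nf <- dose$n_fractions
    out[ptv] <- bed_ebrt(D[ptv], D[ptv] / nf, tumor_params)
    out[!ptv] <- bed_ebrt(D[!ptv], D[!ptv] / nf, normal_params)
  } else {
    out[ptv] <- bed_y90(D[ptv], tumor_params)
    out[!ptv] <- bed_y90(D[!ptv], normal_params)
  }
  out
}
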