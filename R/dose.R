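#' Absorbed dose by convolution of cumulated activity with the kernel
#'
#' Evaluates the voxel dosimetry sum
#' \deqn{D(x,y,z) = \frac{1}{\lambda}\sum_{x'}\sum_{y'}\sum_{z'}
#'   A(x',y',z')\,DVK(x-x', y-y', z-z'),}
#' i.e. the discrete linear convolution of the per-voxel cumulated activity
#' \eqn{A/\lambda} with the dose voxel kernel, computed in the frequency
#' domain with zero padding (no circular wrap-around) and double-precision
#' accumulation.  The kernel must have been generated on exactly the
#' activity map's voxel size; a mismatched kernel is refused rather than
#' resampled.  Dose deposited outside the image grid is discarded but
#' tallied in `lost_fraction`.
#'
#' @param activity a [build_activity_map()] result.
#' @param kernel a [generate_dvk()] result on the same voxel size.
#' @return object of class `dose_map`: `voxel_dose` (Gy), `voxel_mm`,
#'   `source = "convolution"`, `n_fractions = 1`, `total_activity_MBq`,
#'   `lost_fraction` (fraction of kernel-predicted dose falling outside the
#'   grid).
#' @export
convolve_dose <- function(activity, kernel) {
  stopifnot(inherits(activity, "activity_map"), inherits(kernel, "dose_kernel"))
  if (any(abs(activity$voxel_mm - kernel$grid$voxel_mm) > 1e-6))
    stop("kernel voxel size does not match the activity map; ",
         "regenerate the kernel on the map's grid (kernels are not resampled)")
  if (any(!is.finite(activity$voxel_activity)) || any(!is.finite(kernel$values)))
    stop("non-finite values in inputs")
  atil <- cumulated_activity(activity)                 # MBq s
  dose_mGy <- .convolve3d(atil, kernel$values)         # mGy
  expected <- sum(atil) * sum(kernel$values)
  lost <- max(0, 1 - sum(dose_mGy) / expected)
  structure(list(voxel_dose = dose_mGy / 1000,
                 voxel_mm = activity$voxel_mm,
                 source = "convolution", n_fractions = 1L,
                 total_activity_MBq = activity$total_activity_MBq,
                 lost_fraction = lost),
            class = "dose_map")
}

#' Rescale a physical dose map to a different administered activity
#'
#' Physical dose from the convolution is exactly linear in the administered
#' activity; this returns the same map scaled to `activity_MBq`.
#'
#' @param map a convolution [convolve_dose()] dose map.
#' @param activity_MBq new administered activity.
#' @return a `dose_map` at the new activity.
#' @export
rescale_dose <- function(map, activity_MBq) {
  stopifnot(inherits(map, "dose_map"))
  if (map$source != "convolution")
    stop("only convolution dose maps scale linearly with activity")
  s <- activity_MBq / map$total_activity_MBq
  map$voxel_dose <- map$voxel_dose * s
  map$total_activity_MBq <- activity_MBq
  map
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("Dose map (%s): %s voxels, max %.2f Gy, mean %.3f Gy\n",
              x$source, paste(dim(x$voxel_dose), collapse = "x"),
              max(x$voxel_dose), mean(x$voxel_dose)))
  if (!is.null(x$total_activity_MBq) && x$source == "convolution")
    cat(sprintf("  administered activity: %.1f MBq; dose lost outside grid: %.2f%%\n",
                x$total_activity_MBq, 100 * x$lost_fraction))
  invisible(x)
}
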