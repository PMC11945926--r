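#' Map image intensity to a voxel activity distribution
#'
#' Implements the central surrogate assumption of the pipeline: the relative
#' contrast-enhanced intensity of each voxel inside the volume of interest is
#' proportional to the local carrier (and hence Y-90) concentration.  The
#' administered activity is allocated proportionally,
#' \eqn{a_i = A \, I_i / \sum_{VOI} I_j}, with activity exactly zero outside
#' the VOI.  Negative intensities (possible after preprocessing) are clipped
#' to zero before normalisation.
#'
#' @param intensity 3-D intensity array.
#' @param voi_mask logical array of the same shape (the PTV).
#' @param total_activity_MBq administered activity to distribute, MBq.
#' @param T_phys_h physical half-life, h (Y-90: 64 h).
#' @param voxel_mm voxel edge lengths, mm (scalar recycled).
#' @return object of class `activity_map`: `voxel_activity` (MBq per voxel),
#'   `total_activity_MBq`, `decay_constant_h` (\eqn{\lambda = \ln 2 / T_{phys}}),
#'   `voxel_mm`.
#' @examples
#' a <- array(0, c(3, 3, 3)); m <- array(FALSE, c(3, 3, 3))
#' a[1:3, 2, 2] <- c(1, 2, 5); m[1:3, 2, 2] <- TRUE
#' am <- build_activity_map(a, m, total_activity_MBq = 800)
#' am$voxel_activity[1:3, 2, 2]  # 100 200 500
#' @export
build_activity_map <- function(intensity, voi_mask, total_activity_MBq = 1000,
                               T_phys_h = 64, voxel_mm = 0.8) {
  if (!identical(dim(intensity), dim(voi_mask)))
    stop("intensity and mask shapes differ")
  if (!any(voi_mask)) stop("empty VOI")
  .check_scalar(total_activity_MBq, "total_activity_MBq")
  .check_scalar(T_phys_h, "T_phys_h")
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  w <- pmax(as.numeric(intensity[voi_mask]), 0)
  if (sum(w) <= 0)
    stop("all-zero intensity in VOI: activity normalisation undefined")
  act <- array(0, dim(intensity))
  act[voi_mask] <- total_activity_MBq * w / sum(w)
  structure(list(voxel_activity = act,
                 total_activity_MBq = total_activity_MBq,
                 decay_constant_h = log(2) / T_phys_h,
                 T_phys_h = T_phys_h,
                 voxel_mm = voxel_mm),
            class = "activity_map")
}

#' Cumulated activity under the permanent-implant assumption
#'
#' Time-integrates each voxel's activity assuming physical decay only (the
#' carrier stays fixed at the injection site for the lifetime of the
#' radionuclide), giving \eqn{\tilde a = a / \lambda} with \eqn{\lambda} in
#' 1/s.
#'
#' @param map an [build_activity_map()] result.
#' @return 3-D array of cumulated activity, MBq s.
#' @examples
#' a <- array(FALSE, c(1,1,1)); a[1] <- TRUE
#' am <- build_activity_map(array(1, c(1,1,1)), a, 1, T_phys_h = 64)
#' cumulated_activity(am)  # 64*3600/log(2) ~ 3.324e5 MBq s
#' @export
cumulated_activity <- function(map) {
  stopifnot(inherits(map, "activity_map"))
  lambda_s <- map$decay_constant_h / 3600
  if (lambda_s <= 0) stop("non-positive decay constant")
  map$voxel_activity / lambda_s
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("Activity map: %.1f MBq over %d voxels (T1/2 = %.1f h)\n",
              x$total_activity_MBq, sum(x$voxel_activity > 0), x$T_phys_h))
  invisible(x)
}
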