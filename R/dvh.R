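#' Cumulative dose-volume histogram of a structure
#'
#' Fraction of the structure volume receiving at least each dose level, on a
#' regular dose grid.  The curve starts at 1 at zero dose, is non-increasing
#' and reaches 0 beyond the maximum dose.
#'
#' @param dose a `dose_map` or a 3-D dose array (Gy).
#' @param mask logical array selecting the structure voxels.
#' @param bin_Gy dose bin width (default 0.1 Gy).
#' @param structure optional structure name carried into the result.
#' @return object of class `dvh`: `dose_Gy` (bin edges), `volume_fraction`,
#'   `structure`, `n_voxels`.
#' @export
compute_dvh <- function(dose, mask, bin_Gy = 0.1, structure = "structure") {
  d <- if (inherits(dose, "dose_map")) dose$voxel_dose else dose
  if (!identical(dim(d), dim(mask))) stop("dose and mask shapes differ")
  if (!any(mask)) stop("empty mask")
  .check_scalar(bin_Gy, "bin_Gy")
  dv <- sort(as.numeric(d[mask]))
  edges <- seq(0, max(dv) + bin_Gy, by = bin_Gy)
  # fraction of voxels at or above each edge (ties count as covered)
  frac <- (length(dv) - findInterval(edges, dv, left.open = TRUE)) / length(dv)
  structure(list(dose_Gy = edges, volume_fraction = frac,
                 structure = structure, n_voxels = length(dv)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("DVH for %s (%d voxels), dose range 0-%.1f Gy\n",
              x$structure, x$n_voxels, max(x$dose_Gy)))
  for (p in c(0.95, 0.5, 0.05))
    cat(sprintf("  D%.0f%% = %.2f Gy\n", 100 * p, dose_at_volume(x, p)))
  invisible(x)
}

#' @export
plot.dvh <- function(x, add = FALSE, col = "black", ...) {
  if (add) lines(x$dose_Gy, 100 * x$volume_fraction, col = col, ...)
  else plot(x$dose_Gy, 100 * x$volume_fraction, type = "l", col = col,
            xlab = "dose (Gy)", ylab = "volume (%)", ylim = c(0, 100), ...)
  invisible(x)
}

#' Dose covering a given volume fraction (D_p)
#'
#' The largest dose level received by at least fraction `p` of the
#' structure.  For a `dvh` the value is read off the binned curve with
#' linear interpolation between bin edges; for a raw vector of voxel doses
#' the exact order statistic is returned (this form commutes exactly with
#' rescaling and is used by the activity prescription).
#'
#' @param x a `dvh` object or a numeric vector of voxel doses.
#' @param p volume fraction in (0, 1].
#' @return dose in Gy.
#' @examples
#' dose_at_volume(c(10, 30), 0.5)   # 30
#' dose_at_volume(c(10, 30), 1)     # 10
#' @export
dose_at_volume <- function(x, p) UseMethod("dose_at_volume")

#' @export
dose_at_volume.dvh <- function(x, p) {
  if (p <= 0 || p > 1) stop("'p' must be in (0, 1]")
  f <- x$volume_fraction
  i <- max(which(f >= p))
  if (f[i] == p || i == length(f)) return(x$dose_Gy[i])
  x$dose_Gy[i] + (f[i] - p) / (f[i] - f[i + 1]) *
    (x$dose_Gy[i + 1] - x$dose_Gy[i])
}

#' @export
dose_at_volume.numeric <- function(x, p) {
  if (p <= 0 || p > 1) stop("'p' must be in (0, 1]")
  s <- sort(x, decreasing = TRUE)
  s[ceiling(p * length(s))]
}

#' Activity reaching a dose-coverage prescription
#'
#' Physical dose is exactly linear in administered activity, so the activity
#' delivering `prescription` Gy to at least fraction `coverage` of the PTV
#' is the nominal activity rescaled by prescription / D_p at nominal:
#' \eqn{A_p = A_0 \, D_{rx} / D_p(A_0)}.
#'
#' @param dose dose map (or 3-D array, Gy) simulated at the nominal
#'   activity.
#' @param ptv_mask logical PTV mask.
#' @param prescription_Gy prescribed dose level (default 60 Gy).
#' @param coverage target covered volume fraction (e.g. 0.95 or 0.99).
#' @param nominal_activity_MBq the activity the dose map was simulated at
#'   (taken from the dose map when available; default 1000 MBq = 1 GBq).
#' @return prescribed activity in MBq.
#' @export
prescribe_activity <- function(dose, ptv_mask, prescription_Gy = 60,
                               coverage = 0.95, nominal_activity_MBq = NULL) {
  d <- if (inherits(dose, "dose_map")) dose$voxel_dose else dose
  A0 <- nominal_activity_MBq %||%
    (if (inherits(dose, "dose_map")) dose$total_activity_MBq else NULL) %||% 1000
  if (!any(ptv_mask)) stop("empty PTV mask")
  Dp <- dose_at_volume(as.numeric(d[ptv_mask]), coverage)
  if (Dp <= 0) stop("zero PTV coverage at nominal activity")
  A0 * prescription_Gy / Dp
}

#' Activity matching a target biologically effective dose
#'
#' Finds the administered activity at which a chosen PTV statistic of the
#' Y-90 BED equals `target_bed_Gy` -- typically the mean PTV BED of the
#' external-beam comparator, making the two plans iso-effective in the
#' target.  Because [bed_y90()] is strictly increasing in dose and physical
#' dose is linear in activity, the root is unique; it is found by bracket
#' expansion and root solving on the activity scale factor, to a relative
#' BED tolerance of 1e-6.
#'
#' @param dose dose map (or array) at the nominal activity.
#' @param ptv_mask logical PTV mask.
#' @param target_bed_Gy target value of the matching statistic.
#' @param params tumor [bed_params()].
#' @param statistic `"mean"` (mean PTV BED) or `"D95"` (BED at the D95
#'   level).
#' @param nominal_activity_MBq activity of the supplied dose map.
#' @param max_scale largest activity scale factor explored during
#'   bracketing.
#' @return matched activity in MBq.
#' @export
prescribe_activity_bed_matched <- function(dose, ptv_mask, target_bed_Gy,
                                           params = bed_params("tumor"),
                                           statistic = c("mean", "D95"),
                                           nominal_activity_MBq = NULL,
                                           max_scale = 1e6) {
  statistic <- match.arg(statistic)
  d <- if (inherits(dose, "dose_map")) dose$voxel_dose else dose
  A0 <- nominal_activity_MBq %||%
    (if (inherits(dose, "dose_map")) dose$total_activity_MBq else NULL) %||% 1000
  .check_scalar(target_bed_Gy, "target_bed_Gy")
  d0 <- as.numeric(d[ptv_mask])
  if (!length(d0) || max(d0) <= 0) stop("zero PTV dose at nominal activity")
  stat_fun <- switch(statistic,
                     mean = function(x) mean(x),
                     D95 = function(x) dose_at_volume(x, 0.95))
  f <- function(s) stat_fun(bed_y90(s * d0, params)) / target_bed_Gy - 1
  lo <- 1e-9; hi <- 1
  while (f(hi) < 0 && hi < max_scale) hi <- hi * 4
  if (f(hi) < 0) stop("no activity bracket found below the configured bound")
  s <- uniroot(f, c(lo, hi), tol = 1e-12 * hi)$root
  A0 * s
}

#' Paired comparison of plan metrics across a cohort
#'
#' Two-sided paired t-test on per-phantom differences of a plan metric
#' (e.g. mean PTV dose under the radionuclide plan vs the external-beam
#' comparator).  An all-zero-variance difference vector is reported as
#' degenerate rather than producing NaN.
#'
#' @param x,y paired metric vectors of equal length (>= 2).
#' @return object of class `plan_comparison`: `statistic`, `df`, `p_value`,
#'   `mean_difference`, `degenerate`.
#' @examples
#' compare_plans(c(2, 4, 6), c(1, 2, 3))
#' @export
compare_plans <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("paired samples of equal length >= 2 required")
  d <- x - y
  if (sd(d) == 0) {
    res <- list(statistic = NA_real_, df = length(d) - 1, p_value = NA_real_,
                mean_difference = mean(d), degenerate = TRUE)
  } else {
    tt <- t.test(x, y, paired = TRUE)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, mean_difference = unname(tt$estimate),
                degenerate = FALSE)
  }
  structure(res, class = "plan_comparison")
}

#' @export
print.plan_comparison <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("Paired comparison: degenerate (all differences equal %.4g)\n",
                x$mean_difference))
  else
    cat(sprintf("Paired t-test: t = %.3f, df = %d, p = %.4g, mean diff = %.4g\n",
                x$statistic, x$df, x$p_value, x$mean_difference))
  invisible(x)
}
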