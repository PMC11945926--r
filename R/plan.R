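#' Plan an intra-arterial Y-90 treatment for a phantom
#'
#' The package's end-to-end fitting function.  Starting from a phantom (or
#' any intensity volume plus structure set), it
#' \enumerate{
#'   \item maps contrast-enhanced intensity inside the PTV to a voxel
#'     activity distribution at a nominal administered activity
#'     ([build_activity_map()]),
#'   \item convolves the cumulated activity with the Y-90 dose voxel kernel
#'     to obtain the physical dose map ([convolve_dose()]),
#'   \item solves for the administered activities that deliver the
#'     prescription to the requested PTV coverage fractions
#'     ([prescribe_activity()]; A95 and A99 by default),
#'   \item builds the external-beam comparator plan
#'     ([generate_vmat_like_dose()]) and solves for the activity matching
#'     its mean PTV biologically effective dose
#'     ([prescribe_activity_bed_matched()]),
#'   \item computes per-structure mean dose, mean BED and DVHs for every
#'     plan.
#' }
#'
#' @param phantom a [generate_phantom()] result, or a list with elements
#'   `intensity` and `structures`.
#' @param kernel a [generate_dvk()] result on the phantom's voxel size.
#' @param nominal_activity_MBq activity at which the dose map is simulated
#'   before rescaling (default 1000 MBq = 1 GBq).
#' @param prescription_Gy prescribed dose level.
#' @param coverage PTV volume fractions to prescribe to.
#' @param vmat a [vmat_plan_spec()] for the comparator.
#' @param tumor_params,normal_params [bed_params()] objects.
#' @param bed_match statistic matched between the comparator and Y-90 plan
#'   (`"mean"` PTV BED, or `"D95"`).
#' @param T_phys_h physical half-life used for cumulated activity, h.
#' @param dvh_bin_Gy DVH bin width.
#' @param seed seed for the comparator's homogeneity ripple.
#' @return object of class `y90_plan` with fields `activities` (named:
#'   solved activities in MBq per coverage plus `A_BED`), `metrics` (a
#'   data.frame of mean dose / mean BED per structure per plan), `dvh`
#'   (nested list plan -> structure), `dose_nominal`, `dose_vmat`,
#'   `target_bed_Gy`, and the inputs' summaries.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(grid_shape = 48, voxel_mm = 1.6,
#'   tumor_volume_cm3 = 4, oars = list(), seed = 2))
#' k <- generate_dvk(grid = kernel_grid(17, 1.6), n_primaries = 2e4, seed = 1)
#' pl <- y90_plan(ph, k)
#' summary(pl)
#' }
#' @export
y90_plan <- function(phantom, kernel, nominal_activity_MBq = 1000,
                     prescription_Gy = 60, coverage = c(0.95, 0.99),
                     vmat = NULL, tumor_params = bed_params("tumor"),
                     normal_params = bed_params("normal"),
                     bed_match = c("mean", "D95"), T_phys_h = 64,
                     dvh_bin_Gy = 0.1, seed = 1) {
  bed_match <- match.arg(bed_match)
  structures <- phantom$structures
  ptv <- structures$PTV
  vmat <- vmat %||% vmat_plan_spec(prescription_Gy = prescription_Gy)

  amap <- build_activity_map(phantom$intensity, ptv,
                             total_activity_MBq = nominal_activity_MBq,
                             T_phys_h = T_phys_h,
                             voxel_mm = attr(structures, "voxel_mm"))
  d0 <- convolve_dose(amap, kernel)

  acts <- vapply(coverage, function(p)
    prescribe_activity(d0, ptv, prescription_Gy, p), numeric(1))
  names(acts) <- sprintf("A%g", 100 * coverage)

  dvmat <- generate_vmat_like_dose(structures, vmat, seed = seed)
  bed_vmat <- bed_map(dvmat, structures, tumor_params, normal_params)
  target_bed <- if (bed_match == "mean") mean(bed_vmat[ptv]) else
    dose_at_volume(as.numeric(bed_vmat[ptv]), 0.95)
  acts["A_BED"] <- prescribe_activity_bed_matched(
    d0, ptv, target_bed, tumor_params, statistic = bed_match)

  eval_structs <- intersect(c("PTV", "BrainMinusPTV"), names(structures))
  plans <- c(as.list(acts), list(VMAT = NA_real_))
  metrics <- do.call(rbind, lapply(names(plans), function(pl) {
    if (pl == "VMAT") {
      dmap <- dvmat; bmap <- bed_vmat
    } else {
      dmap <- rescale_dose(d0, plans[[pl]])
      bmap <- bed_map(dmap, structures, tumor_params, normal_params)
    }
    do.call(rbind, lapply(eval_structs, function(st) {
      m <- structures[[st]]
      data.frame(plan = pl, structure = st,
                 activity_MBq = if (pl == "VMAT") NA_real_ else plans[[pl]],
                 mean_dose_Gy = mean(dmap$voxel_dose[m]),
                 mean_bed_Gy = mean(bmap[m]),
                 d95_Gy = dose_at_volume(as.numeric(dmap$voxel_dose[m]), 0.95),
                 stringsAsFactors = FALSE)
    }))
  }))

  dvhs <- lapply(names(plans), function(pl) {
    dmap <- if (pl == "VMAT") dvmat else rescale_dose(d0, plans[[pl]])
    lapply(setNames(eval_structs, eval_structs), function(st)
      compute_dvh(dmap, structures[[st]], bin_Gy = dvh_bin_Gy, structure = st))
  })
  names(dvhs) <- names(plans)

  structure(list(
    activities = acts, metrics = metrics, dvh = dvhs,
    dose_nominal = d0, dose_vmat = dvmat,
    nominal_activity_MBq = nominal_activity_MBq,
    prescription_Gy = prescription_Gy, coverage = coverage,
    target_bed_Gy = target_bed, bed_match = bed_match,
    ptv_brain_ratio = phantom$ptv_brain_ratio %||% NA_real_,
    ptv_volume_cm3 = phantom$ptv_volume_cm3 %||%
      (sum(ptv) * prod(attr(structures, "voxel_mm")) / 1000)
  ), class = "y90_plan")
}

#' @export
print.y90_plan <- function(x, ...) {
  cat("Y-90 intra-arterial activity plan\n")
  cat(sprintf("  prescription: %.0f Gy; PTV %.2f cm^3 (PTV/brain ratio %.4f)\n",
              x$prescription_Gy, x$ptv_volume_cm3, x$ptv_brain_ratio))
  for (nm in names(x$activities))
    cat(sprintf("  %-6s= %8.1f MBq\n", nm, x$activities[nm]))
  cat(sprintf("  comparator mean PTV BED (matching target): %.1f Gy\n",
              x$target_bed_Gy))
  invisible(x)
}

#' @export
summary.y90_plan <- function(object, ...) {
  cat("Y-90 plan summary: per-structure mean dose and BED\n\n")
  print(object$metrics, row.names = FALSE, digits = 4)
  invisible(object$metrics)
}

#' @export
plot.y90_plan <- function(x, structure = "PTV", ...) {
  plans <- names(x$dvh)
  cols <- palette.colors(max(3, length(plans)))[seq_along(plans)]
  xmax <- max(vapply(plans, function(p) max(x$dvh[[p]][[structure]]$dose_Gy),
                     numeric(1)))
  plot(NULL, xlim = c(0, xmax), ylim = c(0, 100), xlab = "dose (Gy)",
       ylab = "volume (%)", main = sprintf("DVH: %s", structure), ...)
  for (i in seq_along(plans))
    plot(x$dvh[[plans[i]]][[structure]], add = TRUE, col = cols[i])
  abline(v = x$prescription_Gy, lty = 3)
  legend("topright", plans, col = cols, lty = 1, bty = "n")
  invisible(x)
}
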