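#' Run the planning pipeline over a phantom cohort
#'
#' Applies [y90_plan()] to every phantom of a cohort with a shared kernel
#' and collects per-phantom prescriptions and plan metrics into one table,
#' the form consumed by the cohort trend and paired-comparison analyses.
#'
#' @param cohort a [generate_cohort()] result (or list of phantoms).
#' @param kernel a [generate_dvk()] result matching the phantoms' voxel
#'   size.
#' @param ... further arguments passed to [y90_plan()].
#' @return data.frame with one row per phantom: `ptv_brain_ratio`,
#'   `ptv_volume_cm3`, the solved activities (`A95`, `A99`, `A_BED` under
#'   default coverage), and mean dose / mean BED of PTV and Brain-minus-PTV
#'   under the Y-90 plans and the external-beam comparator.
#' @export
run_cohort <- function(cohort, kernel, ...) {
  rows <- lapply(seq_along(cohort), function(i) {
    pl <- y90_plan(cohort[[i]], kernel, ...)
    m <- pl$metrics
    g <- function(plan, st, col) m[m$plan == plan & m$structure == st, col]
    a <- as.list(pl$activities)
    names(a) <- gsub("[^A-Za-z0-9]", "", names(a))
    cbind(data.frame(phantom = i,
                     ptv_brain_ratio = pl$ptv_brain_ratio,
                     ptv_volume_cm3 = pl$ptv_volume_cm3),
          as.data.frame(a),
          data.frame(
            ptv_mean_y90 = g(names(pl$activities)[1], "PTV", "mean_dose_Gy"),
            ptv_mean_vmat = g("VMAT", "PTV", "mean_dose_Gy"),
            brain_mean_y90 = g(names(pl$activities)[1], "BrainMinusPTV",
                               "mean_dose_Gy"),
            brain_mean_vmat = g("VMAT", "BrainMinusPTV", "mean_dose_Gy"),
            ptv_bed_y90 = g("A_BED", "PTV", "mean_bed_Gy"),
            ptv_bed_vmat = g("VMAT", "PTV", "mean_bed_Gy"),
            brain_bed_y90 = g("A_BED", "BrainMinusPTV", "mean_bed_Gy"),
            brain_bed_vmat = g("VMAT", "BrainMinusPTV", "mean_bed_Gy")))
  })
  do.call(rbind, rows)
}

#' Cohort trend between relative tumor burden and prescription spread
#'
#' Spearman rank correlation between the PTV/normal-brain volume ratio and
#' the difference between the 99% and 95% coverage activities across a
#' cohort table from [run_cohort()].
#'
#' @param results a [run_cohort()] data.frame with `A95` and `A99` columns.
#' @return Spearman correlation coefficient.
#' @export
cohort_trend <- function(results) {
  stopifnot(all(c("A95", "A99", "ptv_brain_ratio") %in% names(results)))
  cor(results$ptv_brain_ratio, results$A99 - results$A95, method = "spearman")
}
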