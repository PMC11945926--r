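# NIfTI + JSON-sidecar I/O for kernels, dose maps and phantoms.
# Volumes are written as 32-bit float NIfTI; everything needed to rebuild the
# R object that is not an image lives in the sidecar.

.write_nifti_vol <- function(x, path, voxel_mm) {
  img <- RNifti::asNifti(x, reference = NULL)
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Write / read a dose voxel kernel
#'
#' `write_kernel()` stores the kernel as a 4-D NIfTI (total, beta, photon,
#' relative uncertainty along the fourth axis) plus a JSON sidecar carrying
#' the grid, seed, primary count, component energy bookkeeping and model
#' parameters.  `read_kernel()` rebuilds a `dose_kernel` object.
#'
#' @param kernel a [generate_dvk()] result.
#' @param prefix path prefix; `<prefix>.nii.gz` and `<prefix>.json` are
#'   written.
#' @return `write_kernel()` the prefix, invisibly; `read_kernel()` a
#'   `dose_kernel`.
#' @export
write_kernel <- function(kernel, prefix) {
  stopifnot(inherits(kernel, "dose_kernel"))
  vol <- array(0, c(kernel$grid$shape, 4))
  vol[, , , 1] <- kernel$values
  vol[, , , 2] <- kernel$beta_component
  vol[, , , 3] <- kernel$photon_component
  ru <- kernel$rel_uncertainty; ru[!is.finite(ru)] <- -1
  vol[, , , 4] <- ru
  .write_nifti_vol(vol, paste0(prefix, ".nii.gz"), kernel$grid$voxel_mm)
  meta <- kernel[c("n_primaries", "n_batches", "seed", "density_g_cm3",
                   "brems_yield", "mu_photon_cm", "spectrum_label",
                   "spectrum_mean_MeV", "sampled_mean_MeV")]
  meta$shape <- kernel$grid$shape
  meta$voxel_mm <- kernel$grid$voxel_mm
  meta$energy_MeV_per_decay <- as.list(kernel$energy_MeV_per_decay)
  meta$max_rel_uncertainty_4p8mm <-
    tryCatch(estimate_kernel_uncertainty(kernel, 4.8), error = function(e) NA)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vol <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  grid <- kernel_grid(meta$shape, meta$voxel_mm)
  ru <- array(vol[, , , 4], grid$shape)
  ru[ru < 0] <- NA_real_
  structure(list(
    values = array(vol[, , , 1], grid$shape),
    beta_component = array(vol[, , , 2], grid$shape),
    photon_component = array(vol[, , , 3], grid$shape),
    rel_uncertainty = ru, se = array(vol[, , , 1], grid$shape) * ru,
    grid = grid,
    n_primaries = meta$n_primaries, n_batches = meta$n_batches,
    seed = meta$seed, density_g_cm3 = meta$density_g_cm3,
    brems_yield = meta$brems_yield, mu_photon_cm = meta$mu_photon_cm,
    spectrum_label = meta$spectrum_label,
    spectrum_mean_MeV = meta$spectrum_mean_MeV,
    sampled_mean_MeV = meta$sampled_mean_MeV,
    energy_MeV_per_decay = unlist(meta$energy_MeV_per_decay)
  ), class = "dose_kernel")
}

#' Write / read a dose map
#'
#' Dose maps are stored as a single-volume float NIfTI (Gy) with a JSON
#' sidecar (source, fractionation, administered activity); a round trip
#' reproduces values within 32-bit float precision and the grid metadata
#' exactly.
#'
#' @param map a `dose_map`.
#' @param prefix path prefix for `<prefix>.nii.gz` + `<prefix>.json`.
#' @return `write_dose()` the prefix, invisibly; `read_dose()` a `dose_map`.
#' @export
write_dose <- function(map, prefix) {
  stopifnot(inherits(map, "dose_map"))
  .write_nifti_vol(map$voxel_dose, paste0(prefix, ".nii.gz"), map$voxel_mm)
  meta <- list(voxel_mm = map$voxel_mm, source = map$source,
               n_fractions = map$n_fractions,
               total_activity_MBq = map$total_activity_MBq,
               lost_fraction = map$lost_fraction)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_dose
#' @export
read_dose <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vol <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  structure(list(voxel_dose = array(as.numeric(vol), dim(vol)),
                 voxel_mm = meta$voxel_mm, source = meta$source,
                 n_fractions = meta$n_fractions,
                 total_activity_MBq = meta$total_activity_MBq,
                 lost_fraction = meta$lost_fraction),
            class = "dose_map")
}

#' Write a phantom to NIfTI volumes
#'
#' Writes the intensity volume and every structure mask as NIfTI files in
#' `dir`, plus `phantom.json` with the generating specification and achieved
#' volumes.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- rep(phantom$spec$voxel_mm, 3)
  .write_nifti_vol(phantom$intensity, file.path(dir, "intensity.nii.gz"), v)
  for (nm in names(phantom$structures))
    .write_nifti_vol(phantom$structures[[nm]] * 1,
                     file.path(dir, paste0("mask_", nm, ".nii.gz")), v)
  meta <- phantom$spec
  class(meta) <- NULL
  meta$achieved <- list(ptv_volume_cm3 = phantom$ptv_volume_cm3,
                        brain_volume_cm3 = phantom$brain_volume_cm3,
                        ptv_brain_ratio = phantom$ptv_brain_ratio)
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
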