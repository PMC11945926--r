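#' Specification of a synthetic brain/tumor phantom
#'
#' Describes one "virtual patient": an ellipsoidal brain mask inside a voxel
#' grid, a contiguous tumor volume (the PTV) with heterogeneous contrast
#' enhancement, and small spherical organs at risk.  The defaults emulate a
#' contrast-enhanced T1-weighted acquisition at 0.8 mm isotropic voxels with
#' a right-skewed (log-normal) enhancement distribution inside the tumor;
#' the grid is a reduced brain-scale field of view chosen so a full planning
#' run stays desk-sized.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_mm isotropic voxel edge, mm.
#' @param brain_semiaxes_mm ellipsoid semi-axes of the brain mask, mm.
#' @param tumor_centroid_mm tumor centroid offset from the grid centre, mm.
#' @param tumor_volume_cm3 requested PTV volume; achieved within one voxel
#'   volume.
#' @param heterogeneity log-scale standard deviation of within-PTV
#'   enhancement (0 gives perfectly uniform enhancement).
#' @param background mean background intensity of normal brain (arbitrary
#'   units).
#' @param noise_sd Gaussian noise s.d. of the background (clipped at 0).
#' @param enhancement median tumor enhancement as a multiple of `background`.
#' @param tumor_shape `"irregular"` builds the PTV from 3--7 overlapping
#'   random spheres sharing the centroid; `"sphere"` gives a single sphere
#'   for analytic tests.
#' @param oars named list of organs at risk, each
#'   `list(centroid_mm =, radius_mm =)`.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), voxel_mm = 0.8,
                         brain_semiaxes_mm = c(35, 30, 28),
                         tumor_centroid_mm = c(10, 8, 8),
                         tumor_volume_cm3 = 15,
                         heterogeneity = 0.5,
                         background = 100, noise_sd = 5, enhancement = 3,
                         tumor_shape = c("irregular", "sphere"),
                         oars = list(
                           brainstem = list(centroid_mm = c(-6, -10, -16),
                                            radius_mm = 6),
                           chiasm = list(centroid_mm = c(-4, 6, -18),
                                         radius_mm = 4)),
                         seed = 1) {
  tumor_shape <- match.arg(tumor_shape)
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  .check_scalar(tumor_volume_cm3, "tumor_volume_cm3")
  .check_scalar(background, "background")
  if (heterogeneity < 0) stop("'heterogeneity' must be >= 0")
  structure(list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
                 brain_semiaxes_mm = brain_semiaxes_mm,
                 tumor_centroid_mm = tumor_centroid_mm,
                 tumor_volume_cm3 = tumor_volume_cm3,
                 heterogeneity = heterogeneity, background = background,
                 noise_sd = noise_sd, enhancement = enhancement,
                 tumor_shape = tumor_shape, oars = oars, seed = seed),
            class = "phantom_spec")
}

# ellipsoid membership on the phantom grid; shrink_mm erodes the surface
.ellipsoid_mask <- function(shape, voxel_mm, semi, center_mm = c(0, 0, 0),
                            shrink_mm = 0) {
  semi <- pmax(semi - shrink_mm, 1e-6)
  ax <- lapply(1:3, function(i) ((.axis_mm(shape[i], voxel_mm) - center_mm[i]) / semi[i])^2)
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`) < 1
}

.sphere_mask <- function(shape, voxel_mm, center_mm, radius_mm) {
  ax <- lapply(1:3, function(i) (.axis_mm(shape[i], voxel_mm) - center_mm[i])^2)
  outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`) < radius_mm^2
}

#' Generate a synthetic phantom
#'
#' Builds the intensity volume and structure set described by a
#' [phantom_spec()].  The PTV is the set of voxels with the smallest values
#' of a lobed shape field (minimum over the component spheres of the scaled
#' distance to each sphere centre), restricted to the brain interior, taken
#' in increasing order until the requested volume is reached -- this yields a
#' contiguous, irregular volume whose voxel count equals the requested
#' volume rounded to the nearest voxel.  Tumor voxel intensities are drawn
#' from a log-normal distribution above background; normal brain carries
#' Gaussian noise around the background level, clipped at zero.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom`: fields `intensity` (3-D array),
#'   `structures` (class `structure_set`: named logical masks `PTV`,
#'   `Brain`, `BrainMinusPTV` and one per OAR, sharing the grid), `spec`,
#'   and achieved volume summaries including `ptv_brain_ratio`
#'   (PTV / Brain-minus-PTV volume ratio).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = 48, voxel_mm = 1.6,
#'   tumor_volume_cm3 = 4, seed = 7))
#' ph
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  shp <- spec$grid_shape; v <- spec$voxel_mm
  voxvol_cm3 <- (v^3) / 1000
  brain <- .ellipsoid_mask(shp, v, spec$brain_semiaxes_mm)
  interior <- .ellipsoid_mask(shp, v, spec$brain_semiaxes_mm, shrink_mm = v)

  # lobed shape field around the centroid
  r0 <- (3 * spec$tumor_volume_cm3 * 1000 / (4 * pi))^(1 / 3)  # mm
  if (spec$tumor_shape == "sphere") {
    centers <- matrix(spec$tumor_centroid_mm, nrow = 1)
    radii <- r0
  } else {
    k <- sample(3:7, 1)
    u <- matrix(rnorm(3 * k), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    off <- runif(k, 0, 0.6) * r0
    centers <- sweep(u * off, 2, spec$tumor_centroid_mm, `+`)
    radii <- runif(k, 0.45, 1) * r0
  }
  phi <- array(Inf, shp)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer(outer((.axis_mm(shp[1], v) - centers[i, 1])^2,
                      (.axis_mm(shp[2], v) - centers[i, 2])^2, `+`),
                (.axis_mm(shp[3], v) - centers[i, 3])^2, `+`)
    phi <- pmin(phi, sqrt(d2) / radii[i])
  }
  phi[!interior] <- Inf

  n_target <- round(spec$tumor_volume_cm3 / voxvol_cm3)
  if (n_target < 1) stop("requested tumor volume smaller than one voxel")
  if (sum(is.finite(phi)) < n_target)
    stop("tumor too large for brain: requested volume does not fit inside the brain mask")
  ord <- order(phi)[seq_len(n_target)]
  ptv <- array(FALSE, shp)
  ptv[ord] <- TRUE

  # intensity volume
  intensity <- array(0, shp)
  nb <- sum(brain)
  intensity[brain] <- pmax(0, rnorm(nb, spec$background, spec$noise_sd))
  np <- sum(ptv)
  intensity[ptv] <- spec$background * spec$enhancement *
    exp(rnorm(np, 0, spec$heterogeneity))

  structures <- list(PTV = ptv, Brain = brain,
                     BrainMinusPTV = brain & !ptv)
  for (nm in names(spec$oars)) {
    o <- spec$oars[[nm]]
    m <- .sphere_mask(shp, v, o$centroid_mm, o$radius_mm)
    if (any(m & ptv))
      stop(sprintf("OAR '%s' collides with the PTV", nm))
    structures[[nm]] <- m
  }
  attr(structures, "voxel_mm") <- rep(v, 3)
  attr(structures, "shape") <- shp
  class(structures) <- "structure_set"

  vol_ptv <- np * voxvol_cm3
  vol_brain <- nb * voxvol_cm3
  structure(list(
    intensity = intensity, structures = structures, spec = spec,
    ptv_volume_cm3 = vol_ptv, brain_volume_cm3 = vol_brain,
    ptv_brain_ratio = vol_ptv / (vol_brain - vol_ptv)
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Synthetic phantom (seed %d): grid %s at %.2f mm\n",
              x$spec$seed, paste(x$spec$grid_shape, collapse = "x"),
              x$spec$voxel_mm))
  cat(sprintf("  brain %.1f cm^3, PTV %.2f cm^3 (PTV/brain ratio %.4f)\n",
              x$brain_volume_cm3, x$ptv_volume_cm3, x$ptv_brain_ratio))
  cat(sprintf("  structures: %s\n", paste(names(x$structures), collapse = ", ")))
  invisible(x)
}

#' Generate a cohort of phantoms spanning PTV/brain volume ratios
#'
#' Produces `n` phantoms whose PTV to normal-brain (Brain-minus-PTV) volume
#' ratios are log-spaced across `ratio_range`, emulating the order-of-
#' magnitude spread of relative tumor burden across a patient cohort.  Each
#' phantom gets a distinct seed derived from the master seed.
#'
#' @param n cohort size.
#' @param ratio_range lower and upper PTV/normal-brain volume ratio.
#' @param seed master seed.
#' @param base_spec a [phantom_spec()] whose non-volume fields are shared by
#'   the whole cohort.
#' @return list of [generate_phantom()] results, class `phantom_cohort`.
#' @export
generate_cohort <- function(n = 9, ratio_range = c(0.005, 0.15), seed = 1,
                            base_spec = phantom_spec()) {
  if (n < 1) stop("'n' must be >= 1")
  if (length(ratio_range) != 2 || any(ratio_range <= 0) ||
      diff(ratio_range) < 0)
    stop("'ratio_range' must be an increasing pair of positive ratios")
  ratios <- if (n == 1) ratio_range[1] else
    exp(seq(log(ratio_range[1]), log(ratio_range[2]), length.out = n))
  v_brain <- 4 / 3 * pi * prod(base_spec$brain_semiaxes_mm) / 1000
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- base_spec
    sp$tumor_volume_cm3 <- ratios[i] / (1 + ratios[i]) * v_brain
    sp$seed <- seed + i
    cohort[[i]] <- generate_phantom(sp)
  }
  structure(cohort, class = "phantom_cohort", master_seed = seed)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("Phantom cohort of %d (master seed %d)\n", length(x),
              attr(x, "master_seed")))
  for (p in x)
    cat(sprintf("  seed %d: PTV %.2f cm^3, ratio %.4f\n",
                p$spec$seed, p$ptv_volume_cm3, p$ptv_brain_ratio))
  invisible(x)
}
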