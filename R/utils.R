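# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal quadrature
.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

.cumtrapz <- function(x, y) c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))

# distance (mm) of every voxel centre from the central voxel of an odd grid
.radius_grid_mm <- function(shape, voxel_mm) {
  ax <- lapply(1:3, function(i) (seq_len(shape[i]) - (shape[i] + 1) / 2) * voxel_mm[i])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  sqrt(r2)
}

# voxel-centre coordinates (mm, grid centre at the origin) for a given axis
.axis_mm <- function(n, v) (seq_len(n) - (n + 1) / 2) * v

#' 3-D linear (zero-padded) convolution via the FFT
#'
#' Computes the discrete linear convolution of a volume with an odd-shaped
#' kernel and returns the "same"-sized result centred on the kernel centre.
#' Zero padding removes circular wrap-around; accumulation is in double
#' precision.
#' @noRd
.convolve3d <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  stopifnot(length(da) == 3, length(dk) == 3, all(dk %% 2 == 1))
  dfull <- da + dk - 1L
  dpad <- vapply(dfull, nextn, integer(1), factors = c(2, 3, 5))
  A <- array(0, dpad); A[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  K <- array(0, dpad); K[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(fft(fft(A) * fft(K), inverse = TRUE)) / prod(dpad)
  off <- (dk - 1L) / 2L
  out <- full[off[1] + seq_len(da[1]), off[2] + seq_len(da[2]), off[3] + seq_len(da[3])]
  # clip tiny negative FFT round-off
  out[out < 0 & out > -1e-9 * max(abs(out))] <- 0
  out
}

# isotropic 3-D Gaussian blur of a volume (sigma in voxels may differ per axis)
.gaussian_blur3d <- function(a, sigma_vox) {
  half <- pmax(1L, ceiling(4 * sigma_vox))
  ks <- lapply(1:3, function(i) {
    x <- (-half[i]):(half[i])
    w <- exp(-x^2 / (2 * sigma_vox[i]^2))
    w / sum(w)
  })
  k <- outer(outer(ks[[1]], ks[[2]]), ks[[3]])
  .convolve3d(a, k)
}

.check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
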