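# independent oracles used against the production code paths

# brute-force triple-loop evaluation of the voxel dosimetry convolution sum
direct_convolve <- function(a, k) {
  da <- dim(a); dk <- dim(k); hk <- (dk - 1L) / 2L
  out <- array(0, da)
  for (x in seq_len(da[1])) for (y in seq_len(da[2])) for (z in seq_len(da[3])) {
    s <- 0
    for (i in -hk[1]:hk[1]) for (j in -hk[2]:hk[2]) for (l in -hk[3]:hk[3]) {
      xs <- x - i; ys <- y - j; zs <- z - l
      if (xs >= 1 && xs <= da[1] && ys >= 1 && ys <= da[2] &&
          zs >= 1 && zs <= da[3])
        s <- s + a[xs, ys, zs] * k[i + hk[1] + 1L, j + hk[2] + 1L, l + hk[3] + 1L]
    }
    out[x, y, z] <- s
  }
  out
}

# closed-form inversion of the permanent-implant BED quadratic in D:
# BED = D + g D^2 / ab  =>  D = ab/(2g) (sqrt(1 + 4 g BED / ab) - 1)
invert_bed_y90 <- function(bed, params) {
  g <- params$lambda_h / (params$lambda_h + params$mu_h)
  ab <- params$alpha_beta_Gy
  ab / (2 * g) * (sqrt(1 + 4 * g * bed / ab) - 1)
}

# 6-connectivity flood fill: is a voxel mask one connected component?
mask_is_connected <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(FALSE)
  d <- dim(mask)
  lab <- array(FALSE, d)
  queue <- idx[1]
  lab[queue] <- TRUE
  n_seen <- 1L
  strides <- c(1L, d[1], d[1] * d[2])
  coord <- function(i) arrayInd(i, d)
  while (length(queue)) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    ci <- arrayInd(cur, d)
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      ni <- ci; ni[ax] <- ni[ax] + s
      if (ni[ax] < 1 || ni[ax] > d[ax]) next
      j <- ((ni[3] - 1L) * d[2] + (ni[2] - 1L)) * d[1] + ni[1]
      if (mask[j] && !lab[j]) {
        lab[j] <- TRUE
        n_seen <- n_seen + 1L
        queue <- c(queue, j)
      }
    }
  }
  n_seen == length(idx)
}
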