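# Shared fixtures built in code at test time.

paradigm10 <- oxygen_paradigm()  # the 10/10/10-min block design

# Tiny 4D series with constant intensity v.
const_series <- function(v = 100, shape = c(4, 4, 3), nt = 12, tr = 60,
                         te = 0.035) {
  volume_series(array(v, c(shape, nt)), tr = tr, te = te)
}

# Series whose every voxel follows the same temporal profile `prof`.
profile_series <- function(prof, shape = c(4, 4, 3), tr = 60, te = 0.035,
                           frame_times = NULL) {
  arr <- array(rep(prof, each = prod(shape)), c(shape, length(prof)))
  volume_series(arr, tr = tr, te = te, frame_times = frame_times)
}

# Full-volume single-ROI mask set.
full_roi <- function(shape = c(4, 4, 3)) {
  roi_set(array(1L, shape), c(placenta_twinA = 1L))
}

# Brute-force zero-padded 3D Gaussian convolution (triple loop oracle).
brute_conv3 <- function(vol, width, sigma) {
  half <- (width - 1) / 2
  x <- seq(-half, half)
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  d <- dim(vol)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(x)) for (b in seq_along(x)) for (cc in seq_along(x)) {
      ii <- i + x[a]; jj <- j + x[b]; ll <- l + x[cc]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          ll >= 1 && ll <= d[3])
        acc <- acc + k1[a] * k1[b] * k1[cc] * vol[ii, jj, ll]
    }
    out[i, j, l] <- acc
  }
  out
}
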