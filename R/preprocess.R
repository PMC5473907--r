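#' Detect outlier frames from unexpected mean-signal jumps
#'
#' Flags frames whose mean intensity inside a mask departs from the
#' median of its temporal neighborhood by more than `threshold` robust
#' standard deviations. The robust z of a frame is
#' `|residual| / (1.4826 * MAD(residuals))`, where the residual is the
#' frame's masked mean minus the median of the means of its neighboring
#' frames (the frame itself excluded).
#'
#' @param series A [volume_series()].
#' @param mask 3D logical array (nonempty).
#' @param threshold Robust-z cutoff, default 3.
#' @param neighborhood Half-width of the temporal neighborhood in frames,
#'   default 2 (i.e. +/- 2 frames).
#' @return A list of class `frame_qc`: `outlier_flags` (logical),
#'   `frame_mean`, `robust_z` (per frame), `threshold`.
#' @export
detect_outlier_frames <- function(series, mask, threshold = 3,
                                  neighborhood = 2) {
  stopifnot(inherits(series, "volume_series"))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  nt <- dim(series$data)[4]
  if (nt < 5) stop("need at least 5 frames", call. = FALSE)
  mvec <- which(mask)
  nvox <- prod(dim(series$data)[1:3])
  fm <- vapply(seq_len(nt), function(k)
    mean(series$data[(k - 1) * nvox + mvec]), numeric(1))
  resid <- vapply(seq_len(nt), function(k) {
    # full-width window, shifted inward at the series edges so every
    # frame is judged against the same number of neighbors
    lo <- max(1, min(k - neighborhood, nt - 2 * neighborhood))
    hi <- min(nt, lo + 2 * neighborhood)
    nb <- setdiff(lo:hi, k)
    fm[k] - stats::median(fm[nb])
  }, numeric(1))
  s <- 1.4826 * stats::mad(resid, constant = 1)
  z <- if (s > 0) abs(resid) / s else rep(0, nt)
  structure(list(outlier_flags = is.finite(z) & z > threshold,
                 frame_mean = fm, robust_z = z, threshold = threshold),
            class = "frame_qc")
}

# 1D Gaussian taps, truncated at `width` (odd), unit sum.
gaussian_kernel_1d <- function(width, sigma) {
  half <- (width - 1) / 2
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Zero-padded 1D convolution along one margin of a 3D array.
conv_along <- function(vol, k, margin) {
  half <- (length(k) - 1) / 2
  out <- array(0, dim(vol))
  for (j in seq_along(k)) {
    off <- j - 1 - half
    n <- dim(vol)[margin]
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    idx_to <- which(ok); idx_from <- src[ok]
    if (margin == 1) out[idx_to, , ] <- out[idx_to, , ] + k[j] * vol[idx_from, , ]
    else if (margin == 2) out[, idx_to, ] <- out[, idx_to, ] + k[j] * vol[, idx_from, ]
    else out[, , idx_to] <- out[, , idx_to] + k[j] * vol[, , idx_from]
  }
  out
}

#' Spatial Gaussian smoothing of a volume series
#'
#' Per-frame 3D Gaussian convolution with a separable kernel truncated
#' at `kernel_width` taps per axis (default width 5, sigma 1.5 pixels)
#' and normalized to unit sum. With a mask, the smoothed values are
#' renormalized inside the mask by the smoothed mask (so signal does not
#' bleed across the ROI edge); voxels outside the mask are passed
#' through unchanged.
#'
#' @param series A [volume_series()] or a 3D array.
#' @param kernel_width Odd kernel width in pixels, default 5.
#' @param sigma Gaussian sigma in pixels, default 1.5.
#' @param mask Optional 3D logical array.
#' @return Same type as `series`, smoothed.
#' @export
spatial_smooth <- function(series, kernel_width = 5, sigma = 1.5,
                           mask = NULL) {
  if (kernel_width %% 2 == 0)
    stop("kernel width must be odd", call. = FALSE)
  k <- gaussian_kernel_1d(kernel_width, sigma)
  conv3 <- function(vol)
    conv_along(conv_along(conv_along(vol, k, 1), k, 2), k, 3)
  smooth3 <- function(vol) {
    if (is.null(mask)) return(conv3(vol))
    w <- conv3(array(as.numeric(mask), dim(vol)))
    num <- conv3(vol * as.numeric(mask))
    res <- vol
    inside <- mask & w > 0
    res[inside] <- num[inside] / w[inside]
    res
  }
  if (inherits(series, "volume_series")) {
    out <- series
    d <- dim(series$data)
    for (f in seq_len(d[4]))
      out$data[, , , f] <- smooth3(array(series$data[, , , f], d[1:3]))
    out
  } else smooth3(series)
}

#' Temporal interpolation and moving-average smoothing
#'
#' Drops flagged frames, linearly interpolates the remaining frames onto
#' a uniform grid of step `resample_dt`, then applies a centered moving
#' average of `window` samples (edge samples use truncated windows).
#' The default window of 10 frames at the scanner's 5-8 s repetition
#' time corresponds to roughly one minute of smoothing.
#'
#' @param series A [volume_series()].
#' @param window Moving-average window in frames (>= 1), default 10.
#' @param resample_dt Uniform grid step in minutes; default the median
#'   frame interval.
#' @param qc Optional `frame_qc`; flagged frames are dropped before
#'   interpolation.
#' @return A [volume_series()] on the uniform grid.
#' @export
temporal_smooth <- function(series, window = 10, resample_dt = NULL,
                            qc = NULL) {
  stopifnot(inherits(series, "volume_series"))
  keep <- if (is.null(qc)) rep(TRUE, length(series$frame_times))
          else !qc$outlier_flags
  if (sum(keep) < 2) stop("fewer than 2 usable frames", call. = FALSE)
  t_in <- series$frame_times[keep]
  if (is.null(resample_dt))
    resample_dt <- stats::median(diff(series$frame_times))
  t_out <- seq(min(t_in), max(t_in), by = resample_dt)
  nt_out <- length(t_out)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window > nt_out) stop("window longer than series", call. = FALSE)
  d <- dim(series$data)
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])[, keep,
                                                                drop = FALSE]
  # linear interpolation of every voxel onto the uniform grid
  interp <- t(apply(flat, 1, function(y)
    stats::approx(t_in, y, xout = t_out, rule = 2)$y))
  if (window > 1) {
    half_lo <- floor((window - 1) / 2); half_hi <- window - 1 - half_lo
    cs <- cbind(0, t(apply(interp, 1, cumsum)))
    sm <- interp
    for (j in seq_len(nt_out)) {
      lo <- max(1, j - half_lo); hi <- min(nt_out, j + half_hi)
      sm[, j] <- (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
    }
    interp <- sm
  }
  volume_series(array(pmax(interp, 0), c(d[1:3], nt_out)),
                tr = resample_dt * 60, te = series$te,
                voxel_size = series$voxel_size, t0 = t_out[1],
                frame_times = t_out, orientation = series$orientation)
}

#' Voxel-wise baseline intensity map
#'
#' Mean of the unflagged frames acquired during the normoxic baseline
#' epoch (frame time < baseline duration).
#'
#' @param series A [volume_series()].
#' @param paradigm An [oxygen_paradigm()].
#' @param qc Optional `frame_qc` from [detect_outlier_frames()].
#' @return 3D baseline intensity map.
#' @export
compute_baseline <- function(series, paradigm, qc = NULL) {
  stopifnot(inherits(series, "volume_series"),
            inherits(paradigm, "oxygen_paradigm"))
  keep <- series$frame_times < paradigm$baseline_dur
  if (!is.null(qc)) keep <- keep & !qc$outlier_flags
  if (sum(keep) < 3)
    stop("fewer than 3 usable baseline frames", call. = FALSE)
  d <- dim(series$data)
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  array(rowMeans(flat[, keep, drop = FALSE]), d[1:3])
}
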