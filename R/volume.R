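#' Construct a 4D BOLD volume series
#'
#' A `volume_series` bundles a 4D intensity array (x, y, z, t) with its
#' acquisition metadata. Times are carried in minutes everywhere
#' downstream; the echo time TE stays in seconds so that delta-R2* maps
#' come out in s^-1.
#'
#' @param data 4D numeric array (x, y, z, t); finite, nonnegative.
#' @param tr Repetition time, seconds per frame.
#' @param te Echo time, seconds.
#' @param voxel_size Voxel edge lengths, mm, length 3.
#' @param t0 Acquisition start time, minutes (default 0).
#' @param frame_times Frame midpoint times in minutes; defaults to
#'   `t0 + (0:(nt-1)) * tr / 60`.
#' @param orientation 4x4 voxel-to-world affine (mm); default diagonal
#'   from `voxel_size`.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr, te, voxel_size = c(3, 3, 3), t0 = 0,
                          frame_times = NULL, orientation = NULL) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, z, t)", call. = FALSE)
  if (!all(is.finite(data)) || any(data < 0))
    stop("intensities must be finite and nonnegative", call. = FALSE)
  if (!is.finite(tr) || tr <= 0) stop("tr must be positive seconds", call. = FALSE)
  if (!is.finite(te) || te <= 0) stop("te must be positive seconds", call. = FALSE)
  nt <- dim(data)[4]
  if (is.null(frame_times)) frame_times <- t0 + (seq_len(nt) - 1) * tr / 60
  if (length(frame_times) != nt)
    stop("frame_times length must equal number of frames", call. = FALSE)
  if (any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing", call. = FALSE)
  if (is.null(orientation)) {
    orientation <- diag(c(voxel_size, 1))
  }
  structure(list(data = data, voxel_size = voxel_size, tr = tr, te = te,
                 t0 = t0, frame_times = frame_times,
                 orientation = orientation),
            class = "volume_series")
}

#' @exportS3Method base::print
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD volume series: %d x %d x %d voxels, %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TR %.3g s, TE %.3g ms, t = [%.2f, %.2f] min\n",
              x$tr, x$te * 1000, min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

#' Read a 4D BOLD series from a NIfTI-1 file
#'
#' @param path Path to a 4D NIfTI-1 file. If a sidecar JSON file with the
#'   same stem exists (fields `tr`, `te`, `t0` seconds/seconds/minutes),
#'   its values override the arguments.
#' @param tr,te Repetition and echo time, seconds.
#' @param t0 Acquisition start, minutes.
#' @return A [volume_series()].
#' @export
read_volume_series <- function(path, tr, te, t0 = 0) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop(sprintf("expected a 4D volume, got %dD", length(dim(img))),
         call. = FALSE)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (sidecar != path && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$tr)) tr <- meta$tr
    if (!is.null(meta$te)) te <- meta$te
    if (!is.null(meta$t0)) t0 <- meta$t0
  }
  pix <- attr(img, "pixdim")
  vox <- if (!is.null(pix) && length(pix) >= 3) abs(pix[1:3]) else c(3, 3, 3)
  volume_series(array(as.numeric(img), dim(img)), tr = tr, te = te,
                voxel_size = vox, t0 = t0,
                orientation = RNifti::xform(img))
}

#' Write a volume series (or bare array) as NIfTI-1
#'
#' @param x A [volume_series()], or a 3D/4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_series <- function(x, path) {
  arr <- if (inherits(x, "volume_series")) x$data else x
  meta <- if (inherits(x, "volume_series")) {
    dt <- if (length(dim(arr)) == 4L) x$tr else 0
    list(pixdim = c(-1, x$voxel_size, dt, 0, 0, 0))  # qfac + 7 dims
  } else list()
  img <- RNifti::asNifti(arr, meta, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Construct an ROI label set
#'
#' Integer-labelled regions of interest on the same voxel grid as a
#' paired [volume_series()]. The dictionary maps each nonzero label to a
#' role such as `placenta_twinA` or `liver_twinB`.
#'
#' @param labels 3D integer array of region labels (0 = background).
#' @param dictionary Named integer vector or list: role -> label.
#' @param series Optional [volume_series()] to validate the grid against.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, dictionary, series = NULL) {
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  dict <- unlist(dictionary)
  if (is.null(names(dict)) || any(names(dict) == ""))
    stop("dictionary must map role names to labels", call. = FALSE)
  present <- setdiff(unique(as.integer(labels)), 0L)
  missing <- setdiff(present, as.integer(dict))
  if (length(missing))
    stop(sprintf("labels without dictionary entry: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!is.null(series) &&
      !identical(dim(labels), dim(series$data)[1:3]))
    stop("ROI grid does not match the volume series grid", call. = FALSE)
  structure(list(labels = labels, dictionary = dict), class = "roi_set")
}

#' Logical mask for one ROI role
#'
#' @param rois An [roi_set()].
#' @param role Role name present in the dictionary.
#' @return 3D logical array.
#' @export
roi_mask <- function(rois, role) {
  stopifnot(inherits(rois, "roi_set"))
  if (!role %in% names(rois$dictionary))
    stop(sprintf("unknown ROI role '%s'", role), call. = FALSE)
  rois$labels == rois$dictionary[[role]]
}
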