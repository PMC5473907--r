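#' Maternal oxygen challenge paradigm
#'
#' Describes the inspired-oxygen (FiO2) schedule of a hyperoxia challenge
#' acquisition: a normoxic baseline epoch, a hyperoxia epoch, and a
#' post-hyperoxia normoxic epoch. The default is the 10/10/10-minute
#' block design (room air, 100\% oxygen, room air).
#'
#' @param baseline_dur Baseline (normoxia) epoch duration, minutes.
#' @param hyperoxia_dur Hyperoxia epoch duration, minutes.
#' @param post_dur Post-hyperoxia (return to normoxia) epoch duration,
#'   minutes.
#' @param fio2_baseline Inspired oxygen fraction at baseline (room air).
#' @param fio2_hyperoxia Inspired oxygen fraction during the challenge.
#' @return An object of class `oxygen_paradigm`: a list with the epoch
#'   durations, FiO2 levels, cumulative epoch boundaries
#'   (`hyperoxia_start`, `hyperoxia_end`, `total_dur`, all minutes).
#' @examples
#' p <- oxygen_paradigm()
#' p$hyperoxia_start  # 10 min
#' p$total_dur        # 30 min
#' @export
oxygen_paradigm <- function(baseline_dur = 10, hyperoxia_dur = 10,
                            post_dur = 10, fio2_baseline = 0.21,
                            fio2_hyperoxia = 1.0) {
  if (!all(is.finite(c(baseline_dur, hyperoxia_dur, post_dur))) ||
      any(c(baseline_dur, hyperoxia_dur, post_dur) <= 0))
    stop("all epoch durations must be positive", call. = FALSE)
  if (fio2_hyperoxia <= fio2_baseline)
    stop("hyperoxia FiO2 must exceed baseline FiO2", call. = FALSE)
  structure(list(
    baseline_dur = baseline_dur,
    hyperoxia_dur = hyperoxia_dur,
    post_dur = post_dur,
    fio2_baseline = fio2_baseline,
    fio2_hyperoxia = fio2_hyperoxia,
    hyperoxia_start = baseline_dur,
    hyperoxia_end = baseline_dur + hyperoxia_dur,
    total_dur = baseline_dur + hyperoxia_dur + post_dur
  ), class = "oxygen_paradigm")
}

#' @exportS3Method base::print
print.oxygen_paradigm <- function(x, ...) {
  cat(sprintf(
    "Oxygen paradigm: %g / %g / %g min (FiO2 %.2f -> %.2f -> %.2f)\n",
    x$baseline_dur, x$hyperoxia_dur, x$post_dur,
    x$fio2_baseline, x$fio2_hyperoxia, x$fio2_baseline))
  invisible(x)
}

#' FiO2 level at given acquisition times
#'
#' @param paradigm An [oxygen_paradigm()].
#' @param t Acquisition times, minutes from scan start.
#' @return Numeric vector of inspired oxygen fractions.
#' @export
fio2_at <- function(paradigm, t) {
  stopifnot(inherits(paradigm, "oxygen_paradigm"))
  ifelse(t >= paradigm$hyperoxia_start & t < paradigm$hyperoxia_end,
         paradigm$fio2_hyperoxia, paradigm$fio2_baseline)
}
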