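#' Default run configuration
#'
#' Collects every tunable constant of the pipeline in one structure:
#' paradigm epoch durations, smoothing parameters, outlier threshold,
#' fit bounds and initialization grid, the TTP mode convention, and
#' resampling settings. Values can be overridden via a YAML config file
#' ([read_config()]) and, at the command line, by flags.
#'
#' @param ... Named overrides of top-level fields.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    paradigm = list(baseline_dur = 10, hyperoxia_dur = 10, post_dur = 10),
    smoothing = list(kernel_width = 5, sigma = 1.5, temporal_window = 10),
    outlier = list(threshold = 3, neighborhood = 2),
    fit = list(alpha_bounds = c(1, 20), beta_bounds = c(1, 10),
               delta_max_frac = 0.9, grid_n = c(4, 4, 4)),
    ttp_mode_convention = "as_printed",
    resampling = list(reps = 1000),
    seed = 1L
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  durs <- unlist(cfg$paradigm)
  if (any(durs <= 0)) stop("paradigm durations must be > 0", call. = FALSE)
  if (cfg$resampling$reps < 1) stop("resampling reps must be >= 1", call. = FALSE)
  if (cfg$outlier$threshold <= 0) stop("outlier threshold must be > 0", call. = FALSE)
  if (!cfg$ttp_mode_convention %in% c("as_printed", "standard_mode"))
    stop("unknown ttp_mode_convention", call. = FALSE)
  invisible(cfg)
}

#' Read a YAML run configuration
#'
#' Missing fields fall back to [run_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(run_config())
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Provenance record written next to every CLI output set.
write_provenance <- function(dir, cfg, seed, extra = list()) {
  rec <- c(list(
    package = "placentabold",
    version = as.character(utils::packageVersion("placentabold")),
    seed = seed,
    config = unclass(cfg)
  ), extra)
  jsonlite::write_json(rec, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(rec)
}

paradigm_from_config <- function(cfg) {
  oxygen_paradigm(cfg$paradigm$baseline_dur, cfg$paradigm$hyperoxia_dur,
                  cfg$paradigm$post_dur)
}
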