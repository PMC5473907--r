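#' Construct a list of pathology findings
#'
#' @param severity Character vector of severities, each one of
#'   `"minor"`, `"moderate"`, `"severe_listed"`.
#' @param name Optional finding names (free text), recycled.
#' @return A list of class `pathology_findings`.
#' @export
pathology_findings <- function(severity = character(), name = NULL) {
  allowed <- c("minor", "moderate", "severe_listed")
  bad <- setdiff(unique(severity), allowed)
  if (length(bad))
    stop(sprintf("unknown severity tag(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(name)) name <- severity
  structure(Map(function(n, s) list(name = n, severity = s),
                rep_len(name, length(severity)), severity),
            class = "pathology_findings")
}

#' Global 4-point placental histopathology score
#'
#' Scores a findings list on the clinical 4-point scale (1 = normal,
#' 4 = severely abnormal) from the counts of minor and moderate
#' findings:
#' no findings or one minor finding -> 1; two minor findings, or one
#' moderate finding -> 2; one minor plus one moderate -> 3; two or more
#' moderate findings, or any listed severe finding -> 4. Three minor
#' findings appear under both score 3 and score 4 in the printed scale;
#' the maximum applicable rule wins (score 4), and any combination not
#' covered by a printed sentence resolves to the maximum of the
#' applicable rules (attribute `extrapolated` marks such cases).
#'
#' @param findings A [pathology_findings()] list (may be empty), or a
#'   character vector of severity tags.
#' @return Integer score in 1..4, with attribute `extrapolated`.
#' @examples
#' pathology_score(pathology_findings("minor"))             # 1
#' pathology_score(pathology_findings(c("minor", "minor"))) # 2
#' pathology_score(pathology_findings(c("minor", "moderate"))) # 3
#' @export
pathology_score <- function(findings) {
  if (is.character(findings)) findings <- pathology_findings(findings)
  sev <- vapply(findings, function(f) f$severity, character(1))
  bad <- setdiff(unique(sev), c("minor", "moderate", "severe_listed"))
  if (length(bad))
    stop(sprintf("unknown severity tag(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  m <- sum(sev == "minor"); M <- sum(sev == "moderate")
  severe <- any(sev == "severe_listed")
  score <- 1L; extrapolated <- FALSE
  if (severe || M >= 2 || m >= 3) {
    score <- 4L
  } else if ((m >= 1 && M == 1)) {
    score <- 3L
  } else if (m == 2 || M == 1) {
    score <- 2L
  } else if (m <= 1 && M == 0) {
    score <- 1L
  }
  # combinations beyond the printed sentences (e.g. many minors) are
  # already covered by the max rule above; mark the ambiguous 3-minor
  # case and anything with > 3 findings as extrapolated
  if ((m == 3 && M == 0) || length(sev) > 3) extrapolated <- TRUE
  attr(score, "extrapolated") <- extrapolated
  score
}

#' Classify a fetus as SGA or AGA by birth-weight percentile
#'
#' Small-for-gestational-age is defined as a birth weight at or below
#' the 10th percentile; above that is appropriate-for-gestational-age.
#'
#' @param weight_percentile Percentile in `[0, 100]`.
#' @return `"SGA"` or `"AGA"` (vectorized).
#' @examples
#' classify_sga(10)    # "SGA" (boundary included)
#' classify_sga(10.1)  # "AGA"
#' @export
classify_sga <- function(weight_percentile) {
  if (any(!is.finite(weight_percentile)) ||
      any(weight_percentile < 0) || any(weight_percentile > 100))
    stop("percentile must lie in [0, 100]", call. = FALSE)
  ifelse(weight_percentile <= 10, "SGA", "AGA")
}

#' Birth-weight discordance of a twin pair
#'
#' The absolute co-twin weight difference divided by the weight of the
#' larger twin: `|w_a - w_b| / max(w_a, w_b)`, in `[0, 1)`.
#'
#' @param w_a,w_b Birth weights, grams (> 0).
#' @return Discordance fraction.
#' @examples
#' birth_weight_discordance(2000, 1600)  # 0.20
#' @export
birth_weight_discordance <- function(w_a, w_b) {
  if (any(!is.finite(c(w_a, w_b))) || any(c(w_a, w_b) <= 0))
    stop("weights must be positive", call. = FALSE)
  abs(w_a - w_b) / pmax(w_a, w_b)
}

#' Score a findings table into twin records
#'
#' Reads rows (pair_id, twin, finding, severity), aggregates per fetus
#' and attaches the 4-point pathology score.
#'
#' @param findings_df data.frame with columns `pair_id`, `twin`,
#'   `finding`, `severity` (empty `severity` rows mean no findings).
#' @return data.frame with one row per fetus: pair_id, twin, findings,
#'   pathology_score.
#' @export
score_findings_table <- function(findings_df) {
  req <- c("pair_id", "twin", "severity")
  if (!all(req %in% names(findings_df)))
    stop("findings table needs columns pair_id, twin, severity",
         call. = FALSE)
  key <- interaction(findings_df$pair_id, findings_df$twin, drop = TRUE)
  out <- lapply(split(findings_df, key), function(g) {
    sev <- g$severity[nzchar(g$severity)]
    data.frame(pair_id = g$pair_id[1], twin = g$twin[1],
               findings = paste(sev, collapse = ";"),
               pathology_score = as.integer(
                 pathology_score(pathology_findings(sev))))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
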