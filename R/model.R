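#' Gamma-convolution oxygenation response model
#'
#' Evaluates the phenomenological model of the regional BOLD oxygenation
#' response: a unit step in inspired oxygen convolved with a gamma kernel.
#' With the kernel normalized to unit area the convolution is the
#' regularized lower incomplete gamma function, so the predicted
#' delta-R2* curve is
#' \deqn{C_1 + C_2 \, P(\alpha, (t - t_{on})/\beta)}
#' for \eqn{t \ge t_{on}} and \eqn{C_1} before, where
#' \eqn{P} is the regularized gamma CDF, \eqn{t_{on}} is the response
#' onset, \eqn{C_1} the baseline offset (s^-1) and \eqn{C_2} the plateau
#' amplitude (s^-1). The curve is monotone nondecreasing and tends to
#' \eqn{C_1 + C_2}.
#'
#' When a paradigm is supplied the onset is `paradigm$hyperoxia_start +
#' delta`, i.e. the oxygen-arrival delay `delta` is measured from
#' hyperoxia onset. With `paradigm = NULL` the onset is `delta` itself
#' (times already relative to hyperoxia onset).
#'
#' @param params List or named vector with elements `alpha`, `beta`
#'   (gamma shape/scale, `alpha >= 1`, `beta >= 1` with time in minutes),
#'   `delta` (delay, minutes, `>= 0`), `c1` (baseline offset, s^-1),
#'   `c2` (plateau amplitude, s^-1).
#' @param t Nondecreasing time vector, minutes.
#' @param paradigm An [oxygen_paradigm()] or NULL.
#' @return Predicted delta-R2* at `t`, s^-1.
#' @examples
#' p <- list(alpha = 1, beta = 2, delta = 0, c1 = 0, c2 = 10)
#' model_eval(p, t = 2)   # 10 * (1 - exp(-1))
#' @export
model_eval <- function(params, t, paradigm = NULL) {
  params <- as.list(params)
  alpha <- params$alpha; beta <- params$beta; delta <- params$delta
  c1 <- params$c1; c2 <- params$c2
  if (!is.finite(alpha) || alpha < 1 || !is.finite(beta) || beta < 1)
    stop("gamma parameters require alpha >= 1 and beta >= 1", call. = FALSE)
  if (!is.finite(delta) || delta < 0)
    stop("delay delta must be nonnegative", call. = FALSE)
  if (is.unsorted(t)) stop("t must be nondecreasing", call. = FALSE)
  onset <- if (is.null(paradigm)) delta else paradigm$hyperoxia_start + delta
  c1 + c2 * gamma_step_response(t - onset, alpha, beta)
}

# Unit step convolved with a unit-area gamma(alpha, scale beta) kernel,
# as a function of elapsed time since onset; 0 for elapsed <= 0.
gamma_step_response <- function(elapsed, alpha, beta) {
  out <- numeric(length(elapsed))
  pos <- elapsed > 0
  out[pos] <- stats::pgamma(elapsed[pos], shape = alpha, scale = beta)
  out
}

#' Time-To-Plateau from gamma model parameters
#'
#' Derives TTP (minutes from hyperoxia onset) from the gamma parameters
#' and the oxygen-arrival delay as `delta + tau`, where `tau` is the
#' kernel mode. Two conventions for the mode are provided:
#' `"as_printed"` uses `tau = alpha * (beta - 1)`; `"standard_mode"`
#' uses the textbook gamma-density mode `tau = (alpha - 1) * beta`.
#'
#' @param alpha,beta Gamma parameters (`alpha >= 1`, `beta >= 1`).
#' @param delta Delay, minutes (`>= 0`).
#' @param convention `"as_printed"` (default) or `"standard_mode"`.
#' @return TTP in minutes.
#' @examples
#' ttp_from_params(3, 2, 1.5)                   # 4.5
#' ttp_from_params(3, 2, 1.5, "standard_mode")  # 5.5
#' @export
ttp_from_params <- function(alpha, beta, delta,
                            convention = c("as_printed", "standard_mode")) {
  convention <- match.arg(convention)
  if (any(alpha < 1) || any(beta < 1) || any(delta < 0))
    stop("require alpha >= 1, beta >= 1, delta >= 0", call. = FALSE)
  tau <- switch(convention,
                as_printed = alpha * (beta - 1),
                standard_mode = (alpha - 1) * beta)
  delta + tau
}

#' Full-paradigm response curve including post-hyperoxia return
#'
#' Extends [model_eval()] past the end of hyperoxia with a mirrored gamma
#' decay: after hyperoxia ends the response relaxes from its
#' end-of-hyperoxia value toward `c1 + c2_post` following
#' `1 - P(alpha_r, elapsed/beta_r)`. `c2_post = 0` returns to baseline;
#' a negative `c2_post` models the post-hyperoxia undershoot seen in the
#' organs of growth-restricted fetuses.
#'
#' @param params Model parameters as in [model_eval()]; optional elements
#'   `alpha_r`, `beta_r` (recovery kernel, default = rise kernel) and
#'   `c2_post` (post-phase asymptote relative to `c1`, s^-1, default 0).
#' @param t Time vector, minutes from scan start.
#' @param paradigm An [oxygen_paradigm()].
#' @return delta-R2* curve at `t`, s^-1.
#' @export
response_curve <- function(params, t, paradigm) {
  stopifnot(inherits(paradigm, "oxygen_paradigm"))
  params <- as.list(params)
  alpha_r <- params$alpha_r %||% params$alpha
  beta_r <- params$beta_r %||% params$beta
  c2_post <- params$c2_post %||% 0
  y <- model_eval(params, pmin(t, paradigm$hyperoxia_end), paradigm)
  post <- t > paradigm$hyperoxia_end
  if (any(post)) {
    v_end <- model_eval(params, paradigm$hyperoxia_end, paradigm)
    g <- gamma_step_response(t[post] - paradigm$hyperoxia_end,
                             max(alpha_r, 1), max(beta_r, 1))
    y[post] <- (params$c1 + c2_post) + (v_end - params$c1 - c2_post) * (1 - g)
  }
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
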