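#' Construct a transient velocity perturbation event
#'
#' A perturbation is a 1-s additive velocity transient injected into the
#' true self-motion (the process-noise term of the control dynamics). Its
#' linear and angular amplitudes are drawn independently and uniformly from
#' the configured ranges (default -2..2 m/s and -120..120 deg/s), and its
#' onset uniformly from 0-1 s after movement onset. The velocity profile is
#' either Gaussian (sigma = 0.2 s, peak at the window midpoint, truncated at
#' the window edges) or an isosceles triangle peaking at the midpoint.
#'
#' @param config A [sim_config()].
#' @param onset,amp_linear,amp_angular Optional fixed values overriding the
#'   random draws (s, m/s, deg/s).
#' @param profile Optional profile override (`"gaussian"`/`"triangular"`).
#' @return An object of class `firefly_perturbation`: list with `onset`,
#'   `duration`, `profile`, `amp_linear`, `amp_angular`.
#' @seealso [perturbation_velocity()]
#' @export
#' @examples
#' set.seed(1)
#' make_perturbation(sim_config())
make_perturbation <- function(config, onset = NULL, amp_linear = NULL,
                              amp_angular = NULL, profile = NULL) {
  validate_config(config)
  ev <- list(
    onset = if (is.null(onset)) {
      stats::runif(1, config$pert_onset_range[1], config$pert_onset_range[2])
    } else onset,
    duration = config$pert_duration,
    profile = if (is.null(profile)) config$pert_profile else profile,
    amp_linear = if (is.null(amp_linear)) {
      stats::runif(1, config$pert_amp_linear_range[1],
                   config$pert_amp_linear_range[2])
    } else amp_linear,
    amp_angular = if (is.null(amp_angular)) {
      stats::runif(1, config$pert_amp_angular_range[1],
                   config$pert_amp_angular_range[2])
    } else amp_angular
  )
  class(ev) <- "firefly_perturbation"
  ev
}

#' Perturbation velocity at given times
#'
#' Evaluates the perturbation's (linear, angular) velocity at times `t`
#' measured from movement onset. Zero outside the perturbation window.
#' The triangular profile ramps linearly from zero at the onset to the full
#' amplitude at the window midpoint and back to zero; the Gaussian profile
#' is `amp * exp(-(t - mid)^2 / (2 * 0.2^2))`, truncated (not renormalized)
#' at the window edges.
#'
#' @param event A `firefly_perturbation` (see [make_perturbation()]).
#' @param t Time(s) in s from movement onset (vectorized).
#' @return A list with numeric vectors `linear` (m/s) and `angular` (deg/s).
#' @export
#' @examples
#' ev <- make_perturbation(sim_config(pert_profile = "triangular"),
#'                         onset = 0.2, amp_linear = 2, amp_angular = 0)
#' perturbation_velocity(ev, 0.7)$linear  # peak: 2 m/s
perturbation_velocity <- function(event, t) {
  stopifnot(inherits(event, "firefly_perturbation"), all(t >= 0))
  shape <- pert_shape(event, t)
  list(linear = event$amp_linear * shape, angular = event$amp_angular * shape)
}

## unit-amplitude profile shape, vectorized over t (s from movement onset)
pert_shape <- function(event, t) {
  u <- t - event$onset
  inside <- u >= 0 & u <= event$duration
  half <- event$duration / 2
  shape <- numeric(length(t))
  if (event$profile == "triangular") {
    shape[inside] <- 1 - abs(u[inside] - half) / half
  } else if (event$profile == "gaussian") {
    shape[inside] <- exp(-(u[inside] - half)^2 / (2 * 0.2^2))
  } else {
    stop("unknown perturbation profile: ", event$profile, call. = FALSE)
  }
  shape
}

#' @export
print.firefly_perturbation <- function(x, ...) {
  cat(sprintf(
    "<perturbation> %s, onset %.3f s, duration %g s, amp (%.3f m/s, %.2f deg/s)\n",
    x$profile, x$onset, x$duration, x$amp_linear, x$amp_angular))
  invisible(x)
}
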