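#' Dynamic response to perturbations
#'
#' Trial-averaged deviation of the subject's self-motion velocity from that
#' of a target-matched unperturbed trial, at time lags 0-2 s from
#' perturbation onset (6-ms steps), normalized by the perturbation
#' amplitude. The sign is flipped so that positive values denote steering
#' *against* the perturbation; an agent that ignores perturbations yields a
#' flat response at 0, while an idealized instant canceller reproduces the
#' normalized perturbation profile.
#'
#' By default the deviation is computed on the *controlled* velocity (gain
#' times joystick command), excluding the perturbation itself — including
#' it would mechanically imprint the perturbation profile and mask the
#' compensatory component. Set `velocity = "total"` for the alternative
#' reading (true self-motion including the perturbation).
#'
#' Trials are grouped by perturbation direction: for the linear component,
#' forward (`amp > 0`) vs backward; for the angular component, congruent vs
#' incongruent with the remaining target bearing at perturbation onset.
#' Trials with zero amplitude in the analyzed component are excluded (their
#' count is reported).
#'
#' @param perturbed List of perturbed `firefly_trial` records.
#' @param pool List of unperturbed `firefly_trial` records used for target
#'   matching.
#' @param component `"linear"` (m/s) or `"angular"` (deg/s).
#' @param velocity `"controlled"` (default) or `"total"`.
#' @param lag_max,lag_step Lag grid in s (defaults 2 and 0.006).
#' @return A data.frame of class `firefly_dynresp`: columns `lag` (s),
#'   `response` (dimensionless), `group`, `n_trials`; attribute
#'   `n_excluded` counts zero-amplitude trials dropped.
#' @export
dynamic_response <- function(perturbed, pool,
                             component = c("linear", "angular"),
                             velocity = c("controlled", "total"),
                             lag_max = 2, lag_step = 0.006) {
  component <- match.arg(component)
  velocity <- match.arg(velocity)
  lags <- seq(0, lag_max, by = lag_step)
  groups <- list()
  n_excluded <- 0L

  for (tr in perturbed) {
    ev <- tr$perturbation
    if (is.null(ev)) stop("unperturbed trial in `perturbed`", call. = FALSE)
    amp <- if (component == "linear") ev$amp_linear else ev$amp_angular
    if (abs(amp) < 1e-12) {
      n_excluded <- n_excluded + 1L
      next
    }
    m <- match_unperturbed(tr, pool)
    v_p <- velocity_at(tr, ev$onset + lags, component, velocity)
    v_m <- velocity_at(m, ev$onset + lags, component, velocity)
    resp <- -(v_p - v_m) / amp
    grp <- if (component == "linear") {
      if (amp > 0) "forward" else "backward"
    } else {
      if (sign(amp) == sign(bearing_at_onset(tr))) "congruent"
      else "incongruent"
    }
    groups[[grp]] <- c(groups[[grp]], list(resp))
  }
  if (n_excluded > 0) {
    message(n_excluded, " trial(s) with zero ", component,
            " amplitude excluded")
  }
  if (length(groups) == 0) {
    stop("no usable perturbed trials for component ", component,
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(groups), function(g) {
    mat <- do.call(rbind, groups[[g]])
    data.frame(lag = lags, response = colMeans(mat), group = g,
               n_trials = nrow(mat))
  }))
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("firefly_dynresp", class(out))
  out
}

## velocity of one component at times tau (s from movement onset), linearly
## interpolated; zero-held beyond the recorded series (the subject has
## stopped steering).
velocity_at <- function(trial, tau, component, velocity) {
  dt <- trial$config$dt
  G <- trial$config$gain_factor
  if (component == "linear") {
    v <- if (velocity == "controlled") G * trial$config$v_max * trial$ts$a_lin
         else trial$ts$s_lin
  } else {
    v <- if (velocity == "controlled") G * trial$config$w_max * trial$ts$a_ang
         else trial$ts$s_ang
  }
  onset_t <- if (is.na(trial$onset_time)) 0 else trial$onset_time
  t_rel <- trial$ts$t - onset_t
  stats::approx(t_rel, v, xout = tau, rule = 2)$y
}

## signed remaining target bearing (deg) at perturbation onset, from the
## recorded true pose (positive = target to the right of current heading)
bearing_at_onset <- function(trial) {
  ev <- trial$perturbation
  onset_t <- if (is.na(trial$onset_time)) 0 else trial$onset_time
  k <- which.min(abs(trial$ts$t - (onset_t + ev$onset)))
  txy <- polar_to_xy(trial$target[["r"]], trial$target[["theta"]])
  dx <- txy$x - trial$ts$x[k]
  dy <- txy$y - trial$ts$y[k]
  wrap_deg(rad2deg(atan2(dx, dy)) - trial$ts$heading[k])
}
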