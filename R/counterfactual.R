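#' Find the target-matched unperturbed trial
#'
#' For a perturbed trial, picks the unperturbed trial from `pool` whose
#' target position is most similar (minimum Euclidean distance between the
#' Cartesian target positions); ties are broken by the lowest trial id.
#' The pool should come from the same session and the same gain/density
#' condition, otherwise the counterfactual would be confounded.
#'
#' @param perturbed A `firefly_trial` carrying a perturbation.
#' @param pool A list of unperturbed `firefly_trial` records.
#' @return The matched `firefly_trial`, with attribute `match_distance` (m).
#' @export
match_unperturbed <- function(perturbed, pool) {
  if (length(pool) == 0) stop("empty unperturbed pool", call. = FALSE)
  if (any(vapply(pool, function(tr) !is.null(tr$perturbation), logical(1)))) {
    stop("pool contains perturbed trials", call. = FALSE)
  }
  pt <- polar_to_xy(perturbed$target[["r"]], perturbed$target[["theta"]])
  d <- vapply(pool, function(tr) {
    q <- polar_to_xy(tr$target[["r"]], tr$target[["theta"]])
    sqrt((q$x - pt$x)^2 + (q$y - pt$y)^2)
  }, numeric(1))
  ids <- vapply(pool, function(tr) tr$trial_id, integer(1))
  ## ties in the match distance (to numerical precision) break to the
  ## lowest trial id
  best <- which(d <= min(d) + 1e-12)
  best <- best[which.min(ids[best])]
  out <- pool[[best]]
  attr(out, "match_distance") <- d[best]
  out
}

#' Uncompensated-case counterfactual endpoint
#'
#' Simulates where a subject would have stopped had it not compensated for
#' a perturbation: the perturbation's linear and angular velocities are
#' added, preserving their timing relative to movement onset, to the
#' steering velocities of a target-matched unperturbed trial
#' (`v~ = v + alpha`, `w~ = w + beta`), and the summed velocity time series
#' of the whole trial is integrated to an endpoint. Perturbation samples
#' falling beyond the matched trial's duration extend the series with
#' zero-padded steering.
#'
#' @param perturbed A `firefly_trial` with a perturbation event.
#' @param matched The matched unperturbed trial (see [match_unperturbed()]).
#' @return A list of class `firefly_uncompensated`: `trial_id`,
#'   `matched_id`, `endpoint` (polar, m/deg), `error` (m, relative to the
#'   perturbed trial's target) and `match_distance` (m, `NA` when the
#'   matched trial was supplied directly).
#' @export
uncompensated_endpoint <- function(perturbed, matched) {
  ev <- perturbed$perturbation
  if (is.null(ev)) {
    stop("perturbed trial carries no perturbation event", call. = FALSE)
  }
  if (!is.null(matched$perturbation)) {
    stop("matched trial must be unperturbed", call. = FALSE)
  }
  dt <- matched$config$dt
  v <- matched$ts$s_lin
  w <- matched$ts$s_ang
  onset_t <- matched$onset_time
  if (is.na(onset_t)) onset_t <- 0
  ## extend so the full perturbation window fits
  n_need <- ceiling((onset_t + ev$onset + ev$duration) / dt) + 1L
  if (n_need > length(v)) {
    v <- c(v, numeric(n_need - length(v)))
    w <- c(w, numeric(n_need - length(w)))
  }
  t_rel <- (seq_along(v) - 1L) * dt - onset_t
  shape <- pert_shape(ev, t_rel)  # zero outside the window
  traj <- integrate_pose(v + ev$amp_linear * shape,
                         w + ev$amp_angular * shape, dt)
  endpoint <- final_polar(traj)
  err <- trial_error(perturbed$target[["r"]], perturbed$target[["theta"]],
                     endpoint[["r"]], endpoint[["theta"]])
  structure(list(
    trial_id = perturbed$trial_id,
    matched_id = matched$trial_id,
    endpoint = endpoint,
    error = unname(err),
    match_distance = attr(matched, "match_distance") %||% NA_real_
  ), class = "firefly_uncompensated")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Uncompensated endpoints for all perturbed trials of a session
#'
#' Applies [match_unperturbed()] and [uncompensated_endpoint()] to every
#' perturbed trial, matching within the session's unperturbed trials of the
#' same gain and density condition.
#'
#' @param session A `firefly_session` (or plain list of `firefly_trial`).
#' @return A data.frame with one row per perturbed trial: `trial_id`,
#'   `matched_id`, `match_distance`, `endpoint_r`, `endpoint_theta`,
#'   `error`.
#' @export
session_uncompensated <- function(session) {
  trials <- if (inherits(session, "firefly_session")) session$trials
            else session
  is_pert <- vapply(trials, function(tr) !is.null(tr$perturbation),
                    logical(1))
  if (!any(is_pert)) stop("session has no perturbed trials", call. = FALSE)
  if (all(is_pert)) stop("session has no unperturbed pool", call. = FALSE)
  pool_all <- trials[!is_pert]
  cond <- function(tr) paste(tr$config$gain_factor, tr$config$density)
  pool_cond <- vapply(pool_all, cond, character(1))
  rows <- lapply(trials[is_pert], function(tr) {
    pool <- pool_all[pool_cond == cond(tr)]
    if (length(pool) == 0) {
      stop("no unperturbed trials in condition of trial ", tr$trial_id,
           call. = FALSE)
    }
    m <- match_unperturbed(tr, pool)
    uc <- uncompensated_endpoint(tr, m)
    data.frame(trial_id = uc$trial_id, matched_id = uc$matched_id,
               match_distance = uc$match_distance,
               endpoint_r = uc$endpoint[["r"]],
               endpoint_theta = uc$endpoint[["theta"]],
               error = uc$error)
  })
  do.call(rbind, rows)
}
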