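#' Per-trial summary table of a session
#'
#' One row per trial: ids, target coordinates, condition (gain, density,
#' flow duration), perturbation fields, endpoint coordinates, travel time,
#' mean speed, reward outcome and the per-trial RNG seed. This is the
#' tabular exchange format of the package; imported real data must be
#' mappable onto these columns.
#'
#' @param session A `firefly_session` or plain list of `firefly_trial`.
#' @return A data.frame.
#' @export
trials_table <- function(session) {
  trials <- if (inherits(session, "firefly_session")) session$trials
            else session
  do.call(rbind, lapply(trials, function(tr) {
    ev <- tr$perturbation
    data.frame(
      trial_id = tr$trial_id,
      target_r = tr$target[["r"]],
      target_theta = tr$target[["theta"]],
      gain = tr$config$gain_factor,
      density = tr$config$density,
      flow_duration = tr$config$flow_duration,
      perturbed = !is.null(ev),
      pert_onset = if (is.null(ev)) NA_real_ else ev$onset,
      pert_duration = if (is.null(ev)) NA_real_ else ev$duration,
      pert_profile = if (is.null(ev)) NA_character_ else ev$profile,
      pert_amp_linear = if (is.null(ev)) NA_real_ else ev$amp_linear,
      pert_amp_angular = if (is.null(ev)) NA_real_ else ev$amp_angular,
      endpoint_r = tr$endpoint[["r"]],
      endpoint_theta = tr$endpoint[["theta"]],
      error = tr$error,
      travel_time = tr$travel_time,
      mean_speed = tr$mean_speed,
      rewarded = tr$rewarded,
      valid = tr$valid,
      rng_seed = tr$seed
    )
  }))
}

#' Long-format time-series table of a session
#'
#' @param session A `firefly_session` or list of `firefly_trial`.
#' @return A data.frame with columns `trial_id`, `t`, `a_lin`, `a_ang`,
#'   `s_lin`, `s_ang`, `o_lin`, `o_ang`, `pert_lin`, `pert_ang`, `x`, `y`,
#'   `heading` (one row per trial per time step).
#' @export
timeseries_table <- function(session) {
  trials <- if (inherits(session, "firefly_session")) session$trials
            else session
  cols <- c("t", "a_lin", "a_ang", "s_lin", "s_ang", "o_lin", "o_ang",
            "pert_lin", "pert_ang", "x", "y", "heading")
  do.call(rbind, lapply(trials, function(tr) {
    cbind(trial_id = tr$trial_id, tr$ts[, cols])
  }))
}

#' Write a session to CSV files
#'
#' @param session A `firefly_session`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the two file paths (`trials`, `timeseries`).
#' @export
write_session <- function(session, dir, prefix = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_tr <- file.path(dir, paste0(prefix, "_trials.csv"))
  f_ts <- file.path(dir, paste0(prefix, "_timeseries.csv"))
  utils::write.csv(trials_table(session), f_tr, row.names = FALSE)
  utils::write.csv(timeseries_table(session), f_ts, row.names = FALSE)
  invisible(c(trials = f_tr, timeseries = f_ts))
}

required_trial_cols <- c(
  "trial_id", "target_r", "target_theta", "gain", "density", "perturbed",
  "pert_onset", "pert_duration", "pert_profile", "pert_amp_linear",
  "pert_amp_angular", "endpoint_r", "endpoint_theta", "travel_time",
  "rewarded"
)
required_ts_cols <- c("trial_id", "t", "a_lin", "a_ang", "s_lin", "s_ang",
                      "o_lin", "o_ang", "pert_lin", "pert_ang", "x", "y",
                      "heading")

#' Import a session from trial and time-series CSV tables
#'
#' Reconstructs `firefly_trial` records from the tabular exchange format
#' (see [trials_table()] / [timeseries_table()]). Rows violating the
#' record invariants — joystick commands outside \[-1, 1\], an irregular
#' time grid, an endpoint inconsistent with the integrated final pose —
#' are rejected, with reasons collected in the `rejected` attribute of the
#' result.
#'
#' @param trials_csv Path to the per-trial summary CSV.
#' @param timeseries_csv Path to the long-format time-series CSV.
#' @param config A [sim_config()] describing the session (defaults assumed
#'   where the tables are silent); its `dt` must match the time grid.
#' @param agent Optional [agent_params()] to attach to the records.
#' @return A list of `firefly_trial` (class `firefly_session`), with
#'   attribute `rejected`: a data.frame of trial ids and reasons.
#' @export
import_session <- function(trials_csv, timeseries_csv,
                           config = sim_config(), agent = agent_params()) {
  tr_tab <- utils::read.csv(trials_csv, stringsAsFactors = FALSE)
  ts_tab <- utils::read.csv(timeseries_csv, stringsAsFactors = FALSE)
  miss <- setdiff(required_trial_cols, names(tr_tab))
  if (length(miss) > 0) {
    stop("trials table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(required_ts_cols, names(ts_tab))
  if (length(miss) > 0) {
    stop("time-series table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  trials <- list()
  rejected <- data.frame(trial_id = integer(), reason = character())
  reject <- function(id, why) {
    rejected <<- rbind(rejected, data.frame(trial_id = id, reason = why))
  }

  for (i in seq_len(nrow(tr_tab))) {
    row <- tr_tab[i, ]
    ts <- ts_tab[ts_tab$trial_id == row$trial_id, , drop = FALSE]
    if (nrow(ts) == 0) { reject(row$trial_id, "no time series"); next }
    ts <- ts[order(ts$t), ]
    dts <- diff(ts$t)
    if (nrow(ts) > 1 &&
        (max(dts) - min(dts) > 1e-6 ||
         abs(mean(dts) - config$dt) > 1e-6)) {
      reject(row$trial_id, "irregular or mismatched time grid"); next
    }
    if (any(abs(ts$a_lin) > 1 + 1e-9) || any(abs(ts$a_ang) > 1 + 1e-9)) {
      reject(row$trial_id, "joystick command outside [-1, 1]"); next
    }
    cfg <- config
    cfg$gain_factor <- row$gain
    cfg$density <- row$density
    if ("flow_duration" %in% names(tr_tab) &&
        is.finite(row$flow_duration)) {
      cfg$flow_duration <- row$flow_duration
    }
    ev <- NULL
    if (isTRUE(row$perturbed)) {
      ev <- make_perturbation(cfg, onset = row$pert_onset,
                              amp_linear = row$pert_amp_linear,
                              amp_angular = row$pert_amp_angular,
                              profile = row$pert_profile)
      ev$duration <- row$pert_duration
    }
    endpoint <- final_polar(ts)
    if (abs(endpoint[["r"]] - row$endpoint_r) > 1e-6 ||
        (endpoint[["r"]] > 1e-9 &&
         abs(wrap_deg(endpoint[["theta"]] - row$endpoint_theta)) > 1e-6)) {
      reject(row$trial_id, "endpoint inconsistent with final pose"); next
    }
    moving <- which(ts$a_lin != 0 | ts$a_ang != 0)
    onset_time <- if (length(moving) > 0) ts$t[moving[1]] else NA_real_
    err <- trial_error(row$target_r, row$target_theta,
                       row$endpoint_r, row$endpoint_theta)
    trial <- structure(list(
      trial_id = as.integer(row$trial_id),
      target = c(r = row$target_r, theta = row$target_theta),
      config = cfg,
      agent = agent,
      perturbation = ev,
      ts = ts[, setdiff(names(ts), "trial_id")],
      endpoint = c(r = row$endpoint_r, theta = row$endpoint_theta),
      error = unname(err),
      travel_time = row$travel_time,
      mean_speed = if ("mean_speed" %in% names(tr_tab)) row$mean_speed
                   else NA_real_,
      rewarded = isTRUE(row$rewarded),
      valid = if ("valid" %in% names(tr_tab)) isTRUE(row$valid)
              else !is.na(onset_time),
      timeout = FALSE,
      onset_time = onset_time,
      seed = if ("rng_seed" %in% names(tr_tab)) row$rng_seed else NA_integer_
    ), class = "firefly_trial")
    trials <- c(trials, list(trial))
  }
  structure(list(trials = trials, config = config, agent = agent,
                 manipulation = "imported", seed = NA_integer_,
                 assignments = NULL),
            class = "firefly_session", rejected = rejected)
}
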