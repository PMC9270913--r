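#' Sample a target location
#'
#' Targets are uniformly distributed within the subject's field of view:
#' distance and angle are drawn independently and uniformly from the
#' configured ranges (1-4 m / +/-35 deg for the monkey task, 1-6 m /
#' +/-40 deg for the human task). A zero-width range pins that coordinate.
#'
#' @param config A [sim_config()].
#' @return Named numeric vector `c(r = , theta = )` (m, deg).
#' @export
#' @examples
#' set.seed(1)
#' sample_target(preset_config("monkey_default"))
sample_target <- function(config) {
  validate_config(config)
  c(r = stats::runif(1, config$target_r_range[1], config$target_r_range[2]),
    theta = stats::runif(1, config$target_theta_range[1],
                         config$target_theta_range[2]))
}

#' One step of the task's control dynamics
#'
#' Implements the first-order plant of the task: with inertia set to zero,
#' the true velocity is the gain-scaled joystick command plus process noise
#' plus any perturbation velocity, `s = G * (v_max * a_lin, w_max * a_ang)
#' + eta + pert`. The observation (optic flow) is the true velocity
#' corrupted by zero-mean Gaussian noise whose SD scales with ground-element
#' density as `sqrt(rho_ref / rho)` (`rho_ref` = 2.5); when the flow is off
#' (`flow_on = FALSE` or density 0) the observation is missing (`NA`).
#'
#' @param action Length-2 numeric joystick command in \[-1, 1\]^2
#'   (linear, angular).
#' @param config A [sim_config()].
#' @param pert_vel Length-2 perturbation velocity (m/s, deg/s), default 0.
#' @param process_noise Length-2 additive process noise (m/s, deg/s),
#'   default drawn from `config$process_noise_sd`.
#' @param flow_on Is optic flow present at this step?
#' @return List with `s` (true velocity, m/s and deg/s) and `o`
#'   (observation, or `c(NA, NA)` when flow is off).
#' @export
#' @examples
#' step_dynamics(c(1, 0), sim_config())$s  # (2 m/s, 0 deg/s)
step_dynamics <- function(action, config, pert_vel = c(0, 0),
                          process_noise = NULL, flow_on = TRUE) {
  if (any(abs(action) > 1 + 1e-12)) {
    stop("joystick command outside [-1, 1]", call. = FALSE)
  }
  if (is.null(process_noise)) {
    process_noise <- c(
      if (config$process_noise_sd[1] > 0)
        stats::rnorm(1, 0, config$process_noise_sd[1]) else 0,
      if (config$process_noise_sd[2] > 0)
        stats::rnorm(1, 0, config$process_noise_sd[2]) else 0
    )
  }
  G <- config$gain_factor
  s <- c(G * config$v_max * action[1] + process_noise[1] + pert_vel[1],
         G * config$w_max * action[2] + process_noise[2] + pert_vel[2])
  if (flow_on && config$density > 0) {
    sd_obs <- obs_noise_sd(config)
    o <- c(s[1] + if (sd_obs[1] > 0) stats::rnorm(1, 0, sd_obs[1]) else 0,
           s[2] + if (sd_obs[2] > 0) stats::rnorm(1, 0, sd_obs[2]) else 0)
  } else {
    o <- c(NA_real_, NA_real_)
  }
  list(s = s, o = o)
}

## observation-noise SD (linear m/s, angular deg/s) at the config's density
obs_noise_sd <- function(config) {
  if (config$density <= 0) return(c(Inf, Inf))
  config$obs_noise_base_sd * sqrt(2.5 / config$density)
}

#' Initial agent belief for a trial
#'
#' @param target Named vector `c(r = , theta = )` (m, deg).
#' @param config A [sim_config()].
#' @return A belief list: believed pose (`x`, `y` m, `heading` deg), the
#'   remembered target in start-frame Cartesian coordinates, and a `stopped`
#'   latch.
#' @export
make_belief <- function(target, config) {
  txy <- polar_to_xy(target[["r"]], target[["theta"]])
  list(x = 0, y = 0, heading = 0,
       target_x = txy$x, target_y = txy$y, stopped = FALSE)
}

## proportional controller on the believed state (scalar, rad internally).
## Turns hard before translating when the believed bearing error exceeds
## 30 deg. Commands drop to zero once believed distance < stop_distance;
## the agent re-engages only if the believed distance grows past a
## hysteresis margin of half the stop distance (e.g. a perturbation
## displaces it after stopping), so observation noise alone does not
## restart steering.
.controller <- function(bx, by, bh_rad, tx, ty, stopped, params) {
  dx <- tx - bx
  dy <- ty - by
  dist <- sqrt(dx * dx + dy * dy)
  if (stopped) {
    if (dist <= 1.5 * params$stop_distance) return(c(0, 0, 1))
  } else if (dist < params$stop_distance) {
    return(c(0, 0, 1))
  }
  be <- atan2(dx, dy) - bh_rad
  be <- (be + pi) %% (2 * pi) - pi    # wrap to (-pi, pi]
  a_ang <- max(-1, min(1, params$k_angular * be))
  abe_deg <- abs(be) * 180 / pi
  damp <- if (abe_deg <= 30) 1 else max(0, 1 - (abe_deg - 30) / 60)
  a_lin <- min(params$max_linear_command, params$k_linear * dist) * damp
  c(a_lin, a_ang, 0)
}

## believed velocity estimate (m/s, deg/s) from observation + efference copy.
## o_lin/o_ang NA => observation missing: the sensory channel falls back to
## the slow-speed prior shrunk toward zero information.
.belief_velocity <- function(o_lin, o_ang, a_lin, a_ang, params, config) {
  lam <- params$lambda_sensory
  eff_lin <- params$assumed_gain * config$v_max * a_lin
  eff_ang <- params$assumed_gain * config$w_max * a_ang
  if (is.na(o_lin)) {
    shrink <- params$prior_weight / (1 + params$prior_weight)
    o_lin <- shrink * params$prior_mean_speed
    o_ang <- 0
  }
  c(lam * o_lin + (1 - lam) * eff_lin,
    lam * o_ang + (1 - lam) * eff_ang)
}

#' One belief-and-control step of a steering agent
#'
#' First integrates the agent's velocity estimate into the believed pose,
#' then issues the next joystick command from the updated belief. The
#' velocity estimate mixes the sensory observation (weight
#' `lambda_sensory`) with the efference-copy prediction
#' `assumed_gain * (v_max * a_lin, w_max * a_ang)` (weight
#' `1 - lambda_sensory`). A missing observation (optic flow off) is replaced
#' by the slow-speed prior shrunk toward zero information, which
#' under-estimates displacement and produces target overshoot.
#'
#' With `lambda_sensory = 1` and noiseless observations the believed pose
#' tracks the true pose exactly; with `lambda_sensory = 0` the belief
#' evolves as if the gain were `assumed_gain` and perturbations never
#' occurred.
#'
#' @param belief A belief list from [make_belief()] or a previous step.
#' @param observation Length-2 observed velocity (m/s, deg/s), `c(NA, NA)`
#'   or `NULL` when missing.
#' @param last_action The length-2 joystick command that produced the
#'   observation (use `c(0, 0)` on the first step).
#' @param params An [agent_params()].
#' @param config A [sim_config()].
#' @return List with the updated `belief` and the next `action`
#'   (length-2 in \[-1, 1\]^2).
#' @export
agent_step <- function(belief, observation, last_action, params, config) {
  if (is.null(observation)) observation <- c(NA_real_, NA_real_)
  sh <- .belief_velocity(observation[1], observation[2],
                         last_action[1], last_action[2], params, config)
  bh_rad <- deg2rad(belief$heading)
  belief$x <- belief$x + sh[1] * config$dt * sin(bh_rad)
  belief$y <- belief$y + sh[1] * config$dt * cos(bh_rad)
  bh_rad <- bh_rad + deg2rad(sh[2]) * config$dt
  belief$heading <- wrap_deg(rad2deg(bh_rad))
  act <- .controller(belief$x, belief$y, bh_rad,
                     belief$target_x, belief$target_y, belief$stopped, params)
  belief$stopped <- act[3] > 0
  list(belief = belief, action = act[1:2])
}

#' Simulate a single trial of the firefly task
#'
#' Runs the agent's belief/control loop against the task dynamics from the
#' origin (heading toward 0 deg) until the true linear speed stays below
#' `stop_speed_threshold` for `stop_hold` seconds after movement onset, or
#' `max_trial_duration` elapses. Records the full time series, the polar
#' endpoint, travel time, mean controlled speed and the reward outcome
#' (endpoint error within `reward_boundary`, 0.6 m by default).
#'
#' @param agent An [agent_params()].
#' @param config A [sim_config()].
#' @param target Optional target `c(r = , theta = )`; sampled from the
#'   config if omitted.
#' @param perturbation Optional `firefly_perturbation` to apply, or `TRUE`
#'   to draw one from the config.
#' @param seed Optional integer seed making the trial reproducible in
#'   isolation.
#' @param trial_id Integer identifier stored in the record.
#' @return An object of class `firefly_trial`; see Details.
#' @details The returned record holds `target`, snapshots of `config` and
#'   `agent`, the `perturbation` (or `NULL`), a time-series data.frame `ts`
#'   (columns `t`, `a_lin`, `a_ang`, `s_lin`, `s_ang`, `o_lin`, `o_ang`,
#'   `pert_lin`, `pert_ang`, `x`, `y`, `heading`, `b_x`, `b_y`,
#'   `b_heading`), the polar `endpoint`, `travel_time` (movement onset to
#'   stop, s), `mean_speed` (time-averaged absolute controlled linear
#'   velocity, m/s), `rewarded`, `valid` (`FALSE` if the agent never moved),
#'   `timeout`, `onset_time`, and the `seed`.
#' @export
#' @examples
#' tr <- simulate_trial(preset_agent("integrator"), sim_config(),
#'                      target = c(r = 2.5, theta = 10), seed = 7)
#' tr$endpoint
simulate_trial <- function(agent, config, target = NULL, perturbation = NULL,
                           seed = NULL, trial_id = 1L) {
  validate_config(config)
  stopifnot(inherits(agent, "firefly_agent"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(target)) target <- sample_target(config)
  if (isTRUE(perturbation)) perturbation <- make_perturbation(config)
  if (!is.null(perturbation) &&
      !inherits(perturbation, "firefly_perturbation")) {
    stop("perturbation must be NULL, TRUE or a firefly_perturbation",
         call. = FALSE)
  }

  dt <- config$dt
  n_max <- ceiling(config$max_trial_duration / dt)
  hold_steps <- max(1L, ceiling(config$stop_hold / dt))
  ang_stop_threshold <- config$stop_speed_threshold *
    config$w_max / config$v_max
  G <- config$gain_factor
  v_max <- config$v_max
  w_max <- config$w_max
  lam <- agent$lambda_sensory
  ag <- agent$assumed_gain
  pn_sd <- config$process_noise_sd
  has_obs_noise <- any(config$obs_noise_base_sd > 0) && config$density > 0
  sd_obs <- if (config$density > 0) obs_noise_sd(config) else c(NA, NA)
  prior_lin <- agent$prior_weight / (1 + agent$prior_weight) *
    agent$prior_mean_speed
  if (!is.null(agent$prior_cv) && agent$prior_cv > 0) {
    ## the trial's internal no-flow speed estimate: one mean-preserving
    ## lognormal draw around the prior
    sdlog <- sqrt(log(1 + agent$prior_cv^2))
    prior_lin <- prior_lin * exp(stats::rnorm(1, 0, sdlog) - sdlog^2 / 2)
  }
  txy <- polar_to_xy(target[["r"]], target[["theta"]])
  tx <- txy$x; ty <- txy$y

  a_lin <- numeric(n_max); a_ang <- numeric(n_max)
  s_lin <- numeric(n_max); s_ang <- numeric(n_max)
  o_lin <- rep(NA_real_, n_max); o_ang <- rep(NA_real_, n_max)
  p_lin <- numeric(n_max); p_ang <- numeric(n_max)
  xs <- numeric(n_max); ys <- numeric(n_max); hs <- numeric(n_max)
  bxs <- numeric(n_max); bys <- numeric(n_max); bhs <- numeric(n_max)

  cx <- 0; cy <- 0; ch <- 0          # true pose (rad heading)
  bx <- 0; by <- 0; bh <- 0          # believed pose
  stopped <- FALSE
  onset_k <- NA_integer_
  run <- 0L
  end_k <- n_max
  timeout <- TRUE

  for (k in seq_len(n_max)) {
    act <- .controller(bx, by, bh, tx, ty, stopped, agent)
    al <- act[1]; aa <- act[2]; stopped <- act[3] > 0
    if (is.na(onset_k) && (al != 0 || aa != 0)) onset_k <- k

    pl <- 0; pa <- 0
    if (!is.null(perturbation) && !is.na(onset_k)) {
      sh <- pert_shape(perturbation, (k - onset_k) * dt)
      pl <- perturbation$amp_linear * sh
      pa <- perturbation$amp_angular * sh
    }

    sl <- G * v_max * al + pl
    sa <- G * w_max * aa + pa
    if (pn_sd[1] > 0) sl <- sl + stats::rnorm(1, 0, pn_sd[1])
    if (pn_sd[2] > 0) sa <- sa + stats::rnorm(1, 0, pn_sd[2])

    flow_on <- config$density > 0 && (k - 1) * dt < config$flow_duration
    if (flow_on) {
      ol <- sl; oa <- sa
      if (has_obs_noise) {
        ol <- ol + stats::rnorm(1, 0, sd_obs[1])
        oa <- oa + stats::rnorm(1, 0, sd_obs[2])
      }
      sh_lin <- lam * ol + (1 - lam) * ag * v_max * al
      sh_ang <- lam * oa + (1 - lam) * ag * w_max * aa
    } else {
      ol <- NA_real_; oa <- NA_real_
      sh_lin <- lam * prior_lin + (1 - lam) * ag * v_max * al
      sh_ang <- (1 - lam) * ag * w_max * aa
    }

    ## believed pose (same Euler scheme as the true pose)
    bx <- bx + sh_lin * dt * sin(bh)
    by <- by + sh_lin * dt * cos(bh)
    bh <- bh + sh_ang * (pi / 180) * dt

    cx <- cx + sl * dt * sin(ch)
    cy <- cy + sl * dt * cos(ch)
    ch <- ch + sa * (pi / 180) * dt

    a_lin[k] <- al; a_ang[k] <- aa
    s_lin[k] <- sl; s_ang[k] <- sa
    o_lin[k] <- ol; o_ang[k] <- oa
    p_lin[k] <- pl; p_ang[k] <- pa
    xs[k] <- cx; ys[k] <- cy; hs[k] <- ch
    bxs[k] <- bx; bys[k] <- by; bhs[k] <- bh

    if (!is.na(onset_k)) {
      ## stationary = both components below the same fractional threshold
      ## (an agent turning in place has not finished its response)
      if (abs(sl) < config$stop_speed_threshold &&
          abs(sa) < ang_stop_threshold) run <- run + 1L else run <- 0L
      if (run >= hold_steps) {
        end_k <- k
        timeout <- FALSE
        break
      }
    }
  }

  valid <- !is.na(onset_k)
  stop_k <- if (valid) {
    if (timeout) end_k else max(onset_k, end_k - hold_steps)
  } else end_k
  travel_time <- if (valid) (stop_k - onset_k + 1L) * dt else NA_real_
  mean_speed <- if (valid) {
    mean(abs(G * v_max * a_lin[onset_k:stop_k]))
  } else NA_real_

  idx <- seq_len(end_k)
  ts <- data.frame(
    t = (idx - 1L) * dt,
    a_lin = a_lin[idx], a_ang = a_ang[idx],
    s_lin = s_lin[idx], s_ang = s_ang[idx],
    o_lin = o_lin[idx], o_ang = o_ang[idx],
    pert_lin = p_lin[idx], pert_ang = p_ang[idx],
    x = xs[idx], y = ys[idx], heading = wrap_deg(rad2deg(hs[idx])),
    b_x = bxs[idx], b_y = bys[idx], b_heading = wrap_deg(rad2deg(bhs[idx]))
  )
  endpoint <- final_polar(ts)
  err <- trial_error(target[["r"]], target[["theta"]],
                     endpoint[["r"]], endpoint[["theta"]])

  structure(list(
    trial_id = as.integer(trial_id),
    target = c(r = unname(target[["r"]]), theta = unname(target[["theta"]])),
    config = config,
    agent = agent,
    perturbation = perturbation,
    ts = ts,
    endpoint = endpoint,
    error = unname(err),
    travel_time = travel_time,
    mean_speed = mean_speed,
    rewarded = isTRUE(err <= config$reward_boundary),
    valid = valid,
    timeout = timeout,
    onset_time = if (valid) (onset_k - 1L) * dt else NA_real_,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "firefly_trial")
}

#' @export
print.firefly_trial <- function(x, ...) {
  cat(sprintf(
    "<firefly_trial %d> target (%.2f m, %.1f deg) -> endpoint (%.2f m, %.1f deg)\n",
    x$trial_id, x$target[["r"]], x$target[["theta"]],
    x$endpoint[["r"]], x$endpoint[["theta"]]))
  cat(sprintf("  error %.3f m, T %.2f s, mean speed %.2f m/s, %s%s\n",
              x$error, x$travel_time, x$mean_speed,
              if (x$rewarded) "rewarded" else "unrewarded",
              if (!is.null(x$perturbation)) ", perturbed" else ""))
  invisible(x)
}

## deterministic per-trial seed stream derived from a session seed
trial_seeds <- function(session_seed, n) {
  as.integer((as.double(session_seed) + 100003 * seq_len(n)) %% 2147483629 + 1)
}

#' Simulate a session of trials under an experimental manipulation
#'
#' Generates `n_trials` independent trials, with per-trial conditions
#' assigned as in the corresponding experiment:
#' \describe{
#'   \item{`"none"`}{all trials share `config`.}
#'   \item{`"perturbation"`}{each trial is independently perturbed with
#'     probability `pert_prob` (a random half by default).}
#'   \item{`"gain_blocks"`}{`gain_style = "blocks"` presents each gain in
#'     consecutive blocks of `n_trials / length(gains)` trials
#'     (the monkey design: separate blocks of 500 trials); `"per_trial"`
#'     draws the gain independently every trial (the human design).}
#'   \item{`"density"`}{ground-element density drawn per trial from
#'     `densities` (high/low interleaved).}
#'   \item{`"flow_duration"`}{optic-flow duration drawn per trial from
#'     `config$flow_duration_set`.}
#' }
#' A single session seed makes the whole session reproducible; per-trial
#' seeds are derived deterministically so any trial can be re-simulated in
#' isolation from its recorded seed and condition.
#'
#' @param agent An [agent_params()].
#' @param config A [sim_config()] used as the base condition.
#' @param n_trials Number of trials (>= 1).
#' @param manipulation One of `"none"`, `"perturbation"`, `"gain_blocks"`,
#'   `"density"`, `"flow_duration"`.
#' @param seed Session seed (integer).
#' @param gains Gain factors for the gain manipulation.
#' @param gain_style `"blocks"` or `"per_trial"`.
#' @param densities Density levels (elements/m^2) for the density
#'   manipulation.
#' @param pert_prob Probability that a trial is perturbed.
#' @return An object of class `firefly_session`: list of `firefly_trial`
#'   plus the session metadata.
#' @export
#' @examples
#' ses <- simulate_session(preset_agent("integrator"), sim_config(),
#'                         n_trials = 4, manipulation = "perturbation",
#'                         seed = 42)
#' trials_table(ses)[, c("trial_id", "perturbed", "rewarded")]
simulate_session <- function(agent, config, n_trials,
                             manipulation = c("none", "perturbation",
                                              "gain_blocks", "density",
                                              "flow_duration"),
                             seed = NULL,
                             gains = c(1, 1.5, 2),
                             gain_style = c("blocks", "per_trial"),
                             densities = c(2.5, 0.1),
                             pert_prob = 0.5) {
  manipulation <- match.arg(manipulation)
  gain_style <- match.arg(gain_style)
  validate_config(config)
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop("n_trials must be >= 1", call. = FALSE)
  }
  n_trials <- as.integer(n_trials)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  set.seed(seed)

  perturbed <- rep(FALSE, n_trials)
  gain <- rep(config$gain_factor, n_trials)
  density <- rep(config$density, n_trials)
  flow_dur <- rep(config$flow_duration, n_trials)
  if (manipulation == "perturbation") {
    perturbed <- stats::runif(n_trials) < pert_prob
  } else if (manipulation == "gain_blocks") {
    if (gain_style == "blocks") {
      block_size <- ceiling(n_trials / length(gains))
      gain <- gains[ceiling(seq_len(n_trials) / block_size)]
    } else {
      gain <- sample(gains, n_trials, replace = TRUE)
    }
  } else if (manipulation == "density") {
    density <- sample(densities, n_trials, replace = TRUE)
  } else if (manipulation == "flow_duration") {
    flow_dur <- sample(config$flow_duration_set, n_trials, replace = TRUE)
  }
  seeds <- trial_seeds(seed, n_trials)

  trials <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg_i <- config
    cfg_i$gain_factor <- gain[i]
    cfg_i$density <- density[i]
    cfg_i$flow_duration <- flow_dur[i]
    trials[[i]] <- simulate_trial(
      agent, cfg_i,
      perturbation = if (perturbed[i]) TRUE else NULL,
      seed = seeds[i], trial_id = i
    )
  }

  structure(list(
    trials = trials,
    config = config,
    agent = agent,
    manipulation = manipulation,
    seed = seed,
    assignments = data.frame(trial_id = seq_len(n_trials),
                             perturbed = perturbed, gain = gain,
                             density = density, flow_duration = flow_dur,
                             rng_seed = seeds)
  ), class = "firefly_session")
}

#' @export
print.firefly_session <- function(x, ...) {
  cat(sprintf("<firefly_session> %d trials, manipulation '%s', seed %s\n",
              length(x$trials), x$manipulation, format(x$seed)))
  invisible(x)
}
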