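#' Task simulation configuration
#'
#' Bundles the physical and experimental parameters of the firefly task:
#' control dynamics, joystick gain, optic-flow density, perturbation profile,
#' target distribution, reward criterion and trial termination rules.
#'
#' @param dt Simulation time step in seconds (display frame period).
#' @param v_max Maximum linear speed in m/s at gain 1 (full joystick
#'   deflection maps to `gain_factor * v_max`).
#' @param w_max Maximum angular speed in deg/s at gain 1.
#' @param gain_factor Joystick gain factor G; the experiment uses 1, 1.5, 2.
#' @param density Ground-element density rho in elements/m^2. The reference
#'   (high) density is 2.5; 0.1 is the sparse condition; 0 means no optic
#'   flow (observations missing).
#' @param process_noise_sd Length-2 numeric, SD of additive process noise on
#'   (linear m/s, angular deg/s) true velocity. The task's plant is
#'   noise-free by default; perturbations enter separately.
#' @param obs_noise_base_sd Length-2 numeric, SD of observation noise on
#'   (linear m/s, angular deg/s) at the reference density 2.5. Noise at
#'   density rho scales as `sqrt(2.5 / rho)` (Fisher information from
#'   independent flow elements is proportional to element count).
#' @param reward_boundary Radius in m of the reward zone around the target.
#' @param target_r_range Length-2 numeric, range of target distances in m.
#'   A zero-width range (e.g. `c(3, 3)`) pins the distance to that value.
#' @param target_theta_range Length-2 numeric, range of target angles in deg
#'   (positive = rightward of the initial heading).
#' @param pert_profile Perturbation velocity profile: `"gaussian"` (sigma =
#'   0.2 s, used with monkeys) or `"triangular"` (isosceles, used with
#'   humans).
#' @param pert_duration Perturbation duration in s (fixed at 1 in the task).
#' @param pert_amp_linear_range,pert_amp_angular_range Uniform ranges for
#'   the linear (m/s) and angular (deg/s) perturbation amplitudes.
#' @param pert_onset_range Uniform range (s after movement onset) for the
#'   perturbation onset.
#' @param flow_duration Seconds of optic flow from trial start, or `Inf` for
#'   unlimited. Observations are missing once the flow is off.
#' @param flow_duration_set Candidate flow durations (s) for the
#'   flow-duration manipulation.
#' @param max_trial_duration Hard trial cutoff in s.
#' @param stop_speed_threshold True linear speed (m/s) below which the
#'   subject counts as stationary.
#' @param stop_hold Seconds the speed must stay below threshold (after
#'   movement onset) for the trial to end.
#'
#' @return An object of class `firefly_config` (a validated list).
#' @seealso [preset_config()] for the named task presets,
#'   [agent_params()] for the behavioral strategy.
#' @export
#' @examples
#' cfg <- sim_config(gain_factor = 1.5)
#' cfg$gain_factor
sim_config <- function(dt = 1 / 60,
                       v_max = 2,
                       w_max = 90,
                       gain_factor = 1,
                       density = 2.5,
                       process_noise_sd = c(0, 0),
                       obs_noise_base_sd = c(0, 0),
                       reward_boundary = 0.6,
                       target_r_range = c(1, 4),
                       target_theta_range = c(-35, 35),
                       pert_profile = c("gaussian", "triangular"),
                       pert_duration = 1,
                       pert_amp_linear_range = c(-2, 2),
                       pert_amp_angular_range = c(-120, 120),
                       pert_onset_range = c(0, 1),
                       flow_duration = Inf,
                       flow_duration_set = c(0.5, 0.75, 1, 1.5),
                       max_trial_duration = 30,
                       stop_speed_threshold = 0.1,
                       stop_hold = 0.2) {
  pert_profile <- match.arg(pert_profile)
  cfg <- list(
    dt = dt, v_max = v_max, w_max = w_max, gain_factor = gain_factor,
    density = density,
    process_noise_sd = as.numeric(process_noise_sd),
    obs_noise_base_sd = as.numeric(obs_noise_base_sd),
    reward_boundary = reward_boundary,
    target_r_range = as.numeric(target_r_range),
    target_theta_range = as.numeric(target_theta_range),
    pert_profile = pert_profile,
    pert_duration = pert_duration,
    pert_amp_linear_range = as.numeric(pert_amp_linear_range),
    pert_amp_angular_range = as.numeric(pert_amp_angular_range),
    pert_onset_range = as.numeric(pert_onset_range),
    flow_duration = flow_duration,
    flow_duration_set = as.numeric(flow_duration_set),
    max_trial_duration = max_trial_duration,
    stop_speed_threshold = stop_speed_threshold,
    stop_hold = stop_hold
  )
  class(cfg) <- "firefly_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    inherits(cfg, "firefly_config"),
    is.numeric(cfg$dt), cfg$dt > 0,
    cfg$v_max > 0, cfg$w_max > 0,
    cfg$gain_factor > 0,
    cfg$density >= 0,
    length(cfg$process_noise_sd) == 2, all(cfg$process_noise_sd >= 0),
    length(cfg$obs_noise_base_sd) == 2, all(cfg$obs_noise_base_sd >= 0),
    cfg$reward_boundary > 0,
    length(cfg$target_r_range) == 2,
    length(cfg$target_theta_range) == 2,
    cfg$pert_duration > 0,
    cfg$max_trial_duration > 0,
    cfg$stop_speed_threshold > 0,
    cfg$stop_hold >= 0
  )
  if (cfg$target_r_range[1] > cfg$target_r_range[2] ||
      cfg$target_r_range[1] <= 0) {
    stop("invalid target_r_range: need 0 < min <= max", call. = FALSE)
  }
  if (cfg$target_theta_range[1] > cfg$target_theta_range[2]) {
    stop("invalid target_theta_range: need min <= max", call. = FALSE)
  }
  invisible(cfg)
}

#' Agent behavioral strategy parameters
#'
#' Parameterizes the navigation strategy of a simulated agent as a continuum
#' between two candidate strategies: pure dead reckoning from an internal
#' model of the control dynamics (`lambda_sensory = 0`: velocity is estimated
#' from the efference copy of the joystick command and an assumed gain), and
#' full optic-flow integration (`lambda_sensory = 1`: velocity is estimated
#' from the sensory observation, so gain changes and perturbations are
#' visible to the agent). The estimated velocity is integrated into a
#' believed pose that drives a proportional steering controller.
#'
#' @param lambda_sensory Sensory mixing weight in \[0, 1\].
#' @param assumed_gain Joystick gain assumed by the internal model
#'   (dead reckoning misestimates displacement when this differs from the
#'   true gain).
#' @param prior_mean_speed Mean of the slow-speed prior in m/s: the linear
#'   speed the agent assumes when optic flow is absent.
#' @param prior_weight Relative weight (>= 0) of the slow-speed prior against
#'   the zero-information estimate when the observation is missing; 0 means
#'   the agent believes it is stationary without flow.
#' @param prior_cv Trial-to-trial coefficient of variation of the no-flow
#'   speed estimate: each trial's fallback estimate is drawn once from a
#'   mean-preserving lognormal around the prior (an internal speed signal
#'   without sensory input is noisy). 0 (default) makes the fallback
#'   deterministic.
#' @param k_angular Proportional gain mapping believed bearing error (rad)
#'   to the angular joystick command.
#' @param k_linear Proportional gain mapping believed remaining distance (m)
#'   to the linear joystick command.
#' @param max_linear_command Cap on the linear joystick deflection in
#'   (0, 1\]: the agent's preferred cruise deflection. 1 pins the stick at
#'   full speed; 0.5 gives the field-typical ~1 m/s cruise pace at gain 1.
#' @param stop_distance Believed distance (m) at which the agent stops
#'   steering.
#'
#' @return An object of class `firefly_agent` (a validated list).
#' @seealso [preset_agent()]
#' @export
#' @examples
#' dead_reckoner <- agent_params(lambda_sensory = 0, assumed_gain = 1)
agent_params <- function(lambda_sensory = 1,
                         assumed_gain = 1,
                         prior_mean_speed = 0.3,
                         prior_weight = 2,
                         prior_cv = 0,
                         k_angular = 3,
                         k_linear = 2,
                         max_linear_command = 1,
                         stop_distance = 0.3) {
  par <- list(
    lambda_sensory = lambda_sensory,
    assumed_gain = assumed_gain,
    prior_mean_speed = prior_mean_speed,
    prior_weight = prior_weight,
    prior_cv = prior_cv,
    k_angular = k_angular,
    k_linear = k_linear,
    max_linear_command = max_linear_command,
    stop_distance = stop_distance
  )
  class(par) <- "firefly_agent"
  stopifnot(
    par$lambda_sensory >= 0, par$lambda_sensory <= 1,
    par$assumed_gain > 0,
    par$prior_mean_speed >= 0,
    par$prior_weight >= 0,
    par$prior_cv >= 0,
    par$k_angular > 0, par$k_linear > 0,
    par$max_linear_command > 0, par$max_linear_command <= 1,
    par$stop_distance >= 0
  )
  par
}

preset_file <- function() {
  system.file("extdata", "presets.yaml", package = "fireflynav",
              mustWork = TRUE)
}

#' Named task and agent presets
#'
#' Presets are stored as a structured text (YAML) file shipped with the
#' package and can be extended by pointing `file` at a user file with the
#' same layout. `preset_config()` returns a [sim_config()] and
#' `preset_agent()` an [agent_params()].
#'
#' Available config presets: `"monkey_default"` (targets 1-4 m, +/-35 deg,
#' Gaussian perturbation profile), `"human_default"` (targets 1-6 m,
#' +/-40 deg, triangular profile), `"human_flow"` (targets fixed at 3 m,
#' +/-30 deg, for the flow-duration manipulation). Agent presets:
#' `"integrator"` (lambda = 1), `"dead_reckoner"` (lambda = 0),
#' `"ideal"` (lambda = 1 with a tight stopping distance, approximating an
#' ideal path integrator), `"flow_prior"` (partial integration with a
#' slow-speed prior, for flow-duration runs).
#'
#' @param name Preset name.
#' @param file Optional path to an alternative preset YAML file.
#' @param ... Overrides passed to [sim_config()] / [agent_params()].
#' @return A `firefly_config` or `firefly_agent`.
#' @export
#' @examples
#' cfg <- preset_config("monkey_default", gain_factor = 2)
preset_config <- function(name, ..., file = preset_file()) {
  presets <- yaml::read_yaml(file)$config
  if (!name %in% names(presets)) {
    stop("unknown config preset: ", name, call. = FALSE)
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(sim_config, args)
}

#' @rdname preset_config
#' @export
preset_agent <- function(name, ..., file = preset_file()) {
  presets <- yaml::read_yaml(file)$agent
  if (!name %in% names(presets)) {
    stop("unknown agent preset: ", name, call. = FALSE)
  }
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(agent_params, args)
}

#' @export
print.firefly_config <- function(x, ...) {
  cat("<firefly_config>\n")
  cat(sprintf("  dt=%.4g s, v_max=%g m/s, w_max=%g deg/s, gain=%g\n",
              x$dt, x$v_max, x$w_max, x$gain_factor))
  cat(sprintf("  density=%g el/m^2, obs noise base sd=(%g m/s, %g deg/s)\n",
              x$density, x$obs_noise_base_sd[1], x$obs_noise_base_sd[2]))
  cat(sprintf("  targets: r in [%g, %g] m, theta in [%g, %g] deg\n",
              x$target_r_range[1], x$target_r_range[2],
              x$target_theta_range[1], x$target_theta_range[2]))
  cat(sprintf("  perturbation: %s profile, %g s\n",
              x$pert_profile, x$pert_duration))
  invisible(x)
}

#' @export
print.firefly_agent <- function(x, ...) {
  cat("<firefly_agent>\n")
  cat(sprintf("  lambda_sensory=%g, assumed_gain=%g\n",
              x$lambda_sensory, x$assumed_gain))
  cat(sprintf("  slow-speed prior: mean=%g m/s, weight=%g\n",
              x$prior_mean_speed, x$prior_weight))
  cat(sprintf("  controller: k_angular=%g, k_linear=%g, stop at %g m\n",
              x$k_angular, x$k_linear, x$stop_distance))
  invisible(x)
}
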