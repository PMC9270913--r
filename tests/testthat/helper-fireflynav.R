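# Shared fixtures and independent oracles for the test suite.

# noiseless task configuration used throughout
quiet_config <- function(...) sim_config(obs_noise_base_sd = c(0, 0), ...)

# Independent AUC oracle: the trapezoidal area under the staircase ROC
# equals the probability-with-ties U-statistic
#   mean over shuffled errors s of (P(A <= s) + P(A < s)) / 2,
# computed here directly from the two error samples.
auc_oracle <- function(errors, shuffled_errors) {
  mean(vapply(shuffled_errors, function(s) {
    (mean(errors <= s) + mean(errors < s)) / 2
  }, numeric(1)))
}

# Build a minimal firefly_trial record from a controlled-velocity plan
# (linear m/s, angular deg/s), for metric tests that need hand-crafted
# trials. The true velocity is the controlled velocity plus the
# perturbation (evaluated on the same grid, anchored at t = 0).
toy_trial <- function(v_ctrl, w_ctrl, target = c(r = 3, theta = 0),
                      config = quiet_config(), perturbation = NULL,
                      trial_id = 1L) {
  n <- length(v_ctrl)
  dt <- config$dt
  t <- (seq_len(n) - 1) * dt
  p_lin <- numeric(n)
  p_ang <- numeric(n)
  if (!is.null(perturbation)) {
    pv <- perturbation_velocity(perturbation, t)
    p_lin <- pv$linear
    p_ang <- pv$angular
  }
  s_lin <- v_ctrl + p_lin
  s_ang <- w_ctrl + p_ang
  traj <- integrate_pose(s_lin, s_ang, dt)
  G <- config$gain_factor
  ts <- data.frame(
    t = t,
    a_lin = v_ctrl / (G * config$v_max),
    a_ang = w_ctrl / (G * config$w_max),
    s_lin = s_lin, s_ang = s_ang,
    o_lin = s_lin, o_ang = s_ang,
    pert_lin = p_lin, pert_ang = p_ang,
    x = traj$x, y = traj$y, heading = traj$heading
  )
  endpoint <- final_polar(traj)
  structure(list(
    trial_id = as.integer(trial_id),
    target = target,
    config = config,
    agent = agent_params(),
    perturbation = perturbation,
    ts = ts,
    endpoint = endpoint,
    error = unname(trial_error(target[["r"]], target[["theta"]],
                               endpoint[["r"]], endpoint[["theta"]])),
    travel_time = n * dt,
    mean_speed = mean(abs(v_ctrl)),
    rewarded = NA,
    valid = TRUE,
    timeout = FALSE,
    onset_time = 0,  # toys are aligned to trial start by construction
    seed = NA_integer_
  ), class = "firefly_trial")
}

# random monkey-style target/endpoint tables for ROC tests
random_polar <- function(n, r_range = c(1, 4), th_range = c(-35, 35)) {
  data.frame(r = stats::runif(n, r_range[1], r_range[2]),
             theta = stats::runif(n, th_range[1], th_range[2]))
}
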