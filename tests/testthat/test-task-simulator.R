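test_that("targets are uniform within the configured field of view", {
  cfg <- preset_config("monkey_default")
  set.seed(11)
  tg <- replicate(1e4, sample_target(cfg))
  expect_true(all(tg["r", ] >= 1 & tg["r", ] <= 4))
  expect_true(all(abs(tg["theta", ]) <= 35))
  # CLT bound: empirical means within 3 SE of the uniform midpoints
  expect_lt(abs(mean(tg["r", ]) - 2.5), 3 * (3 / sqrt(12)) / 100)
  expect_lt(abs(mean(tg["theta", ]) - 0), 3 * (70 / sqrt(12)) / 100)

  point <- sim_config(target_r_range = c(3, 3),
                      target_theta_range = c(0, 0))
  set.seed(1)
  expect_equal(sample_target(point), c(r = 3, theta = 0))
})

test_that("perturbation events have uniform amplitudes and onsets", {
  cfg <- preset_config("monkey_default")
  set.seed(7)
  evs <- replicate(1e4, make_perturbation(cfg), simplify = FALSE)
  al <- vapply(evs, `[[`, numeric(1), "amp_linear")
  aa <- vapply(evs, `[[`, numeric(1), "amp_angular")
  on <- vapply(evs, `[[`, numeric(1), "onset")
  expect_true(all(abs(al) <= 2) && all(abs(aa) <= 120))
  expect_true(all(on >= 0 & on <= 1))
  expect_lt(abs(mean(on) - 0.5), 3 * sqrt(1 / 12) / 100)
  expect_true(all(vapply(evs, `[[`, numeric(1), "duration") == 1))

  set.seed(42); e1 <- make_perturbation(cfg)
  set.seed(42); e2 <- make_perturbation(cfg)
  expect_identical(e1, e2)
})

test_that("perturbation velocity profiles have the stated shape", {
  cfg <- sim_config(pert_profile = "triangular")
  ev <- make_perturbation(cfg, onset = 0.3, amp_linear = 2,
                          amp_angular = -60)
  # peak at the window midpoint, zero outside
  expect_equal(perturbation_velocity(ev, 0.8)$linear, 2)
  expect_equal(perturbation_velocity(ev, 0.8)$angular, -60)
  expect_equal(unlist(perturbation_velocity(ev, 0.29)), c(linear = 0,
                                                          angular = 0))
  expect_equal(unlist(perturbation_velocity(ev, 1.31)), c(linear = 0,
                                                          angular = 0))
  # isosceles triangle of height 2 over 1 s integrates to 1 m
  tt <- seq(0, 2, by = 1e-4)
  expect_equal(sum(perturbation_velocity(ev, tt)$linear) * 1e-4, 1,
               tolerance = 1e-3)

  gv <- make_perturbation(sim_config(), onset = 0.5, amp_linear = 1.5,
                          amp_angular = 0, profile = "gaussian")
  expect_equal(perturbation_velocity(gv, 1.0)$linear, 1.5)
  # truncated Gaussian integral: amp * sigma * sqrt(2*pi) * (2*Phi(2.5) - 1)
  closed <- 1.5 * 0.2 * sqrt(2 * pi) * (2 * pnorm(0.5 / 0.2) - 1)
  expect_equal(sum(perturbation_velocity(gv, tt)$linear) * 1e-4, closed,
               tolerance = 1e-3)

  bad <- gv; bad$profile <- "square"
  expect_error(perturbation_velocity(bad, 0.5), "unknown")
})

test_that("plant dynamics follow gain-scaled commands with additive terms", {
  out <- step_dynamics(c(1, 0), quiet_config())
  expect_equal(out$s, c(2, 0))
  expect_equal(out$o, out$s)  # noiseless observation equals the state
  out2 <- step_dynamics(c(0.5, -1), quiet_config(gain_factor = 2))
  expect_equal(out2$s, c(2, -180))
  out3 <- step_dynamics(c(0.5, 0), quiet_config(),
                        pert_vel = c(1, 30))
  expect_equal(out3$s, c(2, 30))
  # no flow: observation missing
  expect_true(all(is.na(step_dynamics(c(1, 0), quiet_config(),
                                      flow_on = FALSE)$o)))
  expect_true(all(is.na(step_dynamics(c(1, 0),
                                      quiet_config(density = 0))$o)))
  expect_error(step_dynamics(c(1.5, 0), quiet_config()), "joystick")
})

test_that("full-sensory noiseless belief tracks the true pose exactly", {
  cfg <- quiet_config()
  ag <- preset_agent("integrator")
  ev <- make_perturbation(cfg, onset = 0.4, amp_linear = 1.5,
                          amp_angular = 60, profile = "gaussian")
  tr <- simulate_trial(ag, cfg, target = c(r = 3, theta = 20),
                       perturbation = ev, seed = 5)
  expect_lt(max(abs(tr$ts$b_x - tr$ts$x)), 1e-9)
  expect_lt(max(abs(tr$ts$b_y - tr$ts$y)), 1e-9)
  expect_lt(max(abs(tr$ts$b_heading - tr$ts$heading)), 1e-9)
})

test_that("open-loop agents ignore perturbations and true gain", {
  ag <- preset_agent("dead_reckoner")
  target <- c(r = 3, theta = -15)
  base <- simulate_trial(ag, quiet_config(), target = target, seed = 9)
  ev <- make_perturbation(quiet_config(), onset = 0.2, amp_linear = -2,
                          amp_angular = 100, profile = "triangular")
  pert <- simulate_trial(ag, quiet_config(), target = target,
                         perturbation = ev, seed = 9)
  gain2 <- simulate_trial(ag, quiet_config(gain_factor = 2),
                          target = target, seed = 9)
  n <- min(nrow(base$ts), nrow(pert$ts), nrow(gain2$ts))
  expect_equal(pert$ts$a_lin[1:n], base$ts$a_lin[1:n], tolerance = 1e-12)
  expect_equal(pert$ts$a_ang[1:n], base$ts$a_ang[1:n], tolerance = 1e-12)
  expect_equal(gain2$ts$a_lin[1:n], base$ts$a_lin[1:n], tolerance = 1e-12)
  # any steps beyond the common length are post-stop zeros
  expect_true(all(abs(pert$ts$a_lin[-(1:n)]) < 1e-12))
  expect_true(all(abs(gain2$ts$a_lin[-(1:n)]) < 1e-12))
})

test_that("dead reckoning with a misassumed gain halves believed motion", {
  # assumed gain 1, true gain 2, straight-ahead target: believed
  # displacement must be exactly half the true displacement at every step
  ag <- preset_agent("dead_reckoner")
  tr <- simulate_trial(ag, quiet_config(gain_factor = 2),
                       target = c(r = 2, theta = 0), seed = 3)
  expect_lt(max(abs(2 * tr$ts$b_y - tr$ts$y)), 1e-9)
  # endpoint overshoots by the gain ratio: G * (r - stop_distance), within
  # one control step of travel
  expect_equal(tr$endpoint[["r"]], 2 * (2 - ag$stop_distance),
               tolerance = 0.1)
  expect_equal(tr$endpoint[["theta"]], 0, tolerance = 1e-6)
})

test_that("perfect-information trials stop on target, perturbed or not", {
  cfg <- quiet_config()
  ag <- preset_agent("ideal")
  bound <- 1.5 * ag$stop_distance + cfg$v_max * cfg$dt
  set.seed(31)
  for (i in 1:12) {
    tgt <- sample_target(cfg)
    ev <- if (i %% 2 == 0) make_perturbation(cfg) else NULL
    tr <- simulate_trial(ag, cfg, target = tgt, perturbation = ev)
    expect_true(tr$valid)
    expect_lt(tr$error, bound + 1e-9)
    expect_true(all(abs(tr$ts$a_lin) <= 1 & abs(tr$ts$a_ang) <= 1))
  }
})

test_that("perturbation displacement is bookkept exactly on straight trials", {
  cfg <- quiet_config()
  ev <- make_perturbation(cfg, onset = 0.5, amp_linear = 1.2,
                          amp_angular = 0, profile = "triangular")
  tr <- simulate_trial(preset_agent("integrator"), cfg,
                       target = c(r = 3, theta = 0), perturbation = ev,
                       seed = 2)
  ctrl <- tr$config$gain_factor * tr$config$v_max * tr$ts$a_lin
  expect_equal(sum(tr$ts$s_lin - ctrl) * cfg$dt,
               sum(tr$ts$pert_lin) * cfg$dt, tolerance = 1e-12)
  # recorded endpoint is recomputable from the velocity series
  traj <- integrate_pose(tr$ts$s_lin, tr$ts$s_ang, cfg$dt)
  expect_equal(unname(final_polar(traj)), unname(tr$endpoint),
               tolerance = 1e-9)
})

test_that("an agent that cannot move is flagged, not silently kept", {
  # no flow from the start and a zero-information fallback: believed
  # position never advances, so the trial must time out
  cfg <- quiet_config(flow_duration = 0, max_trial_duration = 5)
  ag <- agent_params(lambda_sensory = 1, prior_weight = 0)
  tr <- simulate_trial(ag, cfg, target = c(r = 3, theta = 0), seed = 1)
  expect_true(tr$timeout)
  expect_equal(tr$travel_time, 5, tolerance = 0.01)
})
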