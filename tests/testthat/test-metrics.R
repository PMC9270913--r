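test_that("multiplicative bias is the no-intercept slope", {
  expect_equal(multiplicative_bias(1:3, 1:3, n_boot = 0)$slope, 1)
  expect_equal(multiplicative_bias(1:3, 2 * (1:3), n_boot = 0)$slope, 2)
  # closed form: sum(t*y)/sum(t^2) = 14.7 / 14
  expect_equal(multiplicative_bias(c(1, 2, 3), c(1.2, 1.8, 3.3),
                                   n_boot = 0)$slope, 14.7 / 14)
  set.seed(2)
  b <- multiplicative_bias(runif(50, 1, 4), runif(50, 1, 4) * 1.3 +
                             rnorm(50, 0, 0.2), n_boot = 500)
  expect_lte(b$ci_low, b$slope)
  expect_gte(b$ci_high, b$slope)
  expect_error(multiplicative_bias(c(0, 0), c(1, 2)), "all-zero")
  expect_error(multiplicative_bias(1:3, 1:2), "equal length")
})

test_that("ROC attains its analytic anchors", {
  set.seed(4)
  tg <- random_polar(100)
  expect_equal(roc_curve(tg, tg, n_shuffles = 5)$auc, 1)

  # worked example: actual errors (0.1, 0.4), one fixed shuffle (0.2, 0.3)
  roc <- roc_curve(errors = c(0.1, 0.4), shuffled_errors = c(0.2, 0.3))
  expect_equal(roc$boundary, c(0, 0.1, 0.2, 0.3, 0.4))
  expect_equal(roc$tpr, c(0, 0.5, 0.5, 0.5, 1))
  expect_equal(roc$fpr, c(0, 0, 0.5, 1, 1))
  expect_equal(roc$auc, 0.5)

  expect_error(roc_curve(random_polar(1), random_polar(1)), "2 trials")
})

test_that("ROC curves are valid staircases", {
  set.seed(9)
  tg <- random_polar(40)
  ep <- random_polar(40)
  roc <- roc_curve(tg, ep, n_shuffles = 7)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(tail(roc$tpr, 1), 1)
  expect_equal(tail(roc$fpr, 1), 1)
  expect_gte(roc$auc, 0)
  expect_lte(roc$auc, 1)
})

test_that("trapezoidal AUC equals the rank-statistic oracle", {
  set.seed(14)
  for (i in 1:12) {
    n <- sample(3:20, 1)
    tg <- random_polar(n)
    ep <- random_polar(n)
    err <- trial_error(tg$r, tg$theta, ep$r, ep$theta)
    sh <- unlist(lapply(1:4, function(s) {
      p <- sample.int(n)
      trial_error(tg$r[p], tg$theta[p], ep$r, ep$theta)
    }))
    got <- roc_curve(errors = err, shuffled_errors = sh)$auc
    expect_equal(got, auc_oracle(err, sh), tolerance = 1e-6)
  }
  # ties between actual and shuffled errors are split evenly
  got <- roc_curve(errors = c(1, 2), shuffled_errors = c(1, 2, 3))$auc
  expect_equal(got, auc_oracle(c(1, 2), c(1, 2, 3)), tolerance = 1e-12)
})

test_that("compensation indices satisfy their defining identities", {
  expect_equal(pci(0.85, 0.75, 0.85), 1)
  expect_equal(pci(0.75, 0.75, 0.85), 0)
  # group-mean AUCs of the perturbation conditions: (0.83-0.76)/(0.87-0.76)
  expect_equal(pci(0.83, 0.76, 0.87), 0.6364, tolerance = 1e-4)
  expect_error(pci(0.8, 0.9, 0.85), "undefined")

  expect_equal(gci(2, 1, 0.8, 0.8), 1)
  expect_equal(gci(2, 1, 1.6, 0.8), 0)
  expect_equal(gci(2, 1, 1.33, 1), 0.67, tolerance = 1e-10)
  expect_error(gci(1, 1, 0.5, 0.5), "undefined")
  expect_error(gci(2, 1, 0.5, 0), "undefined")

  # property sweep over valid inputs
  set.seed(6)
  for (i in 1:50) {
    a_uc <- runif(1, 0.4, 0.8)
    a_np <- a_uc + runif(1, 0.05, 0.2)
    expect_equal(pci(a_np, a_uc, a_np), 1)
    expect_equal(pci(a_uc, a_uc, a_np), 0)
    g <- sample(c(1.5, 2), 1)
    b0 <- runif(1, 0.5, 2)
    expect_equal(gci(g, 1, b0, b0), 1)
    expect_equal(gci(g, 1, g * b0, b0), 0)
  }
})

test_that("GCI timecourse tracks growing trial prefixes", {
  set.seed(10)
  n <- 500
  tg <- runif(n, 1, 4)
  # constant behavior: flat series, degenerate correlation flagged as 0
  resp_const <- 1.4 * tg
  tc <- gci_timecourse(tg, resp_const, b0 = 1, g = 2, g0 = 1)
  expect_length(tc$gci, 25)
  expect_equal(tc$n_trials, seq(20, 500, by = 20))
  expect_true(all(abs(diff(tc$gci)) < 1e-12))
  expect_true(tc$degenerate)
  expect_equal(tc$pearson_r, 0)

  # bias ramps down across the block: compensation improves, so the GCI
  # series must correlate positively with trial count; cross-check each
  # prefix against a direct recomputation
  ramp <- seq(2, 1.2, length.out = n)
  resp_ramp <- ramp * tg
  tc2 <- gci_timecourse(tg, resp_ramp, b0 = 1, g = 2, g0 = 1)
  expect_gt(tc2$pearson_r, 0)
  for (k in c(1, 7, 25)) {
    m <- tc2$n_trials[k]
    b <- sum(tg[1:m] * resp_ramp[1:m]) / sum(tg[1:m]^2)
    expect_equal(tc2$gci[k], gci(2, 1, b, 1), tolerance = 1e-12)
  }

  expect_error(gci_timecourse(tg[1:10], resp_const[1:10], 1, 2, 1),
               "shorter")
})

test_that("travel-time regression recovers integrator signatures", {
  set.seed(3)
  r <- runif(40, 1, 4)
  v <- runif(40, 0.5, 2)
  # exact kinematic law: T = r / v gives weights (1, -1)
  fit <- travel_time_regression(r / v, r, v)
  expect_equal(fit$w_r, 1, tolerance = 1e-10)
  expect_equal(fit$w_v, -1, tolerance = 1e-10)
  # time independent of speed, proportional to distance: (1, 0)
  fit0 <- travel_time_regression(r, r, v)
  expect_equal(fit0$w_r, 1, tolerance = 1e-10)
  expect_equal(fit0$w_v, 0, tolerance = 1e-10)

  # 5-point instance against the normal equations solved directly
  T5 <- c(1.2, 2.5, 1.8, 3.1, 0.9)
  r5 <- c(1.1, 3.0, 2.2, 3.8, 1.4)
  v5 <- c(0.9, 1.3, 1.5, 1.2, 1.9)
  X <- cbind(log(r5), log(v5))
  w <- solve(crossprod(X), crossprod(X, log(T5)))
  fit5 <- travel_time_regression(T5, r5, v5)
  expect_equal(fit5$w_r, w[1], tolerance = 1e-10)
  expect_equal(fit5$w_v, w[2], tolerance = 1e-10)
  expect_true(all(fit5$ci[, 1] <= c(fit5$w_r, fit5$w_v)))

  expect_error(travel_time_regression(c(1, 2), c(1, 2), c(1, 2)), "3")
  expect_message(travel_time_regression(c(1, 2, 3, -1), c(1, 2, 3, 4),
                                        c(1, 1.5, 2, 1)), "excluded")
  expect_error(travel_time_regression(r / v, r, r), "collinear")
})

test_that("mean speed averages the controlled linear velocity", {
  tr <- toy_trial(rep(1, 120), rep(0, 120))
  tr$mean_speed <- NA_real_  # force recomputation from the time series
  expect_equal(mean_speed(tr), 1)
  # symmetric triangular speed profile peaking at 2: mean 1
  prof <- c(seq(0, 2, length.out = 61)[-1], seq(2, 0, length.out = 61)[-1])
  tr2 <- toy_trial(prof, rep(0, length(prof)))
  expect_equal(mean_speed(tr2), 1, tolerance = 0.02)
  # straight trials: path length / duration
  tr3 <- toy_trial(runif(90, 0.5, 2), rep(0, 90))
  expect_equal(mean_speed(tr3),
               tail(tr3$ts$y, 1) / tr3$travel_time, tolerance = 1e-9)
})
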