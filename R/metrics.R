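#' Multiplicative response bias (no-intercept regression slope)
#'
#' Regresses response positions on target positions without an intercept,
#' separately per coordinate (radial or angular): the slope
#' `sum(target * response) / sum(target^2)` is the multiplicative bias of
#' that component. A slope of 1 is unbiased; the uncompensated response to
#' a doubled joystick gain would double the slope. The 95% confidence
#' interval is a percentile bootstrap over trials.
#'
#' @param targets Numeric vector of target coordinates (m or deg).
#' @param responses Numeric vector of response coordinates, same length.
#' @param n_boot Number of bootstrap resamples (0 skips the interval).
#' @param conf Confidence level.
#' @return List of class `firefly_bias`: `slope`, `ci_low`, `ci_high`,
#'   `n_trials`.
#' @export
#' @examples
#' multiplicative_bias(c(1, 2, 3), c(1.2, 1.8, 3.3), n_boot = 0)$slope
multiplicative_bias <- function(targets, responses, n_boot = 1000,
                                conf = 0.95) {
  n <- length(targets)
  if (length(responses) != n || n < 2) {
    stop("targets and responses must have equal length >= 2", call. = FALSE)
  }
  if (all(targets == 0)) {
    stop("all-zero targets: multiplicative bias undefined", call. = FALSE)
  }
  slope <- sum(targets * responses) / sum(targets^2)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      den <- sum(targets[i]^2)
      if (den == 0) return(NA_real_)
      sum(targets[i] * responses[i]) / den
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  structure(list(slope = slope, ci_low = ci[1], ci_high = ci[2],
                 n_trials = n), class = "firefly_bias")
}

## random permutation with no fixed point, so no trial is ever re-paired
## with its own target in the shuffle null
derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Shuffle-null ROC curve and AUC for continuous endpoint responses
#'
#' Quantifies navigation accuracy on a scale that is comparable across
#' target configurations. For a sweep of hypothetical reward boundaries
#' (from 0 up to the largest observed error), the true-positive rate is the
#' proportion of trials whose endpoint error is within the boundary, and the
#' false-positive rate is the same proportion after shuffling the target
#' locations across trials (destroying the target-response relationship),
#' averaged over `n_shuffles` independent fixed-point-free permutations
#' (derangements, so no trial keeps its own target). The AUC of the
#' resulting curve is 1 for perfectly accurate responses and 0.5 for
#' responses unrelated to the targets.
#'
#' The boundary grid consists of all distinct observed error values (actual
#' and shuffled) plus 0, so the curve is the exact step function; the AUC is
#' the trapezoidal area under it.
#'
#' @param targets Data.frame (or matrix) of target positions with columns
#'   `r` (m) and `theta` (deg).
#' @param endpoints Data.frame of response positions, same format and
#'   length.
#' @param n_shuffles Number of random target permutations for the null.
#' @param errors,shuffled_errors Optional precomputed error vectors
#'   bypassing `targets`/`endpoints` (used mainly for testing).
#' @return List of class `firefly_roc`: `boundary`, `tpr`, `fpr`, `auc`,
#'   `n_shuffles`, `n_trials`.
#' @export
#' @examples
#' set.seed(1)
#' tg <- data.frame(r = runif(50, 1, 4), theta = runif(50, -35, 35))
#' roc_curve(tg, tg, n_shuffles = 10)$auc  # responses == targets: 1
roc_curve <- function(targets, endpoints, n_shuffles = 100,
                      errors = NULL, shuffled_errors = NULL) {
  if (is.null(errors)) {
    targets <- as.data.frame(targets)
    endpoints <- as.data.frame(endpoints)
    n <- nrow(targets)
    if (nrow(endpoints) != n) stop("length mismatch", call. = FALSE)
    if (n < 2) stop("need at least 2 trials for a shuffle null",
                    call. = FALSE)
    errors <- trial_error(targets$r, targets$theta,
                          endpoints$r, endpoints$theta)
    if (is.null(shuffled_errors)) {
      shuffled_errors <- unlist(lapply(seq_len(n_shuffles), function(s) {
        p <- derangement(n)
        trial_error(targets$r[p], targets$theta[p],
                    endpoints$r, endpoints$theta)
      }), use.names = FALSE)
    }
  } else if (is.null(shuffled_errors)) {
    stop("shuffled_errors must accompany precomputed errors", call. = FALSE)
  }
  boundary <- sort(unique(c(0, errors, shuffled_errors)))
  tpr <- stats::ecdf(errors)(boundary)
  fpr <- stats::ecdf(shuffled_errors)(boundary)
  fp <- c(0, fpr)
  tp <- c(0, tpr)
  auc <- sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
  structure(list(boundary = boundary, tpr = tpr, fpr = fpr, auc = auc,
                 n_shuffles = n_shuffles, n_trials = length(errors)),
            class = "firefly_roc")
}

#' @export
print.firefly_roc <- function(x, ...) {
  cat(sprintf("<firefly_roc> %d trials, %d shuffles, AUC = %.4f\n",
              x$n_trials, x$n_shuffles, x$auc))
  invisible(x)
}

#' Perturbation compensation index
#'
#' Locates the accuracy (AUC) of perturbed trials between the uncompensated
#' counterfactual (0 = no compensation) and the unperturbed trials
#' (1 = perfect compensation):
#' `PCI = (auc_p - auc_uc) / (auc_np - auc_uc)`.
#'
#' @param auc_p AUC of perturbed trials.
#' @param auc_uc AUC of the uncompensated-case responses.
#' @param auc_np AUC of unperturbed trials.
#' @return The index (dimensionless).
#' @export
#' @examples
#' pci(0.83, 0.76, 0.87)
pci <- function(auc_p, auc_uc, auc_np) {
  if (auc_np <= auc_uc) {
    stop("PCI undefined: unperturbed AUC must exceed uncompensated AUC",
         call. = FALSE)
  }
  (auc_p - auc_uc) / (auc_np - auc_uc)
}

#' Gain compensation index
#'
#' Measures how invariant the multiplicative steering bias is to a modified
#' joystick gain `g` relative to the baseline gain `g0`:
#' `GCI = (g - b/b0) / (g - g0)`, where `b` and `b0` are the biases of the
#' modified-gain and baseline blocks. 1 denotes perfect compensation (the
#' bias ratio stays 1); 0 denotes no compensation (the bias scales fully
#' with the gain change).
#'
#' @param g Modified gain factor.
#' @param g0 Baseline gain factor.
#' @param b Multiplicative bias under gain `g`.
#' @param b0 Multiplicative bias under gain `g0`.
#' @return The index (dimensionless).
#' @export
#' @examples
#' gci(g = 2, g0 = 1, b = 1.1, b0 = 1.1)  # bias unchanged: 1
gci <- function(g, g0, b, b0) {
  if (g == g0) stop("GCI undefined: g must differ from g0", call. = FALSE)
  if (b0 == 0) stop("GCI undefined: zero baseline bias", call. = FALSE)
  (g - b / b0) / (g - g0)
}

#' GCI timecourse over a block of trials
#'
#' Recomputes the gain compensation index on growing prefixes of a
#' modified-gain block (the first `increment` trials, then `2 * increment`,
#' ... up to the whole block) against a fixed baseline bias, and correlates
#' the series with the cumulative trial count to quantify whether
#' compensation improves over the block.
#'
#' @param targets,responses Per-trial target and response coordinates of the
#'   modified-gain block, in presentation order (one component, radial or
#'   angular).
#' @param b0 Baseline-block multiplicative bias of the same component.
#' @param g,g0 Modified and baseline gain factors.
#' @param increment Trials added per step (20 in the task's analysis, so a
#'   500-trial block yields 25 values).
#' @return List of class `firefly_gci_timecourse`: `n_trials` (cumulative
#'   counts), `gci` (the series), `pearson_r` (correlation with trial
#'   count; 0 with `degenerate = TRUE` when the series has no variance).
#' @export
gci_timecourse <- function(targets, responses, b0, g, g0, increment = 20) {
  n <- length(targets)
  if (length(responses) != n) stop("length mismatch", call. = FALSE)
  if (n < increment) {
    stop("block shorter than one increment", call. = FALSE)
  }
  cuts <- seq(increment, n, by = increment)
  num <- cumsum(targets * responses)
  den <- cumsum(targets^2)
  b_series <- num[cuts] / den[cuts]
  gci_series <- vapply(b_series, function(b) gci(g, g0, b, b0), numeric(1))
  degenerate <- length(gci_series) < 2 ||
    stats::sd(gci_series) < 1e-10 * max(1, abs(mean(gci_series)))
  r <- if (degenerate) 0 else stats::cor(cuts, gci_series)
  structure(list(n_trials = cuts, gci = gci_series, pearson_r = r,
                 degenerate = degenerate),
            class = "firefly_gci_timecourse")
}

#' Travel-time regression separating path from time integration
#'
#' Fits `log(T) = w_r * log(r) + w_v * log(v)` (no intercept) to per-trial
#' travel time `T`, target distance `r` and mean linear speed `v`. An ideal
#' path integrator satisfies `T = r / v`, i.e. weights (1, -1); pure time
#' integration (travel time independent of speed) predicts weights (1, 0).
#' Noise is assumed homoscedastic in log space.
#'
#' @param T Travel times in s (> 0).
#' @param r Target distances in m (> 0).
#' @param v Mean linear speeds in m/s (> 0).
#' @param conf Confidence level for the weight intervals.
#' @return List of class `firefly_ttfit`: `w_r`, `w_v`, `ci` (2x2 matrix),
#'   `n_trials`, `n_excluded` (non-positive inputs dropped), and the `lm`
#'   object as `fit`.
#' @export
#' @examples
#' r <- runif(20, 1, 4); v <- runif(20, 0.5, 2)
#' travel_time_regression(r / v, r, v)[c("w_r", "w_v")]
travel_time_regression <- function(T, r, v, conf = 0.95) {
  n0 <- length(T)
  if (length(r) != n0 || length(v) != n0) {
    stop("T, r, v must have equal length", call. = FALSE)
  }
  floor_ <- 1e-9
  keep <- is.finite(T) & is.finite(r) & is.finite(v) &
    T > floor_ & r > floor_ & v > floor_
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(n_excl, " trial(s) with non-positive T, r or v excluded")
  }
  T <- T[keep]; r <- r[keep]; v <- v[keep]
  if (length(T) < 3) stop("need at least 3 usable trials", call. = FALSE)
  lr <- log(r); lv <- log(v)
  if (qr(cbind(lr, lv))$rank < 2) {
    stop("log(r) and log(v) are collinear", call. = FALSE)
  }
  fit <- stats::lm(log(T) ~ 0 + lr + lv)
  ## exact simulated fits trip the "essentially perfect fit" warning
  ci <- suppressWarnings(stats::confint(fit, level = conf))
  rownames(ci) <- c("w_r", "w_v")
  structure(list(w_r = unname(stats::coef(fit)[1]),
                 w_v = unname(stats::coef(fit)[2]),
                 ci = ci, n_trials = length(T), n_excluded = n_excl,
                 fit = fit),
            class = "firefly_ttfit")
}

#' @export
print.firefly_ttfit <- function(x, ...) {
  cat(sprintf("<travel-time fit> w_r = %.3f [%.3f, %.3f], w_v = %.3f [%.3f, %.3f] (n = %d)\n",
              x$w_r, x$ci[1, 1], x$ci[1, 2],
              x$w_v, x$ci[2, 1], x$ci[2, 2], x$n_trials))
  invisible(x)
}

#' Mean linear speed of a trial
#'
#' Time-average of the absolute controlled (joystick-generated) linear
#' velocity between movement onset and stop. Angular motion is ignored:
#' the quantity enters the travel-time regression, which is motivated by
#' the kinematic law `v = x / t` for travelled distance.
#'
#' @param trial A `firefly_trial`.
#' @return Mean speed in m/s.
#' @export
mean_speed <- function(trial) {
  if (!is.null(trial$mean_speed) && !is.na(trial$mean_speed)) {
    return(trial$mean_speed)
  }
  if (is.na(trial$travel_time) || trial$travel_time <= 0) {
    stop("zero-duration trial", call. = FALSE)
  }
  dt <- trial$config$dt
  k0 <- round(trial$onset_time / dt) + 1L
  k1 <- min(nrow(trial$ts), k0 + round(trial$travel_time / dt) - 1L)
  cv <- trial$config$gain_factor * trial$config$v_max *
    trial$ts$a_lin[k0:k1]
  mean(abs(cv))
}
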