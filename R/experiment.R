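#' Specify an end-to-end experiment
#'
#' Bundles everything [run_experiment()] needs: which manipulation to run,
#' the agent and task configuration, the session size and the seed.
#' Documented minimum sizes: the perturbation experiment needs enough
#' trials for ROC curves of both halves (>= 20 recommended, >= 4 hard
#' minimum); the gain experiment needs >= 2 gain levels and, for the GCI
#' timecourse, blocks of at least one 20-trial increment.
#'
#' @param name One of `"perturbation"`, `"gain"`, `"density"`,
#'   `"flow_duration"`.
#' @param agent An [agent_params()].
#' @param config A [sim_config()].
#' @param n_trials Session size (defaults per experiment: 1000 perturbation,
#'   1500 gain blocks, 1000 density, 1000 flow duration).
#' @param seed Integer session seed.
#' @param n_shuffles Shuffle count for ROC nulls.
#' @param n_boot Bootstrap resamples for bias intervals.
#' @param gains,gain_style,densities Passed to [simulate_session()].
#' @param out_dir Optional output directory; when given,
#'   [run_experiment()] writes the session CSVs, auxiliary tables and a
#'   JSON report there.
#' @return A list of class `firefly_experiment_spec`.
#' @export
experiment_spec <- function(name = c("perturbation", "gain", "density",
                                     "flow_duration"),
                            agent = preset_agent("integrator"),
                            config = preset_config("monkey_default"),
                            n_trials = NULL, seed = 1L,
                            n_shuffles = 100, n_boot = 500,
                            gains = c(1, 1.5, 2),
                            gain_style = c("blocks", "per_trial"),
                            densities = c(2.5, 0.1),
                            out_dir = NULL) {
  name <- match.arg(name)
  gain_style <- match.arg(gain_style)
  if (is.null(n_trials)) {
    n_trials <- switch(name, perturbation = 1000, gain = 1500,
                       density = 1000, flow_duration = 1000)
  }
  structure(list(name = name, agent = agent, config = config,
                 n_trials = as.integer(n_trials), seed = as.integer(seed),
                 n_shuffles = n_shuffles, n_boot = n_boot, gains = gains,
                 gain_style = gain_style, densities = densities,
                 out_dir = out_dir),
            class = "firefly_experiment_spec")
}

roc_of <- function(tab, n_shuffles, what) {
  if (nrow(tab) < 2) {
    stop("ROC for ", what, " requires >= 2 trials, got ", nrow(tab),
         call. = FALSE)
  }
  roc_curve(data.frame(r = tab$target_r, theta = tab$target_theta),
            data.frame(r = tab$endpoint_r, theta = tab$endpoint_theta),
            n_shuffles = n_shuffles)
}

bias_pair <- function(tab, n_boot) {
  list(
    radial = unclass(multiplicative_bias(tab$target_r, tab$endpoint_r,
                                         n_boot = n_boot)),
    angular = unclass(multiplicative_bias(tab$target_theta,
                                          tab$endpoint_theta,
                                          n_boot = n_boot))
  )
}

#' Analyze a session with the metric battery of its experiment
#'
#' Computes the analysis suite appropriate to a (simulated or imported)
#' session:
#' \describe{
#'   \item{perturbation}{unperturbed / perturbed / uncompensated-case AUCs,
#'     the perturbation compensation index, bias estimates, and linear and
#'     angular dynamic-response profiles.}
#'   \item{gain}{per-gain biases and AUCs, gain compensation indices
#'     against the lowest gain with their 20-trial-increment timecourses
#'     (block designs), and the travel-time regression on all trials and on
#'     rewarded trials only.}
#'   \item{density}{per-density response SDs, mean absolute errors, AUCs.}
#'   \item{flow_duration}{per-duration AUCs and mean radial overshoot.}
#' }
#' `experiment = "auto"` picks the analysis from the conditions present in
#' the session (perturbed trials, multiple gains, densities or flow
#' durations).
#'
#' @param session A `firefly_session` (from [simulate_session()] or
#'   [import_session()]).
#' @param experiment Which battery to run, or `"auto"`.
#' @param n_shuffles Shuffle count for ROC nulls.
#' @param n_boot Bootstrap resamples for bias intervals.
#' @return A report list of class `firefly_report`; auxiliary per-trial /
#'   per-lag tables are attached as attribute `tables`.
#' @export
analyze_session <- function(session,
                            experiment = c("auto", "perturbation", "gain",
                                           "density", "flow_duration"),
                            n_shuffles = 100, n_boot = 500) {
  experiment <- match.arg(experiment)
  warnings_log <- character()
  note <- function(msg) warnings_log <<- c(warnings_log, msg)

  tab <- trials_table(session)
  if (any(!tab$valid)) {
    note(sprintf("%d invalid trial(s) excluded", sum(!tab$valid)))
    tab <- tab[tab$valid, ]
  }
  trial_by_id <- function(ids) {
    all_ids <- vapply(session$trials, function(tr) tr$trial_id, integer(1))
    session$trials[match(ids, all_ids)]
  }
  if (experiment == "auto") {
    experiment <- if (any(tab$perturbed)) "perturbation"
      else if (length(unique(tab$gain)) > 1) "gain"
      else if (length(unique(tab$density)) > 1) "density"
      else if (length(unique(tab$flow_duration)) > 1) "flow_duration"
      else "gain"  # single-condition sessions fail the >=2-gain check below
  }

  report <- list(experiment = experiment,
                 provenance = list(
                   seed = session$seed,
                   n_trials = nrow(tab),
                   manipulation = session$manipulation,
                   agent = unclass(session$agent),
                   package_version =
                     as.character(utils::packageVersion("fireflynav"))))
  tables <- list()

  if (experiment == "perturbation") {
    np <- tab[!tab$perturbed, ]
    p <- tab[tab$perturbed, ]
    uc <- session_uncompensated(session)
    uc <- uc[uc$trial_id %in% p$trial_id, ]
    p_t <- p[match(uc$trial_id, p$trial_id), ]
    roc_np <- roc_of(np, n_shuffles, "unperturbed trials")
    roc_p <- roc_of(p, n_shuffles, "perturbed trials")
    if (nrow(uc) < 2) {
      stop("ROC for uncompensated responses requires >= 2 trials",
           call. = FALSE)
    }
    roc_uc <- roc_curve(
      data.frame(r = p_t$target_r, theta = p_t$target_theta),
      data.frame(r = uc$endpoint_r, theta = uc$endpoint_theta),
      n_shuffles = n_shuffles)
    dyn_lin <- dynamic_response(trial_by_id(p$trial_id),
                                trial_by_id(np$trial_id), "linear")
    dyn_ang <- dynamic_response(trial_by_id(p$trial_id),
                                trial_by_id(np$trial_id), "angular")
    report$auc <- list(unperturbed = roc_np$auc, perturbed = roc_p$auc,
                       uncompensated = roc_uc$auc)
    report$pci <- pci(roc_p$auc, roc_uc$auc, roc_np$auc)
    report$bias <- bias_pair(tab, n_boot)
    report$n <- list(unperturbed = nrow(np), perturbed = nrow(p))
    tables$uncompensated <- uc
    tables$dynamic_response <- rbind(
      cbind(component = "linear", as.data.frame(dyn_lin)),
      cbind(component = "angular", as.data.frame(dyn_ang)))
  } else if (experiment == "gain") {
    gains_present <- sort(unique(tab$gain))
    if (length(gains_present) < 2) {
      stop("GCI requires >= 2 gain levels, got ", length(gains_present),
           call. = FALSE)
    }
    g0 <- gains_present[1]
    b0 <- bias_pair(tab[tab$gain == g0, ], n_boot)
    blocked <- is.null(session$assignments) ||
      session$manipulation != "gain_blocks" ||
      !is.unsorted(session$assignments$gain)
    per_gain <- lapply(gains_present, function(g) {
      sub <- tab[tab$gain == g, ]
      out <- list(gain = g, n = nrow(sub),
                  bias = bias_pair(sub, n_boot),
                  auc = roc_of(sub, n_shuffles,
                               paste0("gain ", g, " trials"))$auc)
      if (g != g0) {
        out$gci <- list(
          linear = gci(g, g0, out$bias$radial$slope, b0$radial$slope),
          angular = gci(g, g0, out$bias$angular$slope, b0$angular$slope))
        if (blocked && nrow(sub) >= 20) {
          tc <- gci_timecourse(sub$target_r, sub$endpoint_r,
                               b0$radial$slope, g, g0)
          out$gci_timecourse <- list(pearson_r = tc$pearson_r,
                                     degenerate = tc$degenerate)
          tables[[paste0("gci_timecourse_gain", g)]] <<-
            data.frame(gain = g, n_trials = tc$n_trials, gci = tc$gci)
        }
      }
      out
    })
    names(per_gain) <- paste0("gain_", gains_present)
    ttr_all <- travel_time_regression(tab$travel_time, tab$target_r,
                                      tab$mean_speed)
    rew <- tab[tab$rewarded, ]
    ttr_rew <- if (nrow(rew) >= 3) {
      travel_time_regression(rew$travel_time, rew$target_r, rew$mean_speed)
    } else {
      note("too few rewarded trials for the rewarded-only regression")
      NULL
    }
    report$baseline_gain <- g0
    report$per_gain <- per_gain
    report$travel_time <- list(
      all = list(w_r = ttr_all$w_r, w_v = ttr_all$w_v,
                 ci = unname(ttr_all$ci), n = ttr_all$n_trials),
      rewarded = if (is.null(ttr_rew)) NULL else
        list(w_r = ttr_rew$w_r, w_v = ttr_rew$w_v,
             ci = unname(ttr_rew$ci), n = ttr_rew$n_trials))
  } else if (experiment == "density") {
    report$per_density <- lapply(sort(unique(tab$density),
                                      decreasing = TRUE), function(d) {
      sub <- tab[tab$density == d, ]
      ## response variability around the multiplicative bias line, so the
      ## target spread itself does not inflate the SD
      br <- sum(sub$target_r * sub$endpoint_r) / sum(sub$target_r^2)
      ba <- sum(sub$target_theta * sub$endpoint_theta) /
        sum(sub$target_theta^2)
      list(density = d, n = nrow(sub),
           sd_radial = stats::sd(sub$endpoint_r - br * sub$target_r),
           sd_angular = stats::sd(sub$endpoint_theta - ba * sub$target_theta),
           mean_abs_error = mean(sub$error),
           auc = roc_of(sub, n_shuffles,
                        paste0("density ", d, " trials"))$auc)
    })
  } else if (experiment == "flow_duration") {
    report$per_duration <- lapply(sort(unique(tab$flow_duration)),
                                  function(d) {
      sub <- tab[tab$flow_duration == d, ]
      list(flow_duration = d, n = nrow(sub),
           auc = roc_of(sub, n_shuffles,
                        paste0("flow duration ", d, " trials"))$auc,
           mean_overshoot = mean(sub$endpoint_r - sub$target_r),
           mean_abs_error = mean(sub$error))
    })
  }

  report$warnings <- warnings_log
  class(report) <- "firefly_report"
  attr(report, "tables") <- tables
  report
}

#' Run a complete simulate-analyze-report experiment
#'
#' Simulates a session under the manipulation named by the spec (see
#' [simulate_session()]), analyzes it with [analyze_session()] and,
#' when `spec$out_dir` is set, writes the session tables (CSV), auxiliary
#' tables and the JSON report to disk. The report contains no timestamps,
#' so identical spec + seed yields an identical report.
#'
#' @param spec An [experiment_spec()].
#' @return A `firefly_report`; the simulated session is attached as
#'   attribute `session`.
#' @export
#' @examples
#' \donttest{
#' spec <- experiment_spec("perturbation", n_trials = 60, seed = 3,
#'                         n_shuffles = 20, n_boot = 50)
#' rep <- run_experiment(spec)
#' rep$pci
#' }
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "firefly_experiment_spec"))
  set.seed(spec$seed)
  manip <- switch(spec$name, perturbation = "perturbation",
                  gain = "gain_blocks", density = "density",
                  flow_duration = "flow_duration")
  session <- simulate_session(spec$agent, spec$config, spec$n_trials,
                              manipulation = manip, seed = spec$seed,
                              gains = spec$gains,
                              gain_style = spec$gain_style,
                              densities = spec$densities)
  report <- analyze_session(session, experiment = spec$name,
                            n_shuffles = spec$n_shuffles,
                            n_boot = spec$n_boot)
  attr(report, "session") <- session

  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_session(session, spec$out_dir,
                  prefix = paste0(spec$name, "_session"))
    tables <- attr(report, "tables")
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]],
                       file.path(spec$out_dir,
                                 paste0(spec$name, "_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(unclass(report),
                         file.path(spec$out_dir,
                                   paste0(spec$name, "_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.firefly_report <- function(x, ...) {
  cat(sprintf("<firefly_report> experiment '%s'\n", x$experiment))
  if (!is.null(x$pci)) {
    cat(sprintf("  AUC np/p/uc = %.3f / %.3f / %.3f, PCI = %.3f\n",
                x$auc$unperturbed, x$auc$perturbed, x$auc$uncompensated,
                x$pci))
  }
  if (!is.null(x$per_gain)) {
    for (pg in x$per_gain) {
      cat(sprintf("  gain %g: bias r/ang = %.3f/%.3f, AUC = %.3f%s\n",
                  pg$gain, pg$bias$radial$slope, pg$bias$angular$slope,
                  pg$auc,
                  if (!is.null(pg$gci))
                    sprintf(", GCI lin/ang = %.3f/%.3f",
                            pg$gci$linear, pg$gci$angular) else ""))
    }
    tt <- x$travel_time$all
    cat(sprintf("  travel-time fit: w_r = %.3f, w_v = %.3f (n = %d)\n",
                tt$w_r, tt$w_v, tt$n))
  }
  if (!is.null(x$per_density)) {
    for (pd in x$per_density) {
      cat(sprintf("  density %g: sd r/ang = %.3f m / %.2f deg, AUC = %.3f\n",
                  pd$density, pd$sd_radial, pd$sd_angular, pd$auc))
    }
  }
  if (!is.null(x$per_duration)) {
    for (pd in x$per_duration) {
      cat(sprintf("  flow %g s: AUC = %.3f, overshoot = %.2f m\n",
                  pd$flow_duration, pd$auc, pd$mean_overshoot))
    }
  }
  invisible(x)
}
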