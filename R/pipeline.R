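#' Configuration for an end-to-end simulated experiment
#'
#' Bundles the agent population, task generators and analysis options for
#' one of the four study designs: `exp1` (blocked vigilance + duration
#' discounting), `exp2` (intermixed vigilance + duration discounting),
#' `exp3a` (incentivized N-back performance) and `exp3b` (N-back load
#' discounting).
#'
#' The agent population draws `k_gain` log-normally (median
#' `k_gain_median`, log-sd `k_gain_sdlog`) and couples
#' `k_loss = k_loss_ratio * k_gain` per subject, so `k_loss_ratio < 1`
#' builds in loss aversion (less discounting of loss-framed outcomes) and
#' `k_loss_ratio = 1` is the null. Defaults put the median quadratic
#' discount rate at the point where the hardest effort level loses about
#' 80% of its value, with moderate choice noise (`beta = 10` per dollar).
#'
#' @param experiment one of `"exp1"`, `"exp2"`, `"exp3a"`, `"exp3b"`.
#' @param n_subjects number of simulated participants.
#' @param family generating discount family.
#' @param k_gain_median,k_gain_sdlog log-normal population parameters.
#' @param k_loss_ratio multiplicative gain-to-loss coupling.
#' @param beta softmax inverse temperature (shared across agents).
#' @param effort_levels high effort levels (minutes or N-back loads).
#' @param reference_effort effort of the low option.
#' @param amount_high fixed large amount in dollars.
#' @param n_runs,max_iterations staircase geometry.
#' @param vigilance a [vigilance_config()] (exp1/exp2).
#' @param pupil a [pupil_config()] (exp1/exp2).
#' @param nback an [nback_config()] (exp3a).
#' @param min_pupil_trials pupillometry inclusion gate.
#' @param fit_models fit and compare the five discount families
#'   (slower; off by default in simulation studies).
#' @param master_seed integer; every stage seed derives from it.
#' @export
experiment_config <- function(experiment = c("exp1", "exp2", "exp3a", "exp3b"),
                              n_subjects = 30L,
                              family = "quadratic",
                              k_gain_median = NULL, k_gain_sdlog = 0.5,
                              k_loss_ratio = 0.7, beta = 10,
                              effort_levels = NULL, reference_effort = 1,
                              amount_high = 10,
                              n_runs = 2L, max_iterations = 5L,
                              vigilance = vigilance_config(),
                              pupil = pupil_config(),
                              nback = nback_config(hit_rate = default_nback_hit,
                                                   fa_rate = default_nback_fa),
                              min_pupil_trials = 23L,
                              fit_models = FALSE,
                              master_seed = 1L) {
  experiment <- match.arg(experiment)
  if (n_subjects < 3L) stop_ef("need at least 3 subjects")
  duration_based <- experiment %in% c("exp1", "exp2")
  effort_levels <- effort_levels %||%
    if (duration_based) c(5, 10, 20, 30) else c(2, 3, 4)
  # median k: hardest level retains ~20% of value under quadratic discounting
  k_gain_median <- k_gain_median %||% (0.8 / max(effort_levels)^2)
  structure(list(experiment = experiment, n_subjects = as.integer(n_subjects),
                 family = family, k_gain_median = k_gain_median,
                 k_gain_sdlog = k_gain_sdlog, k_loss_ratio = k_loss_ratio,
                 beta = beta, effort_levels = effort_levels,
                 reference_effort = reference_effort,
                 amount_high = amount_high,
                 n_runs = n_runs, max_iterations = max_iterations,
                 vigilance = vigilance, pupil = pupil, nback = nback,
                 min_pupil_trials = min_pupil_trials,
                 fit_models = fit_models,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

# Default N-back generating rates: sensitivity falls with load; the only
# gain/loss asymmetry is a higher hit rate under loss at the highest load
# (0.68 vs 0.60), with false alarms flat across frames.
default_nback_hit <- function(load, frame) {
  base <- c(`1` = 0.95, `2` = 0.88, `3` = 0.78, `4` = 0.60)[[as.character(load)]]
  if (load == 4 && frame == "loss") 0.68 else base
}

default_nback_fa <- function(load, frame) {
  base <- c(`1` = 0.02, `2` = 0.04, `3` = 0.06, `4` = 0.08)[[as.character(load)]]
  if (load == 4 && frame == "loss") 0.07 else base
}

#' Draw the simulated agent population for an experiment
#' @param config an [experiment_config()].
#' @return list of [agent_params()].
#' @export
sample_agents <- function(config) {
  with_seed(child_seed(config$master_seed, 1L), {
    k_gain <- stats::rlnorm(config$n_subjects,
                            log(config$k_gain_median), config$k_gain_sdlog)
    lapply(seq_len(config$n_subjects), function(i)
      agent_params(sprintf("s%02d", i), config$family,
                   k_gain = k_gain[i],
                   k_loss = config$k_loss_ratio * k_gain[i],
                   beta = config$beta,
                   rng_seed = child_seed(config$master_seed, 100L + i)))
  })
}

#' Run one simulated experiment end to end
#'
#' Simulates the agent population, runs every task stage the design
#' includes, scores it, and returns a structured report: the discounting
#' stages (staircase titration, AUC, paired gain-loss contrast, optional
#' five-family model comparison) for exp1/2/3b; blocked or intermixed
#' vigilance with response-speed ANOVA, criterion accuracy, time-on-task
#' slopes, pupillometry and (exp1) Incentive x Order tests; and N-back
#' SDT scoring with load x frame contrasts for exp3a. Deterministic under
#' `master_seed`. When `out_dir` is given, per-stage CSVs and a JSON
#' report are written there.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory.
#' @return the report, a list of class `ef_report`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  report <- list(schema_version = "1.0",
                 experiment = config$experiment,
                 master_seed = config$master_seed,
                 n_subjects = config$n_subjects)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ef("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (config$experiment %in% c("exp1", "exp2", "exp3b")) {
    agents <- stage("agents", sample_agents(config))
    disc <- stage("discounting", {
      res <- lapply(agents, titrate_subject,
                    effort_levels = config$effort_levels,
                    amount_high = config$amount_high,
                    reference_effort = config$reference_effort,
                    n_runs = config$n_runs,
                    max_iterations = config$max_iterations,
                    interleaved = config$experiment != "exp1")
      ind <- do.call(rbind, lapply(res, `[[`, "indifference"))
      trials <- do.call(rbind, lapply(res, `[[`, "trials"))
      auc <- do.call(rbind, lapply(split(ind, list(ind$subject, ind$frame),
                                         drop = TRUE), function(g)
        data.frame(subject = g$subject[1L], frame = g$frame[1L],
                   auc = auc_from_indifference(g$effort_level, g$indifference,
                                               config$reference_effort,
                                               config$amount_high))))
      auc_w <- stats::reshape(auc, idvar = "subject", timevar = "frame",
                              direction = "wide")
      names(auc_w) <- sub("auc\\.", "", names(auc_w))
      list(indifference = ind, trials = trials, auc = auc, auc_wide = auc_w)
    })
    report$indifference <- disc$indifference
    report$auc <- disc$auc
    report$auc_contrast <- stage("auc_contrast",
      gain_loss_contrast(disc$auc_wide$gain, disc$auc_wide$loss))

    if (config$fit_models) {
      report$model_comparison <- stage("model_fits", {
        fits_by_subject <- lapply(agents, function(ag) {
          tr <- disc$trials[disc$trials$subject == ag$subject_id &
                              disc$trials$frame == "gain", ]
          tt <- data.frame(amount_low = tr$net_low, amount_high = tr$net_high,
                           effort_low = config$reference_effort,
                           effort_high = tr$effort_high)
          fit_all_families(tt, tr$choice, subject_id = ag$subject_id,
                           frame = "gain")
        })
        compare_models(fits_by_subject)
      })
    }
    if (config$experiment == "exp1") {
      # counterbalanced run order, alternating assignment
      ord <- rep(c("gain_first", "loss_first"),
                 length.out = config$n_subjects)
      report$order_effect_auc <- stage("order_auc",
        mixed_anova_order(disc$auc_wide$gain, disc$auc_wide$loss, ord))
    }
  }

  if (config$experiment %in% c("exp1", "exp2")) {
    vig_trials <- stage("vigilance_sim", {
      lapply(seq_len(config$n_subjects), function(i) {
        sid <- sprintf("s%02d", i)
        baseline <- generate_vigilance_session(
          config$vigilance, "baseline",
          seed = child_seed(config$master_seed, 200L + i), subject = sid)
        runs <- if (config$experiment == "exp1") {
          rbind(
            generate_vigilance_session(config$vigilance, "gain",
                                       seed = child_seed(config$master_seed, 300L + i),
                                       subject = sid),
            generate_vigilance_session(config$vigilance, "loss",
                                       seed = child_seed(config$master_seed, 400L + i),
                                       subject = sid))
        } else {
          cfg <- config$vigilance; cfg$design <- "intermixed"
          generate_vigilance_session(cfg,
                                     seed = child_seed(config$master_seed, 300L + i),
                                     subject = sid)
        }
        list(baseline = baseline, incentivized = runs)
      })
    })
    vig <- stage("vigilance_score", {
      do.call(rbind, lapply(vig_trials, function(s) {
        crit <- rt_criterion(s$baseline$rt_ms, s$baseline$valid)
        scored <- score_vigilance(rbind(s$baseline, s$incentivized),
                                  criterion_ms = crit)
        scored$criterion_ms <- crit
        scored
      }))
    })
    report$vigilance <- vig
    speed_w <- stats::reshape(
      vig[, c("subject", "condition", "mean_speed")],
      idvar = "subject", timevar = "condition", direction = "wide")
    names(speed_w) <- sub("mean_speed\\.", "", names(speed_w))
    conds <- setdiff(names(speed_w), "subject")
    report$speed_anova <- stage("speed_anova",
      rm_anova(speed_w[, conds, drop = FALSE]))
    gl <- intersect(c("gain", "loss"), conds)
    if (length(gl) == 2L)
      report$speed_gain_loss <- stage("speed_contrast",
        gain_loss_contrast(speed_w$gain, speed_w$loss))

    report$pupil <- stage("pupillometry", {
      per_subj <- lapply(seq_len(config$n_subjects), function(i) {
        sid <- sprintf("s%02d", i)
        ev <- vig_trials[[i]]$incentivized[, c("onset_s", "condition")]
        # onsets restart at 0 for each blocked run; epoch them per run
        eps <- list()
        for (cond_run in split(ev, cumsum(c(TRUE, diff(ev$onset_s) < 0)))) {
          tr <- generate_pupil_trace(
            config$pupil, cond_run,
            duration_s = config$vigilance$run_duration,
            seed = child_seed(config$master_seed,
                              500L + i * 4L + length(eps)))
          tr <- preprocess_pupil(tr, config$pupil$sampling_rate)
          eps[[length(eps) + 1L]] <- extract_prestim(tr, cond_run)
        }
        ep <- do.call(rbind, eps)
        means <- tapply(ep$prestim_mean_mm[ep$usable],
                        ep$condition[ep$usable], mean)
        data.frame(subject = sid,
                   condition = names(means),
                   prestim_mean = as.numeric(means),
                   included = subject_inclusion(ep, config$min_pupil_trials))
      })
      do.call(rbind, per_subj)
    })
  }

  if (config$experiment == "exp3a") {
    nb <- stage("nback", {
      rows <- list()
      for (i in seq_len(config$n_subjects)) {
        sid <- sprintf("s%02d", i)
        for (load in config$nback$loads) for (fr in c("gain", "loss")) {
          rows[[length(rows) + 1L]] <- generate_nback_session(
            config$nback, load, fr,
            seed = child_seed(config$master_seed,
                              1000L + i * 10L + load * 2L + (fr == "loss")),
            subject = sid)
        }
      }
      score_nback(do.call(rbind, rows))
    })
    report$nback_scores <- nb
    # per-load gain-loss d' contrasts plus load main effect on d'
    report$dprime_contrasts <- do.call(rbind, lapply(
      sort(unique(nb$load)), function(L) {
        g <- nb[nb$load == L & nb$frame == "gain", ]
        l <- nb[nb$load == L & nb$frame == "loss", ]
        g <- g[order(g$subject), ]; l <- l[order(l$subject), ]
        ct <- gain_loss_contrast(g$d_prime, l$d_prime)
        data.frame(load = L, mean_diff = ct$mean_diff, t = ct$t,
                   df = ct$df, p = ct$p)
      }))
    loadmat <- tapply(nb$d_prime, list(nb$subject, nb$load), mean)
    report$dprime_load_anova <- stage("dprime_anova", rm_anova(loadmat))
  }

  report <- structure(report, class = "ef_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.ef_report <- function(x, ...) {
  cat(sprintf("<ef_report> %s, n = %d, seed = %d\n",
              x$experiment, x$n_subjects, x$master_seed))
  if (!is.null(x$auc_contrast))
    cat(sprintf("  AUC loss-gain: mean diff %.4f, t(%d) = %.3f, p = %.4g\n",
                x$auc_contrast$mean_diff, x$auc_contrast$df,
                x$auc_contrast$t, x$auc_contrast$p))
  if (!is.null(x$speed_anova))
    cat(sprintf("  speed ANOVA: F(%g, %g) = %.3f, p = %.4g\n",
                x$speed_anova$df1, x$speed_anova$df2,
                x$speed_anova$F, x$speed_anova$p))
  if (!is.null(x$dprime_load_anova))
    cat(sprintf("  d' load ANOVA: F(%g, %g) = %.3f, p = %.4g\n",
                x$dprime_load_anova$df1, x$dprime_load_anova$df2,
                x$dprime_load_anova$F, x$dprime_load_anova$p))
  invisible(x)
}

#' Write an experiment report to disk
#'
#' Per-stage tables go to CSV; scalar statistics to a versioned JSON
#' report. Byte-identical across reruns with the same configuration.
#'
#' @param report an `ef_report`.
#' @param out_dir directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]]))
      utils::write.csv(report[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  scalars <- list(schema_version = report$schema_version,
                  experiment = report$experiment,
                  master_seed = report$master_seed,
                  n_subjects = report$n_subjects)
  for (nm in c("auc_contrast", "speed_anova", "speed_gain_loss",
               "order_effect_auc", "dprime_load_anova")) {
    if (!is.null(report[[nm]])) {
      x <- report[[nm]]
      scalars[[nm]] <- x[setdiff(names(x), c("differences", "cell_means",
                                             "follow_up"))]
    }
  }
  if (!is.null(report$model_comparison)) {
    scalars$model_comparison <- list(
      group_winner = report$model_comparison$group_winner,
      group = report$model_comparison$group)
  }
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(scalars, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
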