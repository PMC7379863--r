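#' Configuration for a simulated motivated vigilance session
#'
#' Emulates a 10-minute run of a speeded target-detection task with
#' roughly 80 targets. Reaction times are log-normal (right-skewed,
#' positive support): `rt = exp(N(log(rt_mu), rt_sigma))`, scaled down by
#' the incentive speed-up on gain/loss trials, drifting upward linearly
#' with time on task, with occasional lapses (> 2x the median). Inter-
#' stimulus intervals are uniform on `isi_range`; with the 1-s feedback
#' display and the response itself, the default 2-10 s range yields about
#' 80 trials in 600 s.
#'
#' @param n_trials target trial count (used only for feasibility checks).
#' @param run_duration run length in seconds.
#' @param isi_range c(min, max) inter-stimulus interval, seconds.
#' @param rt_mu median RT in ms; `rt_sigma` log-sd.
#' @param incentive_speedup fractional RT reduction on gain and loss trials.
#' @param loss_extra_speedup additional fractional reduction on loss trials
#'   (0 under the null of no gain/loss asymmetry).
#' @param tot_slowing additive RT drift, ms per minute of time on task.
#' @param lapse_prob per-trial probability of an attentional lapse.
#' @param design `"blocked"` (one condition per run) or `"intermixed"`
#'   (gain/loss/neutral cues shuffled with a run-length cap).
#' @param max_consecutive cap on same-condition runs in intermixed design.
#' @param feedback_s RT feedback display time appended to each trial.
#' @export
vigilance_config <- function(n_trials = 80L, run_duration = 600,
                             isi_range = c(2, 10),
                             rt_mu = 400, rt_sigma = 0.2,
                             incentive_speedup = 0.05,
                             loss_extra_speedup = 0,
                             tot_slowing = 5, lapse_prob = 0.02,
                             design = c("blocked", "intermixed"),
                             max_consecutive = 3L, feedback_s = 1) {
  design <- match.arg(design)
  if (isi_range[1L] < 0 || isi_range[2L] < isi_range[1L])
    stop_ef("invalid isi_range")
  mean_trial <- mean(isi_range) + feedback_s + rt_mu / 1000
  if (run_duration / mean_trial < n_trials / 2 ||
      run_duration / mean_trial > n_trials * 2)
    stop_ef("isi_range incompatible with n_trials over run_duration")
  structure(list(n_trials = n_trials, run_duration = run_duration,
                 isi_range = isi_range, rt_mu = rt_mu, rt_sigma = rt_sigma,
                 incentive_speedup = incentive_speedup,
                 loss_extra_speedup = loss_extra_speedup,
                 tot_slowing = tot_slowing, lapse_prob = lapse_prob,
                 design = design, max_consecutive = as.integer(max_consecutive),
                 feedback_s = feedback_s),
            class = "vigilance_config")
}

# Balanced condition sequence with no more than max_consecutive repeats.
# Counts differ by at most 1 across conditions; sampled sequentially with
# rejection of stuck states (rare at cap 3 with 3 conditions).
intermixed_sequence <- function(n, conditions, max_consecutive) {
  base <- n %/% length(conditions)
  extra <- n %% length(conditions)
  counts <- stats::setNames(rep(base, length(conditions)), conditions)
  if (extra > 0) {
    bump <- sample(conditions, extra)
    counts[bump] <- counts[bump] + 1L
  }
  repeat {
    rem <- counts
    seqv <- character(n)
    run_len <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      allowed <- names(rem)[rem > 0L]
      if (i > 1L && run_len >= max_consecutive)
        allowed <- setdiff(allowed, seqv[i - 1L])
      if (length(allowed) == 0L) { ok <- FALSE; break }
      pick <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
      seqv[i] <- pick
      rem[pick] <- rem[pick] - 1L
      run_len <- if (i > 1L && pick == seqv[i - 1L]) run_len + 1L else 1L
    }
    if (ok) return(seqv)
  }
}

#' Generate one vigilance session
#'
#' @param config a [vigilance_config()].
#' @param condition condition of a blocked run
#'   (`"baseline"`, `"gain"`, `"loss"`, `"neutral"`); ignored when the
#'   design is intermixed, where gain/loss/neutral cues alternate.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param subject subject identifier carried into the table.
#' @return data frame with columns `subject`, `trial`, `onset_s`,
#'   `condition`, `rt_ms`, `valid`.
#' @export
generate_vigilance_session <- function(config, condition = "baseline",
                                       seed = 1L, subject = "s01") {
  stopifnot(inherits(config, "vigilance_config"))
  condition <- match.arg(condition, c("baseline", "gain", "loss", "neutral"))
  with_seed(seed, {
    # Pass 1: schedule trials with the unspeeded (multiplier = 1) RT to fix
    # the trial count, so the intermixed condition sequence can be balanced
    # exactly over the realized count. Incentive multipliers are <= 1, so
    # applying them in pass 2 only moves onsets earlier and every scheduled
    # trial still fits in the run.
    isi <- numeric(0); raw_rt <- numeric(0); lapse <- logical(0)
    onset <- 0; n <- 0L
    repeat {
      s <- stats::runif(1L, config$isi_range[1L], config$isi_range[2L])
      t_on <- onset + s
      if (t_on > config$run_duration) break
      n <- n + 1L
      r <- exp(stats::rnorm(1L, log(config$rt_mu), config$rt_sigma))
      l <- config$lapse_prob > 0 && stats::runif(1L) < config$lapse_prob
      rt_prov <- r + config$tot_slowing * t_on / 60 +
        if (l) 2 * config$rt_mu else 0
      isi[n] <- s; raw_rt[n] <- r; lapse[n] <- l
      onset <- t_on + rt_prov / 1000 + config$feedback_s
    }
    if (n == 0L) stop_ef("run_duration too short for a single trial")

    conds <- if (config$design == "intermixed")
      intermixed_sequence(n, c("gain", "loss", "neutral"),
                          config$max_consecutive)
    else rep(condition, n)
    mult <- ifelse(conds %in% c("gain", "loss"),
                   1 - config$incentive_speedup, 1)
    mult <- ifelse(conds == "loss", mult * (1 - config$loss_extra_speedup),
                   mult)

    # Pass 2: final onsets and RTs with condition multipliers applied.
    onset_s <- numeric(n); rt_ms <- numeric(n)
    onset <- 0
    for (i in seq_len(n)) {
      t_on <- onset + isi[i]
      rt <- raw_rt[i] * mult[i] + config$tot_slowing * t_on / 60 +
        if (lapse[i]) 2 * config$rt_mu else 0
      onset_s[i] <- t_on; rt_ms[i] <- rt
      onset <- t_on + rt / 1000 + config$feedback_s
    }
    data.frame(subject = subject, trial = seq_len(n), onset_s = onset_s,
               condition = conds, rt_ms = rt_ms, valid = TRUE)
  })
}

#' Configuration for a simulated tonic pupil-diameter trace
#'
#' The trace emulates only what the downstream analysis consumes: a tonic
#' level (baseline + incentive dilation + linear time-on-task drift),
#' Gaussian sample noise, and blink dropout flagged invalid. No phasic
#' target-locked response is modelled.
#'
#' @param sampling_rate Hz.
#' @param baseline_mm tonic diameter in mm.
#' @param incentive_dilation_mm additive tonic increase on gain/loss trials.
#' @param tot_decline_mm_per_min linear drift (negative = shrinking).
#' @param blink_rate blinks per minute.
#' @param blink_duration_ms c(min, max) blink length.
#' @param noise_sd_mm per-sample Gaussian noise.
#' @export
pupil_config <- function(sampling_rate = 60, baseline_mm = 4,
                         incentive_dilation_mm = 0.15,
                         tot_decline_mm_per_min = -0.05,
                         blink_rate = 12, blink_duration_ms = c(100, 300),
                         noise_sd_mm = 0.05) {
  if (sampling_rate <= 0) stop_ef("sampling_rate must be positive")
  structure(list(sampling_rate = sampling_rate, baseline_mm = baseline_mm,
                 incentive_dilation_mm = incentive_dilation_mm,
                 tot_decline_mm_per_min = tot_decline_mm_per_min,
                 blink_rate = blink_rate,
                 blink_duration_ms = blink_duration_ms,
                 noise_sd_mm = noise_sd_mm),
            class = "pupil_config")
}

#' Generate a pupil trace locked to task events
#'
#' @param config a [pupil_config()].
#' @param events data frame with `onset_s` and `condition`, or a numeric
#'   vector of onsets (then all events count as `condition = "neutral"`).
#'   The incentive dilation applies within `[onset - 1.5, onset + 2]` s of
#'   each gain/loss event (the epoch the analysis looks at).
#' @param duration_s trace length; defaults to covering the last event + 2 s.
#' @param seed integer seed.
#' @return data frame of class spanning columns `time_s`, `diameter_mm`,
#'   `valid` (blink samples are invalid with `diameter_mm = NA`).
#' @export
generate_pupil_trace <- function(config, events, duration_s = NULL, seed = 1L) {
  stopifnot(inherits(config, "pupil_config"))
  if (is.numeric(events))
    events <- data.frame(onset_s = events, condition = "neutral")
  duration_s <- duration_s %||% (max(events$onset_s) + 2)
  if (any(events$onset_s < 0 | events$onset_s > duration_s))
    stop_ef("events must lie within the trace duration")
  with_seed(seed, {
    t <- seq(0, duration_s, by = 1 / config$sampling_rate)
    level <- config$baseline_mm + config$tot_decline_mm_per_min * t / 60
    dil <- numeric(length(t))
    inc <- events[events$condition %in% c("gain", "loss"), , drop = FALSE]
    for (j in seq_len(nrow(inc))) {
      w <- t >= inc$onset_s[j] - 1.5 & t <= inc$onset_s[j] + 2
      dil[w] <- config$incentive_dilation_mm
    }
    d <- level + dil
    if (config$noise_sd_mm > 0)
      d <- d + stats::rnorm(length(t), 0, config$noise_sd_mm)
    valid <- rep(TRUE, length(t))
    if (config$blink_rate > 0) {
      n_blinks <- stats::rpois(1L, config$blink_rate * duration_s / 60)
      if (n_blinks > 0) {
        starts <- stats::runif(n_blinks, 0, duration_s)
        durs <- stats::runif(n_blinks, config$blink_duration_ms[1L],
                             config$blink_duration_ms[2L]) / 1000
        for (j in seq_len(n_blinks))
          valid[t >= starts[j] & t <= starts[j] + durs[j]] <- FALSE
      }
    }
    d[!valid] <- NA_real_
    if (any(valid) && any(d[valid] <= 0))
      stop_ef("generated non-positive diameters; check config")
    data.frame(time_s = t, diameter_mm = d, valid = valid)
  })
}

#' Configuration for a simulated N-back run
#'
#' One canonical run is 64 letter stimuli of which exactly 16 are targets
#' (the letter repeats the one N positions back); non-target letters are
#' constrained never to match at lag N, so target counts are exact rather
#' than expected, and SDT denominators are fixed at 16/48.
#'
#' @param loads admissible memory loads.
#' @param n_stimuli,n_targets run geometry (64 / 16).
#' @param hit_rate,fa_rate either single probabilities or functions
#'   `(load, frame) -> probability` giving the generating hit and
#'   false-alarm rates.
#' @param nonresponse_prob probability a trial gets no response at all.
#' @param letters candidate stimulus letters (consonants by default).
#' @export
nback_config <- function(loads = 1:4, n_stimuli = 64L, n_targets = 16L,
                         hit_rate = 0.8, fa_rate = 0.08,
                         nonresponse_prob = 0,
                         letters = c("B","C","D","F","G","H","J","K","L","M",
                                     "N","P","Q","R","S","T")) {
  if (n_targets >= n_stimuli) stop_ef("n_targets must be below n_stimuli")
  structure(list(loads = loads, n_stimuli = as.integer(n_stimuli),
                 n_targets = as.integer(n_targets),
                 hit_rate = hit_rate, fa_rate = fa_rate,
                 nonresponse_prob = nonresponse_prob, letters = letters),
            class = "nback_config")
}

rate_at <- function(rate, load, frame) {
  if (is.function(rate)) rate(load, frame) else rate
}

#' Generate one N-back run with simulated responses
#'
#' @param config an [nback_config()].
#' @param load memory load (must be in `config$loads`).
#' @param frame `"gain"` or `"loss"`.
#' @param seed integer seed.
#' @param subject identifier.
#' @return data frame with columns `subject`, `load`, `frame`, `trial`,
#'   `letter`, `is_target`, `response` (`"target"`, `"nontarget"` or
#'   `NA` for a non-response), `correct`.
#' @export
generate_nback_session <- function(config, load, frame = c("gain", "loss"),
                                   seed = 1L, subject = "s01") {
  stopifnot(inherits(config, "nback_config"))
  frame <- match.arg(frame)
  if (!load %in% config$loads) stop_ef("load %s not in config$loads", load)
  n <- config$n_stimuli
  if (n - load < config$n_targets)
    stop_ef("cannot place %d targets at load %d in %d stimuli",
            config$n_targets, load, n)
  with_seed(seed, {
    target_pos <- sort(sample((load + 1L):n, config$n_targets))
    is_target <- seq_len(n) %in% target_pos
    letters_v <- character(n)
    for (i in seq_len(n)) {
      if (is_target[i]) {
        letters_v[i] <- letters_v[i - load]
      } else {
        pool <- config$letters
        if (i > load) pool <- setdiff(pool, letters_v[i - load])
        letters_v[i] <- sample(pool, 1L)
      }
    }
    hr <- rate_at(config$hit_rate, load, frame)
    fr <- rate_at(config$fa_rate, load, frame)
    assert_prob(c(hr, fr), "hit/false-alarm rates")
    u <- stats::runif(n)
    response <- ifelse(is_target,
                       ifelse(u < hr, "target", "nontarget"),
                       ifelse(u < fr, "target", "nontarget"))
    if (config$nonresponse_prob > 0)
      response[stats::runif(n) < config$nonresponse_prob] <- NA_character_
    correct <- !is.na(response) &
      response == ifelse(is_target, "target", "nontarget")
    data.frame(subject = subject, load = as.integer(load), frame = frame,
               trial = seq_len(n), letter = letters_v,
               is_target = is_target, response = response, correct = correct)
  })
}
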