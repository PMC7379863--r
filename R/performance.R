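#' @title Scoring vigilance and N-back sessions
#' @name performance
#' @description
#' Vigilance runs are scored as response speed (1/RT), the percentage of
#' responses faster than the subject's baseline median-RT criterion, and
#' per-condition linear time-on-task slopes. N-back runs are tabulated
#' into hit/miss/false-alarm/correct-rejection counts and summarised with
#' signal-detection sensitivity (d') and likelihood-ratio bias (beta).
NULL

# RTs faster than this are treated as false starts and flagged invalid.
FALSE_START_MS <- 100

# Drop invalid rows and apply the false-start exclusion.
valid_rts <- function(rt_ms, valid = rep(TRUE, length(rt_ms))) {
  rt_ms[valid & !is.na(rt_ms) & rt_ms >= FALSE_START_MS]
}

#' Response speed from reaction time
#' @param rt_ms reaction time(s) in milliseconds, > 0.
#' @return speed in 1/seconds (`1000 / rt_ms`).
#' @export
response_speed <- function(rt_ms) {
  if (any(rt_ms <= 0)) stop_ef("rt_ms must be positive")
  1000 / rt_ms
}

#' Baseline reaction-time criterion
#'
#' The individual criterion is the median RT of the unincentivized
#' baseline run, after excluding invalid trials and false starts
#' (< 100 ms). Even counts take the mean of the central pair.
#'
#' @param rt_ms baseline RTs in ms.
#' @param valid logical validity flags (default all valid).
#' @return criterion in ms.
#' @export
rt_criterion <- function(rt_ms, valid = rep(TRUE, length(rt_ms))) {
  v <- valid_rts(rt_ms, valid)
  if (length(v) == 0L) stop_ef("no valid baseline trials")
  stats::median(v)
}

#' Percentage of responses faster than a criterion
#'
#' Strict inequality: a response exactly at the criterion does not count
#' as faster (deterministic tie rule at millisecond resolution).
#'
#' @param rt_ms RTs in ms.
#' @param criterion_ms criterion (> 0).
#' @param valid validity flags.
#' @return percentage in `[0, 100]`.
#' @export
pct_faster <- function(rt_ms, criterion_ms, valid = rep(TRUE, length(rt_ms))) {
  if (criterion_ms <= 0) stop_ef("criterion must be positive")
  v <- valid_rts(rt_ms, valid)
  if (length(v) == 0L) stop_ef("no valid trials")
  100 * mean(v < criterion_ms)
}

#' Linear time-on-task slope
#'
#' Ordinary least-squares slope of a measure on elapsed time in minutes
#' (trial onset, not trial index), computed per incentive condition within
#' a run by the callers.
#'
#' @param values measure (response speed, RT, pupil diameter, ...).
#' @param times_s elapsed time in seconds.
#' @return slope in measure units per minute.
#' @export
tot_slope <- function(values, times_s) {
  keep <- is.finite(values) & is.finite(times_s)
  values <- values[keep]; times_s <- times_s[keep]
  if (length(values) < 3L) stop_ef("need >= 3 points for a slope")
  mins <- times_s / 60
  if (stats::sd(mins) == 0) stop_ef("constant time vector")
  unname(stats::coef(stats::lm(values ~ mins))[2L])
}

#' Signal-detection counts for one subject x load x frame
#' @param hits,misses,false_alarms,correct_rejections non-negative counts.
#' @param load,frame carried metadata.
#' @export
sdt_counts <- function(hits, misses, false_alarms, correct_rejections,
                       load = NA_integer_, frame = NA_character_) {
  cnt <- c(hits, misses, false_alarms, correct_rejections)
  if (any(cnt < 0)) stop_ef("counts must be non-negative")
  structure(list(hits = hits, misses = misses, false_alarms = false_alarms,
                 correct_rejections = correct_rejections,
                 load = load, frame = frame),
            class = "sdt_counts")
}

# 1/(2N) correction for perfect / empty cells so z() stays finite.
corrected_rate <- function(k, n) {
  if (n <= 0) stop_ef("SDT denominator must be positive")
  r <- k / n
  if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
}

#' Signal-detection metrics from counts
#'
#' Rates hitting 0 or 1 are corrected by the 1/(2N) rule before the
#' inverse-normal transform. Sensitivity `d' = z(H) - z(F)`; the
#' likelihood-ratio bias is `beta = exp((z(F)^2 - z(H)^2) / 2)`.
#'
#' @param counts an [sdt_counts()].
#' @return list with `hit_rate`, `fa_rate` (corrected), `d_prime`,
#'   `beta_bias`, plus the raw rates.
#' @export
sdt_metrics <- function(counts) {
  stopifnot(inherits(counts, "sdt_counts"))
  n_sig <- counts$hits + counts$misses
  n_noise <- counts$false_alarms + counts$correct_rejections
  h <- corrected_rate(counts$hits, n_sig)
  f <- corrected_rate(counts$false_alarms, n_noise)
  zh <- stats::qnorm(h); zf <- stats::qnorm(f)
  list(hit_rate = h, fa_rate = f,
       raw_hit_rate = counts$hits / n_sig,
       raw_fa_rate = counts$false_alarms / n_noise,
       d_prime = zh - zf,
       beta_bias = exp((zf^2 - zh^2) / 2))
}

#' Score an N-back trial table into SDT counts and earnings
#'
#' Tabulates hits / misses / false alarms / correct rejections per
#' subject x load x frame. Non-responses count as errors (the loss-frame
#' instruction penalises omissions); tables with more than 10% missing
#' responses are flagged. Earnings follow the incentive scheme: gains pay
#' 6 cents per correct target and 2 cents per correct non-target; losses
#' deduct the same amounts per target / non-target error from a $2
#' endowment.
#'
#' @param tbl data frame as produced by [generate_nback_session()]
#'   (columns `subject`, `load`, `frame`, `is_target`, `response`).
#' @param endowment loss-frame endowment in dollars.
#' @return data frame, one row per subject x load x frame, with count
#'   columns, `d_prime`, `beta_bias`, `earnings` (gain scheme) or
#'   `remaining` (loss scheme), and `flagged_missing`.
#' @export
score_nback <- function(tbl, endowment = 2) {
  req <- c("subject", "load", "frame", "is_target", "response")
  if (!all(req %in% names(tbl))) stop_ef("missing N-back columns")
  key <- interaction(tbl$subject, tbl$load, tbl$frame, drop = TRUE)
  out <- lapply(split(tbl, key), function(g) {
    tgt <- g$is_target
    resp_t <- !is.na(g$response) & g$response == "target"
    resp_n <- !is.na(g$response) & g$response == "nontarget"
    hits <- sum(tgt & resp_t)
    misses <- sum(tgt & !resp_t)           # wrong response or omission
    fas <- sum(!tgt & resp_t)
    crs <- sum(!tgt & !resp_t)             # SDT CR: no target press
    correct_nt <- sum(!tgt & resp_n)       # paid non-target responses
    missing_frac <- mean(is.na(g$response))
    cnt <- sdt_counts(hits, misses, fas, crs,
                      load = g$load[1L], frame = g$frame[1L])
    m <- sdt_metrics(cnt)
    gain_pay <- 0.06 * hits + 0.02 * correct_nt
    loss_deduct <- 0.06 * misses + 0.02 * (sum(!tgt) - correct_nt)
    data.frame(subject = g$subject[1L], load = g$load[1L], frame = g$frame[1L],
               hits = hits, misses = misses, false_alarms = fas,
               correct_rejections = crs,
               hit_rate = m$raw_hit_rate, fa_rate = m$raw_fa_rate,
               d_prime = m$d_prime, beta_bias = m$beta_bias,
               earnings = gain_pay,
               remaining = endowment - loss_deduct,
               flagged_missing = missing_frac > 0.10)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$subject, res$load, res$frame), , drop = FALSE]
}

#' Score a vigilance session into its summary metrics
#'
#' @param trials data frame from [generate_vigilance_session()] (or the
#'   matching CSV schema).
#' @param criterion_ms baseline median-RT criterion (from [rt_criterion()]
#'   on the baseline run); `NA` skips the criterion metric.
#' @return data frame, one row per condition: mean speed (1/s),
#'   `pct_faster`, time-on-task `speed_slope` (1/s per minute) and
#'   `rt_slope` (ms per minute), and trial count.
#' @export
score_vigilance <- function(trials, criterion_ms = NA_real_) {
  out <- lapply(split(trials, trials$condition), function(g) {
    keep <- g$valid & g$rt_ms >= FALSE_START_MS
    g <- g[keep, , drop = FALSE]
    sp <- response_speed(g$rt_ms)
    data.frame(subject = g$subject[1L], condition = g$condition[1L],
               n_trials = nrow(g),
               mean_speed = mean(sp),
               pct_faster = if (is.na(criterion_ms)) NA_real_
                            else pct_faster(g$rt_ms, criterion_ms),
               speed_slope = if (nrow(g) >= 3L) tot_slope(sp, g$onset_s)
                             else NA_real_,
               rt_slope = if (nrow(g) >= 3L) tot_slope(g$rt_ms, g$onset_s)
                          else NA_real_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
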