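#' @title Tonic pupillometry preprocessing and pre-stimulus extraction
#' @name pupillometry
#' @description
#' Traces are cleaned by padding invalid (blink/dropout) runs by 100 ms on
#' each side, linearly interpolating gaps up to 500 ms, and leaving longer
#' gaps invalid. The analysis measure is the mean diameter in the 1-second
#' window before each target onset (tonic, pre-stimulus), with an epoch
#' usable when at least half of its pre-stimulus samples are valid.
#' All four rule constants are configurable arguments.
NULL

#' Clean a pupil trace
#'
#' Invalid runs are padded by `pad_ms` on each side (samples near a blink
#' are contaminated), then gaps no longer than `max_interp_ms` are linearly
#' interpolated from the flanking valid samples and marked valid again;
#' longer gaps stay invalid with `NA` diameter. Optional moving-average
#' smoothing over `smooth_ms`. Sample count is unchanged. The operation is
#' idempotent: a trace that has already been preprocessed (attribute
#' `pupil_preprocessed`) is returned unchanged.
#'
#' @param trace data frame with `time_s`, `diameter_mm`, `valid`.
#' @param sampling_rate Hz; inferred from timestamps when `NULL`.
#' @param pad_ms padding around invalid runs.
#' @param max_interp_ms longest interpolatable gap (after padding).
#' @param smooth_ms moving-average window; 0 disables smoothing.
#' @return the cleaned trace (same columns and row count).
#' @export
preprocess_pupil <- function(trace, sampling_rate = NULL,
                             pad_ms = 100, max_interp_ms = 500,
                             smooth_ms = 0) {
  if (nrow(trace) == 0L) stop_ef("empty trace")
  if (isTRUE(attr(trace, "pupil_preprocessed"))) return(trace)
  if (all(!trace$valid)) stop_ef("trace has no valid samples")
  if (is.unsorted(trace$time_s, strictly = TRUE))
    stop_ef("time must be strictly increasing")
  sampling_rate <- sampling_rate %||% (1 / stats::median(diff(trace$time_s)))

  valid <- trace$valid & !is.na(trace$diameter_mm)
  d <- trace$diameter_mm

  # pad invalid runs
  pad_n <- round(pad_ms / 1000 * sampling_rate)
  if (pad_n > 0 && any(!valid)) {
    bad <- which(!valid)
    padded <- unique(unlist(lapply(bad, function(i)
      max(1L, i - pad_n):min(length(valid), i + pad_n))))
    valid[padded] <- FALSE
  }
  d[!valid] <- NA_real_

  # interpolate short gaps
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap_limit_s <- max_interp_ms / 1000
  for (j in seq_along(r$lengths)) {
    if (r$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    if (i0 == 1L || i1 == length(valid)) next   # edge gaps: no flanks
    gap_s <- trace$time_s[i1 + 1L] - trace$time_s[i0 - 1L]
    if (gap_s > gap_limit_s) next
    idx <- i0:i1
    d[idx] <- stats::approx(x = trace$time_s[c(i0 - 1L, i1 + 1L)],
                            y = d[c(i0 - 1L, i1 + 1L)],
                            xout = trace$time_s[idx])$y
    valid[idx] <- TRUE
  }

  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / 1000 * sampling_rate))
    if (w > 1L) {
      sm <- stats::filter(ifelse(valid, d, NA), rep(1 / w, w), sides = 2)
      d <- ifelse(valid & !is.na(sm), as.numeric(sm), d)
    }
  }

  out <- data.frame(time_s = trace$time_s, diameter_mm = d, valid = valid)
  attr(out, "pupil_preprocessed") <- TRUE
  out
}

#' Extract pre-stimulus epochs around target onsets
#'
#' For each onset, the tonic measure is the mean of valid diameters in
#' `[onset - 1, onset)` seconds; the epoch is usable when at least
#' `min_valid_frac` of the window's samples are valid (and at least one
#' sample falls in the window).
#'
#' @param trace a (preprocessed) pupil trace.
#' @param events data frame with `onset_s` and optionally `condition`, or
#'   a numeric onset vector.
#' @param window_s pre-stimulus window length in seconds.
#' @param min_valid_frac usability threshold (default 0.5).
#' @return data frame, one row per event: `onset_s`, `condition`,
#'   `prestim_mean_mm`, `n_samples`, `n_valid`, `usable`.
#' @export
extract_prestim <- function(trace, events, window_s = 1,
                            min_valid_frac = 0.5) {
  if (is.numeric(events))
    events <- data.frame(onset_s = events, condition = NA_character_)
  if (is.unsorted(trace$time_s)) stop_ef("trace time must be sorted")
  span <- range(trace$time_s)
  if (any(events$onset_s < span[1L] | events$onset_s > span[2L]))
    stop_ef("onsets outside trace span")
  t <- trace$time_s
  n_ev <- nrow(events)
  p_mean <- numeric(n_ev); n_s <- integer(n_ev); n_v <- integer(n_ev)
  for (j in seq_len(n_ev)) {
    on <- events$onset_s[j]
    # samples with t in [on - window_s, on): half-open window
    i0 <- findInterval(on - window_s, t, left.open = TRUE) + 1L
    i1 <- findInterval(on, t, left.open = TRUE)
    if (i1 >= i0) {
      idx <- i0:i1
      v <- trace$valid[idx]
      n_s[j] <- length(idx); n_v[j] <- sum(v)
      p_mean[j] <- if (n_v[j] > 0L) mean(trace$diameter_mm[idx][v]) else NA_real_
    } else {
      n_s[j] <- 0L; n_v[j] <- 0L; p_mean[j] <- NA_real_
    }
  }
  data.frame(onset_s = events$onset_s,
             condition = if (is.null(events$condition)) NA_character_
                         else events$condition,
             prestim_mean_mm = p_mean, n_samples = n_s, n_valid = n_v,
             usable = n_s > 0L & n_v / pmax(n_s, 1L) >= min_valid_frac)
}

#' Subject-level inclusion gate for pupillometry
#'
#' A subject is included when every incentive condition has at least
#' `min_trials` usable epochs (default 23, the quality gate used for
#' intermixed sessions).
#'
#' @param epochs data frame from [extract_prestim()] with `condition`.
#' @param min_trials threshold per condition.
#' @param conditions conditions that must each pass; defaults to the
#'   conditions present.
#' @return logical.
#' @export
subject_inclusion <- function(epochs, min_trials = 23L, conditions = NULL) {
  conditions <- conditions %||% unique(epochs$condition)
  counts <- vapply(conditions, function(cc)
    sum(epochs$usable & epochs$condition == cc), integer(1L))
  all(counts >= min_trials)
}

#' Time-on-task slope of the tonic pupil measure
#'
#' OLS slope of the pre-stimulus mean on onset time in minutes, over
#' usable epochs (per condition in the callers).
#'
#' @param epochs data frame from [extract_prestim()].
#' @return slope in mm per minute.
#' @export
pupil_tot_slope <- function(epochs) {
  use <- epochs[epochs$usable, , drop = FALSE]
  if (nrow(use) < 3L) stop_ef("need >= 3 usable epochs")
  tot_slope(use$prestim_mean_mm, use$onset_s)
}
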