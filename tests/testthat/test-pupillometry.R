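make_trace <- function(duration = 20, rate = 60, value = 3,
                       ramp = 0) {
  t <- seq(0, duration, by = 1 / rate)
  data.frame(time_s = t, diameter_mm = value + ramp * t,
             valid = rep(TRUE, length(t)))
}

invalidate <- function(trace, from, to) {
  w <- trace$time_s >= from & trace$time_s <= to
  trace$valid[w] <- FALSE
  trace$diameter_mm[w] <- NA_real_
  trace
}

test_that("preprocessing is the identity on clean traces", {
  tr <- make_trace()
  out <- preprocess_pupil(tr)
  expect_equal(out$diameter_mm, tr$diameter_mm)
  expect_true(all(out$valid))
  expect_error(preprocess_pupil(invalidate(tr, 0, 20)), "valid")
})

test_that("short gaps interpolate exactly on a linear ramp", {
  tr <- invalidate(make_trace(ramp = 0.1), 10, 10.2)   # 200 ms gap
  out <- preprocess_pupil(tr)
  expect_true(all(out$valid))
  # interpolated samples lie on the generating ramp (pad flanks included)
  expect_equal(out$diameter_mm, 3 + 0.1 * out$time_s, tolerance = 1e-10)
})

test_that("long gaps stay invalid and padding widens the gap", {
  tr <- invalidate(make_trace(), 10, 10.8)             # 800 ms gap
  out <- preprocess_pupil(tr)
  w <- out$time_s >= 10 & out$time_s <= 10.8
  expect_true(all(!out$valid[w]))
  # 100 ms padding on each side is also invalid
  expect_false(any(out$valid[out$time_s >= 9.92 & out$time_s <= 10.88]))
  # samples clear of the padded window survive
  expect_true(all(out$valid[out$time_s < 9.88 | out$time_s > 10.92]))
})

test_that("preprocessing is idempotent", {
  tr <- invalidate(make_trace(), 5, 5.8)
  once <- preprocess_pupil(tr)
  twice <- preprocess_pupil(once)
  expect_identical(once, twice)
})

test_that("pre-stimulus extraction averages the 1-s window", {
  tr <- make_trace(value = 3)
  ep <- extract_prestim(tr, events = c(5, 12))
  expect_equal(ep$prestim_mean_mm, c(3, 3))
  expect_true(all(ep$usable))
  # ramp: mean of the sampled arithmetic sequence in [onset-1, onset)
  trr <- make_trace(ramp = 0.5)
  epr <- extract_prestim(trr, events = 10)
  idx <- trr$time_s >= 9 & trr$time_s < 10
  expect_equal(epr$prestim_mean_mm, mean(trr$diameter_mm[idx]))
  # samples outside the window cannot influence the mean
  tr2 <- trr
  tr2$diameter_mm[tr2$time_s < 9 | tr2$time_s >= 10] <- 99
  expect_equal(extract_prestim(tr2, events = 10)$prestim_mean_mm,
               epr$prestim_mean_mm)
  expect_error(extract_prestim(tr, events = 50), "span")
})

test_that("usability needs half the window valid", {
  tr <- invalidate(make_trace(), 9.2, 9.9)   # ~60% of [9, 10) invalid
  ep <- extract_prestim(tr, events = 10)
  expect_false(ep$usable)
  tr2 <- invalidate(make_trace(), 9.8, 9.9)  # small gap: still usable
  expect_true(extract_prestim(tr2, events = 10)$usable)
})

test_that("subject inclusion gates on usable epochs per condition", {
  ep <- data.frame(condition = rep(c("gain", "loss", "neutral"), each = 25),
                   usable = TRUE)
  expect_true(subject_inclusion(ep, min_trials = 23))
  ep$usable[ep$condition == "loss"][1:3] <- FALSE    # 22 usable in loss
  expect_false(subject_inclusion(ep, min_trials = 23))
  expect_true(subject_inclusion(ep, min_trials = 0))
})

test_that("pupil time-on-task slope recovers a noiseless drift exactly", {
  cfg <- pupil_config(noise_sd_mm = 0, blink_rate = 0,
                      tot_decline_mm_per_min = -0.05,
                      incentive_dilation_mm = 0)
  ev <- seq(10, 590, by = 8)
  tr <- generate_pupil_trace(cfg, ev, duration_s = 600)
  ep <- extract_prestim(tr, ev)
  expect_equal(pupil_tot_slope(ep), -0.05, tolerance = 1e-10)
  # constant tonic level gives slope 0
  cfg0 <- pupil_config(noise_sd_mm = 0, blink_rate = 0,
                       tot_decline_mm_per_min = 0, incentive_dilation_mm = 0)
  ep0 <- extract_prestim(generate_pupil_trace(cfg0, ev, duration_s = 600), ev)
  expect_equal(pupil_tot_slope(ep0), 0, tolerance = 1e-12)
  expect_error(pupil_tot_slope(ep[1:2, ]), "usable")
})

test_that("incentive dilation shows up in pre-stimulus means end to end", {
  cfg <- pupil_config(incentive_dilation_mm = 0.2, blink_rate = 6,
                      noise_sd_mm = 0.05)
  ev <- data.frame(onset_s = seq(10, 590, by = 8),
                   condition = rep(c("gain", "loss", "neutral"), length.out = 73))
  tr <- preprocess_pupil(generate_pupil_trace(cfg, ev, duration_s = 600,
                                              seed = 13))
  ep <- extract_prestim(tr, ev)
  m <- tapply(ep$prestim_mean_mm[ep$usable], ep$condition[ep$usable], mean)
  expect_gt(m[["gain"]], m[["neutral"]])
  expect_gt(m[["loss"]], m[["neutral"]])
})
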