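test_that("simulate_choice follows the softmax generative model", {
  # deterministic limit: higher SV wins with probability 1
  ag <- agent_params("a", "quadratic", k_gain = 0, k_loss = 0, beta = Inf)
  tr <- choice_trial(1, 30, amount_low = 3, amount_high = 10, frame = "gain")
  expect_identical(simulate_choice(ag, tr), "high_effort")
  # k = 0 identity: any titration offer below 10 loses to the fixed 10
  for (offer in c(0, 2.5, 5, 7.5, 9.99)) {
    tr <- choice_trial(1, 30, offer, 10, frame = "gain")
    expect_identical(simulate_choice(ag, tr), "high_effort")
  }
  # exact tie at beta = Inf resolves to low_effort (documented rule)
  tr_tie <- choice_trial(1, 30, 10, 10, frame = "gain")
  expect_identical(simulate_choice(ag, tr_tie), "low_effort")
  # symmetric values give P(high) = 0.5 for finite beta
  ag2 <- agent_params("b", "quadratic", k_gain = 0, k_loss = 0, beta = 3)
  expect_equal(choice_prob_high(ag2, tr_tie), 0.5)
})

test_that("agents draw from a private reproducible stream", {
  mk <- function() agent_params("a", "hyperbolic", 0.3, 0.3, beta = 2,
                                rng_seed = 42L)
  tr <- choice_trial(1, 10, 5, 10, frame = "gain")
  a1 <- mk(); a2 <- mk()
  seq1 <- replicate(20, simulate_choice(a1, tr))
  # global RNG is untouched by agent draws
  set.seed(99); before <- runif(3)
  seq2 <- replicate(20, simulate_choice(a2, tr))
  set.seed(99); expect_identical(before, runif(3))
  expect_identical(seq1, seq2)
})

test_that("invalid agents and trials are rejected", {
  expect_error(agent_params("a", "cubic", 0.1, 0.1, 1), "one of")
  expect_error(agent_params("a", "linear", -0.1, 0.1, 1), "non-negative")
  expect_error(agent_params("a", "sigmoid", 0.1, 0.1, 1), "p_sigmoid")
  expect_error(choice_trial(1, 30, -1, 10, "gain"), "non-negative")
  expect_error(choice_trial(5, 5, 1, 10, "gain"), "effort_low")
})

test_that("vigilance sessions respect design constraints", {
  cfg <- vigilance_config(design = "intermixed")
  for (seed in 1:5) {
    s <- generate_vigilance_session(cfg, seed = seed)
    # no more than three consecutive trials of the same condition
    r <- rle(s$condition)
    expect_lte(max(r$lengths), 3L)
    # condition counts differ by at most 1
    counts <- table(factor(s$condition, c("gain", "loss", "neutral")))
    expect_lte(max(counts) - min(counts), 1L)
  }
  # reproducible bit-identically under a fixed seed
  expect_identical(generate_vigilance_session(cfg, seed = 11),
                   generate_vigilance_session(cfg, seed = 11))
})

test_that("degenerate vigilance config collapses to the median RT", {
  cfg <- vigilance_config(rt_sigma = 0, incentive_speedup = 0,
                          tot_slowing = 0, lapse_prob = 0)
  s <- generate_vigilance_session(cfg, "gain", seed = 1)
  expect_equal(s$rt_ms, rep(cfg$rt_mu, nrow(s)))
})

test_that("incompatible ISI range is rejected", {
  expect_error(vigilance_config(isi_range = c(60, 120)), "incompatible")
  expect_error(vigilance_config(isi_range = c(5, 2)), "isi_range")
})

test_that("default ISI arithmetic yields about 80 trials per 600 s", {
  cfg <- vigilance_config()
  n <- vapply(1:300, function(s)
    nrow(generate_vigilance_session(cfg, seed = s)), numeric(1L))
  expect_lt(abs(mean(n) - 80), 5)
})

test_that("pupil traces have the stated tonic structure", {
  # degenerate config: constant trace at baseline
  cfg0 <- pupil_config(noise_sd_mm = 0, blink_rate = 0,
                       tot_decline_mm_per_min = 0, incentive_dilation_mm = 0)
  tr <- generate_pupil_trace(cfg0, events = c(5, 10), duration_s = 20)
  expect_true(all(tr$valid))
  expect_true(all(tr$diameter_mm == cfg0$baseline_mm))
  # linear drift arithmetic: -0.05 mm/min over 10 min = -0.5 mm
  cfgd <- pupil_config(noise_sd_mm = 0, blink_rate = 0,
                       tot_decline_mm_per_min = -0.05,
                       incentive_dilation_mm = 0)
  trd <- generate_pupil_trace(cfgd, events = 10, duration_s = 600)
  expect_equal(trd$diameter_mm[nrow(trd)], cfgd$baseline_mm - 0.5)
  # blink dropout fraction matches rate x expected duration (Monte Carlo)
  cfgb <- pupil_config(noise_sd_mm = 0, blink_rate = 30,
                       blink_duration_ms = c(200, 200),
                       tot_decline_mm_per_min = 0)
  frac <- vapply(1:50, function(s) {
    x <- generate_pupil_trace(cfgb, events = 10, duration_s = 300, seed = s)
    mean(!x$valid)
  }, numeric(1L))
  expect_lt(abs(mean(frac) - 30 * 0.2 / 60), 0.02)
  # errors
  expect_error(pupil_config(sampling_rate = 0), "positive")
  expect_error(generate_pupil_trace(cfg0, events = 50, duration_s = 20),
               "duration")
})

test_that("n-back runs have exact target structure at every load", {
  cfg <- nback_config()
  for (load in 1:4) for (seed in 1:5) {
    s <- generate_nback_session(cfg, load, "gain", seed = seed)
    lag_match <- s$letter[(load + 1):64] == s$letter[1:(64 - load)]
    expect_identical(sum(lag_match), 16L)              # exact, not expected
    expect_identical(which(lag_match) + load, which(s$is_target))
  }
  expect_identical(generate_nback_session(cfg, 2, "loss", seed = 9),
                   generate_nback_session(cfg, 2, "loss", seed = 9))
  expect_error(generate_nback_session(cfg, 5, "gain"), "load")
  expect_error(generate_nback_session(nback_config(n_targets = 63), 4, "gain"),
               "place")
})

test_that("perfect accuracy scores 16 hits and 0 false alarms", {
  s <- generate_nback_session(nback_config(hit_rate = 1, fa_rate = 0),
                              2, "gain", seed = 1)
  sc <- score_nback(s)
  expect_identical(sc$hits, 16L)
  expect_identical(sc$false_alarms, 0L)
  expect_identical(sc$correct_rejections, 48L)
})

test_that("generated hit rates match the binomial target", {
  cfg <- nback_config(hit_rate = 0.68, fa_rate = 0.07)
  hits <- vapply(1:2000, function(s) {
    x <- generate_nback_session(cfg, 4, "loss", seed = s)
    sum(x$is_target & x$response == "target")
  }, numeric(1L))
  expect_lt(abs(mean(hits) / 16 - 0.68), 0.02)
})
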