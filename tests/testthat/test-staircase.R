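test_that("update_staircase bisects the offer interval", {
  st <- staircase_state(10, 5L)
  expect_equal(st$current_offer, 5)
  # rejecting the offer raises the lower bound
  up <- update_staircase(st, "high_effort")
  expect_equal(up$current_offer, 7.5)
  expect_equal(c(up$lower_bound, up$upper_bound), c(5, 10))
  # accepting lowers the upper bound
  down <- update_staircase(st, "low_effort")
  expect_equal(down$current_offer, 2.5)
  expect_equal(c(down$lower_bound, down$upper_bound), c(0, 5))
  # interval width halves each update: 10 / 2^i
  s <- staircase_state(10, 8L)
  for (i in 1:8) {
    s <- update_staircase(s, sample(c("low_effort", "high_effort"), 1))
    expect_equal(s$upper_bound - s$lower_bound, 10 / 2^i)
  }
  # exhausted staircases refuse further updates
  s5 <- staircase_state(10, 1L)
  s5 <- update_staircase(s5, "low_effort")
  expect_error(update_staircase(s5, "low_effort"), "iterations")
})

test_that("bisection estimate converges for deterministic threshold agents", {
  for (tau in c(0.7, 3.3, 5, 8.6)) {
    est <- run_staircase(threshold_agent(tau), effort_high = 2,
                         frame = "gain")$indifference
    expect_lte(abs(est - tau), 10 / 2^5)
  }
})

test_that("boundary agents drive the estimate to the boundary", {
  # k = 0: the fixed $10 at high effort dominates every offer below 10
  ag0 <- agent_params("a", "quadratic", 0, 0, beta = Inf)
  est <- run_staircase(ag0, 30, "gain")$indifference
  expect_gte(est, 10 - 10 / 2^5)
  # extreme discounting: every offer is accepted, estimate collapses to 0
  agmax <- agent_params("b", "quadratic", 1, 1, beta = Inf)
  expect_lte(run_staircase(agmax, 30, "gain")$indifference, 10 / 2^5)
})

test_that("pegging constructs loss trials with identical net outcomes", {
  g <- choice_trial(1, 20, amount_low = 6, amount_high = 10, frame = "gain")
  l <- peg_loss_trial(g)
  expect_equal(l$loss_low, 4)                    # lose 4, keep 6
  expect_equal(l$loss_high, 0)                   # lose nothing, keep 10
  expect_equal(c(l$amount_low, l$amount_high),
               c(g$amount_low, g$amount_high))
  # boundary: offer 0 pegs to a full loss
  g0 <- choice_trial(1, 20, 0, 10, frame = "gain")
  expect_equal(peg_loss_trial(g0)$loss_low, 10)
  # round-trip identity
  expect_equal(unclass(unpeg_loss_trial(l))[1:5], unclass(g)[1:5])
  expect_error(peg_loss_trial(g, endowment = 8), "endowment")
})

test_that("framing is value-neutral inside the staircase engine", {
  # same k in both frames + same agent stream => identical estimates,
  # because pegged trials present identical net outcomes
  mk <- function() agent_params("a", "hyperbolic", 0.4, 0.4, beta = 8,
                                rng_seed = 7L)
  for (lvl in c(5, 30)) {
    eg <- run_staircase(mk(), lvl, "gain")$indifference
    el <- run_staircase(mk(), lvl, "loss")$indifference
    expect_identical(eg, el)
  }
})

test_that("interleaved presentation preserves per-frame estimates", {
  mk <- function() agent_params("s", "quadratic", 0.002, 0.0014, beta = 10,
                                rng_seed = 3L)
  blocked <- titrate_subject(mk(), c(5, 10, 20, 30))
  mixed <- titrate_subject(mk(), c(5, 10, 20, 30), interleaved = TRUE)
  expect_equal(blocked$indifference, mixed$indifference)
})

test_that("replay mode re-scores a recorded choice sequence", {
  ag <- agent_params("a", "quadratic", 0.002, 0.002, beta = Inf)
  live <- run_staircase(ag, 20, "gain")
  replayed <- run_staircase(NULL, 20, "gain", choices = live$trials$choice)
  expect_equal(replayed$indifference, live$indifference)
  expect_error(run_staircase(NULL, 20, "gain", choices = rep("low_effort", 3)),
               "recorded")
})

test_that("titrate_subject produces one indifference cell per frame x level", {
  ag <- agent_params("s9", "quadratic", 0.002, 0.0014, beta = 10,
                     rng_seed = 5L)
  tt <- titrate_subject(ag, c(5, 10, 20, 30))
  expect_identical(nrow(tt$indifference), 8L)
  expect_true(all(tt$indifference$indifference >= 0 &
                    tt$indifference$indifference <= 10))
  expect_identical(nrow(tt$trials), 8L * 10L)
})
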