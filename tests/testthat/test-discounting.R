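test_that("subjective value families obey their closed forms", {
  # k = 0 is the identity for every family
  for (fam in discount_families())
    expect_equal(subjective_value(fam, 7, 25, 0, p_sigmoid = 10), 7)
  expect_equal(subjective_value("hyperbolic", 10, 5, 0.2), 5)
  expect_equal(subjective_value("quadratic", 10, 30, 1 / 900), 0)
  expect_equal(subjective_value("exponential", 10, 10, 0.1), 10 * exp(-1))
  # linear/quadratic values are clipped at zero, never negative
  expect_equal(subjective_value("linear", 10, 30, 0.5), 0)
  # sigmoid is anchored at SV(0) = M after rescaling
  expect_equal(subjective_value("sigmoid", 10, 0, 0.4, p_sigmoid = 12), 10)
  expect_error(subjective_value("sigmoid", 10, 5, 0.4), "p_sigmoid")
  expect_error(subjective_value("linear", -1, 5, 0.1), "non-negative")
})

test_that("every family is non-increasing in effort for k > 0", {
  E <- seq(0, 30, by = 0.5)
  for (fam in discount_families()) {
    sv <- subjective_value(fam, 10, E, 0.15, p_sigmoid = 15)
    expect_true(all(diff(sv) <= 1e-12), info = fam)
    expect_equal(sv[1L], 10)
  }
})

test_that("choice_loglik evaluates the softmax exactly", {
  # equal values: ln 0.5 per trial
  tied <- data.frame(amount_low = 10, amount_high = 10,
                     effort_low = 0, effort_high = 0)
  expect_equal(choice_loglik(tied, "high_effort", "linear", k = 0, beta = 2),
               log(0.5))
  # beta = 1, Delta-SV = ln 3 => P(high) = 0.75 (k = 0 makes SV = M)
  tr <- data.frame(amount_low = 1, amount_high = 1 + log(3),
                   effort_low = 1, effort_high = 2)
  expect_equal(choice_loglik(tr, "high_effort", "linear", k = 0, beta = 1),
               log(0.75))
  # large beta with value-consistent choices drives loglik toward 0-
  tr40 <- data.frame(amount_low = 2, amount_high = 10,
                     effort_low = 1, effort_high = 2)[rep(1, 40), ]
  ll <- choice_loglik(tr40, rep("high_effort", 40), "linear", 0, beta = 50)
  expect_lte(ll, 0)
  expect_gt(ll, -1e-10)
  expect_error(choice_loglik(tied[0, ], character(0), "linear", 0, 1),
               "trial")
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  ag <- agent_params("fit1", "quadratic", k_gain = 0.002, k_loss = 0.002,
                     beta = 10, rng_seed = 21L)
  dat <- staircase_choice_data(ag)
  expect_identical(nrow(dat$trials), 40L)
  fit <- fit_discount_model(dat$trials, dat$choices, "quadratic")
  expect_lt(abs(fit$k - 0.002) / 0.002, 0.25)
  # MLE dominance: fitted loglik >= loglik at the generating parameters
  ll_true <- choice_loglik(dat$trials, dat$choices, "quadratic",
                           k = 0.002, beta = 10)
  expect_gte(fit$loglik + 1e-8, ll_true)
  # BIC identity
  expect_equal(fit$bic, 2 * log(40) - 2 * fit$loglik)
})

test_that("a null (k = 0) agent yields a near-zero fitted k", {
  ag <- agent_params("null", "quadratic", 0, 0, beta = 20, rng_seed = 4L)
  dat <- staircase_choice_data(ag)
  fit <- fit_discount_model(dat$trials, dat$choices, "quadratic")
  expect_lte(fit$k, 1e-4)
})

test_that("model comparison applies the BIC tie-breaks", {
  mkfit <- function(family, loglik, n = 40L) {
    np <- if (family == "sigmoid") 3L else 2L
    structure(list(subject_id = "s1", frame = "gain", family = family,
                   k = 0.1, beta = 1, p_sigmoid = NA_real_,
                   loglik = loglik, n_trials = n, n_params = np,
                   bic = np * log(n) - 2 * loglik, converged = TRUE),
              class = "discount_fit")
  }
  # equal logliks: the 2-parameter families beat the 3-parameter sigmoid
  fits <- setNames(lapply(discount_families(), mkfit, loglik = -20),
                   discount_families())
  cmpr <- compare_models(list(fits))
  expect_false(cmpr$per_subject$winner == "sigmoid")
  # with equal BIC among 2-parameter families the fixed order decides
  expect_identical(cmpr$per_subject$winner, "hyperbolic")
  # BIC arithmetic: 2 ln 40 + 40
  expect_equal(fits$linear$bic, 2 * log(40) + 40)
  # winner never has a higher BIC than any other family
  expect_lte(min(vapply(fits, `[[`, numeric(1), "bic")),
             fits[[cmpr$per_subject$winner]]$bic + 1e-12)
  # mismatched trial sets across families are rejected
  bad <- fits; bad$linear <- mkfit("linear", -20, n = 30L)
  expect_error(compare_models(list(bad)), "different trial sets")
})

test_that("AUC matches closed-form cases and the quadrature oracle", {
  E <- c(1, 5, 10, 20, 30)
  expect_equal(compute_auc(E, rep(10, 5)), 1)                 # no discounting
  # y falling linearly from 1 to 0 over the x-range: triangle, AUC = 0.5
  x <- E / 30
  y_lin <- (x[5] - x) / (x[5] - x[1])
  expect_equal(compute_auc(E, 10 * y_lin), 0.5)
  # oracle check on the worked example
  y <- c(1, 0.8, 0.6, 0.4, 0.2)
  expect_equal(compute_auc(E, 10 * y),
               auc_oracle(E / 30, y), tolerance = 1e-8)
  # invariance to rescaling both axes by positive constants
  expect_equal(compute_auc(E * 60, 10 * y, amount_high = 10),
               compute_auc(E, 10 * y))
  expect_equal(compute_auc(E, 5 * y, amount_high = 5),
               compute_auc(E, 10 * y))
  expect_error(compute_auc(E, c(1, NA, 3, 4, 5)), "missing")
  expect_error(compute_auc(E, c(1, 2, 3, 4, 12)), "amount_high")
  # the anchor helper prepends (reference, amount_high)
  expect_equal(auc_from_indifference(c(5, 10, 20, 30), 10 * y[-1]),
               compute_auc(E, 10 * y))
})

test_that("gain_loss_contrast handles regular and degenerate input", {
  g <- c(0.5, 0.6, 0.7, 0.4)
  ct0 <- gain_loss_contrast(g, g)
  expect_identical(ct0$t, 0)
  expect_true(all(ct0$differences == 0))
  # constant non-zero differences: flagged degenerate, infinite t, not NaN
  ctd <- gain_loss_contrast(c(1, 2, 3), c(2, 3, 4))
  expect_true(ctd$degenerate)
  expect_identical(ctd$t, Inf)
  # sqrt transform is applied before differencing
  ct <- gain_loss_contrast(c(1, 4, 9), c(4, 9, 16), transform = "sqrt")
  expect_equal(ct$differences, c(1, 1, 1))
  # agreement with the reference paired t implementation
  set.seed(8)
  a <- runif(12); b <- a + rnorm(12, 0.1, 0.05)
  ct2 <- gain_loss_contrast(a, b)
  tt <- t.test(b, a, paired = TRUE)
  expect_equal(ct2$t, unname(tt$statistic))
  expect_equal(ct2$p, tt$p.value)
  expect_error(gain_loss_contrast(1:2, 2:3), "3 paired")
})
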