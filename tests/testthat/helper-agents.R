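# Shared fixtures built in code.

# A deterministic (beta = Inf) linear-family agent whose true indifference
# point at effort_high = 2 (reference 1) equals `threshold`:
# indiff = 10 (1 - 2k) / (1 - k)  =>  k = (10 - threshold) / (20 - threshold).
threshold_agent <- function(threshold, seed = 1L) {
  stopifnot(threshold > 0, threshold < 10)
  k <- (10 - threshold) / (20 - threshold)
  agent_params(sprintf("thr%.3f", threshold), "linear",
               k_gain = k, k_loss = k, beta = Inf, rng_seed = seed)
}

# Simulated titration choice data for one agent, gain frame: the staircase
# trials double as a realistic fitting dataset (offers concentrate near the
# indifference points). Returns list(trials = data.frame, choices = chr).
staircase_choice_data <- function(agent, effort_levels = c(5, 10, 20, 30),
                                  reference_effort = 1) {
  tt <- titrate_subject(agent, effort_levels,
                        reference_effort = reference_effort)
  tr <- tt$trials[tt$trials$frame == "gain", ]
  list(trials = data.frame(amount_low = tr$net_low,
                           amount_high = tr$net_high,
                           effort_low = reference_effort,
                           effort_high = tr$effort_high),
       choices = tr$choice)
}

# Independent high-precision inverse standard-normal CDF via root finding
# on pnorm; used as the SDT oracle (never calls qnorm).
z_oracle <- function(p) {
  vapply(p, function(pp)
    stats::uniroot(function(z) stats::pnorm(z) - pp,
                   lower = -10, upper = 10, tol = 1e-12)$root,
    numeric(1L))
}

# Fine-grid quadrature oracle for the normalized area under a piecewise
# linear curve through (x, y), independent of the trapezoid path.
auc_oracle <- function(x, y, n_grid = 200001L) {
  f <- stats::approxfun(x, y)
  g <- seq(min(x), max(x), length.out = n_grid)
  h <- g[2L] - g[1L]
  (sum(f(g)) - (f(g[1L]) + f(g[n_grid])) / 2) * h / (max(x) - min(x))
}
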