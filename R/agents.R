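#' Synthetic discounting agent
#'
#' An agent is a generative model of one participant in the effort
#' discounting task: a true discount family, frame-specific discount rates
#' (`k_gain`, `k_loss`), and a softmax inverse temperature `beta`
#' controlling decision noise (`beta = Inf` gives a deterministic value
#' maximiser). Each agent owns a private seeded RNG stream; successive
#' [simulate_choice()] calls consume draws from it without touching the
#' global RNG.
#'
#' @param subject_id identifier.
#' @param family one of [discount_families()].
#' @param k_gain,k_loss discount rates (>= 0), family-specific scale.
#' @param beta softmax inverse temperature (per dollar, >= 0; may be `Inf`).
#' @param p_sigmoid sigmoid inflection point; required iff
#'   `family == "sigmoid"`.
#' @param rng_seed integer seed for the agent's private choice stream.
#' @return object of class `agent_params`.
#' @export
agent_params <- function(subject_id, family, k_gain, k_loss, beta,
                         p_sigmoid = NULL, rng_seed = 1L) {
  family <- match.arg(family, discount_families())
  if (k_gain < 0 || k_loss < 0) stop_ef("discount rates must be non-negative")
  if (beta < 0) stop_ef("beta must be non-negative")
  if (family == "sigmoid" && is.null(p_sigmoid))
    stop_ef("sigmoid family requires p_sigmoid")
  state <- new.env(parent = emptyenv())
  state$seed <- with_seed(rng_seed, get(".Random.seed", envir = globalenv()))
  structure(list(subject_id = subject_id, family = family,
                 k_gain = k_gain, k_loss = k_loss, beta = beta,
                 p_sigmoid = p_sigmoid, rng_seed = rng_seed,
                 .state = state),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent> %s  family=%s k_gain=%.4g k_loss=%.4g beta=%s seed=%d\n",
              x$subject_id, x$family, x$k_gain, x$k_loss,
              format(x$beta), x$rng_seed))
  invisible(x)
}

# Draw n uniforms from the agent's private stream.
agent_runif <- function(agent, n = 1L) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  assign(".Random.seed", agent$.state$seed, envir = env)
  u <- stats::runif(n)
  agent$.state$seed <- get(".Random.seed", envir = env, inherits = FALSE)
  if (had) assign(".Random.seed", old, envir = env)
  else rm(".Random.seed", envir = env)
  u
}

#' One titration choice trial
#'
#' The low-effort option is the reference task (1 min vigilance or 1-back)
#' for a variable amount; the high-effort option is a longer/harder task
#' for a fixed amount. Amounts are stored as NET outcomes in both frames;
#' loss-frame trials additionally record the endowment and the loss each
#' option incurs (see [peg_loss_trial()]).
#'
#' @param effort_low,effort_high effort magnitudes (`effort_low < effort_high`).
#' @param amount_low,amount_high net dollar outcomes
#'   (`0 <= amount_low <= amount_high`).
#' @param frame `"gain"` or `"loss"`.
#' @param endowment dollars held before the choice (loss frame only).
#' @return object of class `choice_trial` (a named list).
#' @export
choice_trial <- function(effort_low, effort_high, amount_low, amount_high,
                         frame = c("gain", "loss"), endowment = NA_real_) {
  frame <- match.arg(frame)
  if (amount_low < 0 || amount_high < 0) stop_ef("amounts must be non-negative")
  if (amount_low > amount_high) stop_ef("amount_low must not exceed amount_high")
  if (effort_low >= effort_high) stop_ef("effort_low must be below effort_high")
  loss_low <- loss_high <- NA_real_
  if (frame == "loss") {
    if (is.na(endowment)) stop_ef("loss-frame trials need an endowment")
    loss_low <- endowment - amount_low
    loss_high <- endowment - amount_high
  }
  structure(list(effort_low = effort_low, effort_high = effort_high,
                 amount_low = amount_low, amount_high = amount_high,
                 frame = frame, endowment = endowment,
                 loss_low = loss_low, loss_high = loss_high),
            class = "choice_trial")
}

#' Construct the loss-framed counterpart of a gain trial (pegging)
#'
#' The loss trial starts from an endowment equal to the gain trial's fixed
#' amount. Choosing the low-effort option loses
#' `L = endowment - amount_low` (net outcome `amount_low`); choosing the
#' high-effort option loses nothing (net outcome `endowment`). Net outcomes
#' therefore match the gain trial exactly, so the two frames differ only in
#' presentation.
#'
#' @param gain_trial a gain-frame [choice_trial()].
#' @param endowment dollars; must equal the gain trial's `amount_high`.
#' @return a loss-frame `choice_trial`.
#' @export
peg_loss_trial <- function(gain_trial, endowment = gain_trial$amount_high) {
  if (gain_trial$frame != "gain") stop_ef("peg_loss_trial expects a gain trial")
  if (!isTRUE(all.equal(endowment, gain_trial$amount_high)))
    stop_ef("endowment must equal the gain trial's amount_high")
  if (gain_trial$amount_low > endowment)
    stop_ef("amount_low exceeds the endowment")
  choice_trial(gain_trial$effort_low, gain_trial$effort_high,
               amount_low = gain_trial$amount_low,
               amount_high = endowment,
               frame = "loss", endowment = endowment)
}

#' Recover the gain trial that a loss trial was pegged to
#' @param loss_trial a loss-frame [choice_trial()].
#' @export
unpeg_loss_trial <- function(loss_trial) {
  if (loss_trial$frame != "loss") stop_ef("unpeg_loss_trial expects a loss trial")
  choice_trial(loss_trial$effort_low, loss_trial$effort_high,
               amount_low = loss_trial$amount_low,
               amount_high = loss_trial$endowment,
               frame = "gain")
}

# Frame-appropriate discount rate.
agent_k <- function(agent, frame) {
  if (frame == "gain") agent$k_gain else agent$k_loss
}

#' Softmax probability that an agent picks the high-effort option
#'
#' @param agent an [agent_params()] object.
#' @param trial a [choice_trial()].
#' @return `P(high_effort) = logistic(beta * (SV_high - SV_low))`, with the
#'   deterministic limit at `beta = Inf` (1 / 0 / 0.5 at a tie).
#' @export
choice_prob_high <- function(agent, trial) {
  k <- agent_k(agent, trial$frame)
  sv_low <- subjective_value(agent$family, trial$amount_low, trial$effort_low,
                             k, agent$p_sigmoid)
  sv_high <- subjective_value(agent$family, trial$amount_high, trial$effort_high,
                              k, agent$p_sigmoid)
  dv <- sv_high - sv_low
  if (is.infinite(agent$beta)) {
    if (dv > 0) 1 else if (dv < 0) 0 else 0.5
  } else {
    stats::plogis(agent$beta * dv)
  }
}

#' Simulate one choice of a discounting agent
#'
#' Samples `high_effort` with probability
#' `logistic(beta * (SV_high - SV_low))` using the agent's family and the
#' frame-appropriate k. With `beta = Inf` the higher-valued option is
#' chosen deterministically; an exact tie resolves to `low_effort`
#' (documented tie rule: take the sure small amount). Random draws come
#' from the agent's private seeded stream.
#'
#' @inheritParams choice_prob_high
#' @return `"low_effort"` or `"high_effort"`.
#' @export
simulate_choice <- function(agent, trial) {
  if (!inherits(agent, "agent_params")) stop_ef("agent must be agent_params")
  if (!inherits(trial, "choice_trial")) stop_ef("trial must be a choice_trial")
  if (is.infinite(agent$beta)) {
    k <- agent_k(agent, trial$frame)
    sv_low <- subjective_value(agent$family, trial$amount_low, trial$effort_low,
                               k, agent$p_sigmoid)
    sv_high <- subjective_value(agent$family, trial$amount_high, trial$effort_high,
                                k, agent$p_sigmoid)
    return(if (sv_high > sv_low) "high_effort" else "low_effort")
  }
  p_high <- choice_prob_high(agent, trial)
  if (agent_runif(agent) < p_high) "high_effort" else "low_effort"
}

#' True indifference point of an agent at one effort level
#'
#' The low-effort amount `A` solving `SV(A, E_ref) = SV(M, E)` under the
#' agent's frame-specific parameters; used as ground truth in recovery
#' tests. Solved in closed form for all families except sigmoid (bisection).
#'
#' @inheritParams choice_prob_high
#' @param effort_high high effort level.
#' @param frame `"gain"` or `"loss"`.
#' @param amount_high fixed large amount.
#' @param reference_effort effort of the reference option.
#' @export
true_indifference <- function(agent, effort_high, frame = "gain",
                              amount_high = 10, reference_effort = 1) {
  k <- agent_k(agent, frame)
  target <- subjective_value(agent$family, amount_high, effort_high,
                             k, agent$p_sigmoid)
  # SV is linear in amount at fixed effort: SV(A, E) = A * w(E)
  w_ref <- subjective_value(agent$family, 1, reference_effort, k, agent$p_sigmoid)
  if (w_ref <= 0) return(amount_high)  # reference effort already worthless
  min(amount_high, target / w_ref)
}
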