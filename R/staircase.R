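#' Adaptive bisection staircase for effort indifference points
#'
#' The titration dynamically updates the low-effort offer after each choice
#' to approach the point where the participant values the two options
#' equally. The update rule is a midpoint bisection on
#' `[0, amount_high]`: accepting the offer (choosing `low_effort`) lowers
#' the upper bound to the current offer, rejecting it raises the lower
#' bound, and the next offer is the midpoint of the bounds. Five
#' iterations shrink the interval to `amount_high / 2^5`, and the terminal
#' estimate is the midpoint of the final interval. Two runs are averaged
#' per effort level.
#'
#' @param amount_high upper end of the offer range (dollars, default 10).
#' @param max_iterations choices per run (default 5).
#' @return object of class `staircase_state`.
#' @export
staircase_state <- function(amount_high = 10, max_iterations = 5L) {
  if (amount_high <= 0) stop_ef("amount_high must be positive")
  structure(list(lower_bound = 0, upper_bound = amount_high,
                 current_offer = amount_high / 2,
                 iteration = 0L, max_iterations = as.integer(max_iterations),
                 history = list()),
            class = "staircase_state")
}

#' Advance a staircase by one observed choice
#'
#' @param state a [staircase_state()].
#' @param choice `"low_effort"` (offer accepted) or `"high_effort"`.
#' @return the updated state; `current_offer` is the next offer to present.
#' @export
update_staircase <- function(state, choice) {
  if (!inherits(state, "staircase_state")) stop_ef("not a staircase_state")
  if (state$iteration >= state$max_iterations)
    stop_ef("staircase already ran its %d iterations", state$max_iterations)
  choice <- match.arg(choice, c("low_effort", "high_effort"))
  if (choice == "low_effort") {
    state$upper_bound <- state$current_offer
  } else {
    state$lower_bound <- state$current_offer
  }
  state$history[[length(state$history) + 1L]] <-
    list(offer = state$current_offer, choice = choice)
  state$iteration <- state$iteration + 1L
  state$current_offer <- (state$lower_bound + state$upper_bound) / 2
  state
}

#' Terminal indifference estimate of a finished staircase
#' @param state a [staircase_state()] after its final update.
#' @return midpoint of the final interval (equals `current_offer`).
#' @export
staircase_estimate <- function(state) {
  (state$lower_bound + state$upper_bound) / 2
}

#' Run the full titration for one effort level and frame
#'
#' Executes `n_runs` staircases of `max_iterations` choice trials each and
#' returns the mean terminal estimate. Choices come either from a
#' simulated [agent_params()] or, in replay mode, from a recorded choice
#' sequence (so real trial tables can be re-scored). In the loss frame
#' each presented trial is the pegged counterpart of the gain trial with
#' identical net outcomes.
#'
#' @param agent an [agent_params()], or `NULL` in replay mode.
#' @param effort_high the high effort level being titrated.
#' @param frame `"gain"` or `"loss"`.
#' @param amount_high fixed large amount (dollars).
#' @param reference_effort effort of the low option (1 min / 1-back).
#' @param n_runs,max_iterations staircase geometry (2 runs x 5 trials).
#' @param choices optional recorded character vector of length
#'   `n_runs * max_iterations` (replay mode; overrides `agent`).
#' @return list with `indifference` (mean over runs), `per_run` estimates,
#'   and `trials` (data frame of every presented trial and choice).
#' @export
run_staircase <- function(agent, effort_high, frame = c("gain", "loss"),
                          amount_high = 10, reference_effort = 1,
                          n_runs = 2L, max_iterations = 5L,
                          choices = NULL) {
  frame <- match.arg(frame)
  replay <- !is.null(choices)
  if (replay && length(choices) != n_runs * max_iterations)
    stop_ef("replay needs %d recorded choices", n_runs * max_iterations)
  if (!replay && !inherits(agent, "agent_params"))
    stop_ef("agent must be agent_params (or provide recorded choices)")

  trial_at <- function(offer) {
    g <- choice_trial(reference_effort, effort_high, offer, amount_high,
                      frame = "gain")
    if (frame == "gain") g else peg_loss_trial(g, endowment = amount_high)
  }

  n_tot <- n_runs * max_iterations
  per_run <- numeric(n_runs)
  v_run <- integer(n_tot); v_iter <- integer(n_tot)
  v_offer <- numeric(n_tot); v_loss <- numeric(n_tot)
  v_choice <- character(n_tot)
  idx <- 0L
  for (r in seq_len(n_runs)) {
    st <- staircase_state(amount_high, max_iterations)
    for (i in seq_len(max_iterations)) {
      idx <- idx + 1L
      tr <- trial_at(st$current_offer)
      ch <- if (replay) choices[idx] else simulate_choice(agent, tr)
      v_run[idx] <- r; v_iter[idx] <- i
      v_offer[idx] <- st$current_offer
      v_loss[idx] <- if (frame == "loss") tr$loss_low else NA_real_
      v_choice[idx] <- ch
      st <- update_staircase(st, ch)
    }
    per_run[r] <- staircase_estimate(st)
  }
  trials <- data.frame(run = v_run, iteration = v_iter, frame = frame,
                       effort_high = effort_high, offer = v_offer,
                       amount_high = amount_high,
                       net_low = v_offer, net_high = amount_high,
                       loss_low = v_loss, choice = v_choice)
  list(indifference = mean(per_run), per_run = per_run, trials = trials)
}

#' Titrate indifference points for a whole subject
#'
#' Runs [run_staircase()] for every effort level in both frames and
#' returns the subject's indifference table. When `interleaved = TRUE`
#' (trial-by-trial intermixing of gain and loss), the two frames'
#' staircases still update separately, so estimates are identical to the
#' blocked schedule for a given agent stream order; the flag only changes
#' the recorded presentation order.
#'
#' @param agent an [agent_params()].
#' @param effort_levels high effort levels, e.g. `c(5, 10, 20, 30)` minutes
#'   or `c(2, 3, 4)` for N-back load.
#' @inheritParams run_staircase
#' @param interleaved logical; annotate trials with an intermixed schedule.
#' @return list with `indifference` (data frame subject, frame,
#'   effort_level, indifference) and `trials` (all presented trials).
#' @export
titrate_subject <- function(agent, effort_levels, amount_high = 10,
                            reference_effort = 1, n_runs = 2L,
                            max_iterations = 5L, interleaved = FALSE) {
  grid <- expand.grid(frame = c("gain", "loss"), effort = effort_levels,
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res[[i]] <- run_staircase(agent, grid$effort[i], grid$frame[i],
                              amount_high, reference_effort,
                              n_runs, max_iterations)
  }
  ind <- data.frame(subject = agent$subject_id,
                    frame = grid$frame, effort_level = grid$effort,
                    indifference = vapply(res, `[[`, numeric(1L), "indifference"))
  trials <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(subject = agent$subject_id, res[[i]]$trials)))
  if (interleaved) {
    # stable round-robin over (frame, level) staircases: same per-frame
    # estimates, different presentation order
    trials <- trials[order(trials$run, trials$iteration,
                           trials$effort_high, trials$frame), ]
    rownames(trials) <- NULL
  }
  list(indifference = ind, trials = trials)
}
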