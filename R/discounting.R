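#' @title Effort-discounting value functions and model fitting
#' @name discounting
#' @description
#' Five one-parameter discount families map a monetary amount `M` and an
#' effort magnitude `E` (task duration in minutes, or working-memory load)
#' to a subjective value, discounted at rate `k`:
#' hyperbolic `M/(1+kE)`, exponential `M exp(-kE)`, linear `M(1-kE)`,
#' quadratic `M(1-kE^2)`, and a rescaled sigmoid with inflection `p`.
#' Subjective values are floored at zero: in this design a task cannot be
#' worth less than nothing, and the floor keeps choice likelihoods finite.
NULL

#' Discount families supported by the package
#'
#' Order is fixed and used as the final tie-break in model comparison.
#' @export
discount_families <- function() {
  c("hyperbolic", "exponential", "linear", "quadratic", "sigmoid")
}

n_params_family <- function(family) {
  # k + softmax beta, plus the sigmoid inflection point
  ifelse(family == "sigmoid", 3L, 2L)
}

#' Subjective value of an effortful offer
#'
#' @param family one of [discount_families()].
#' @param M monetary amount (dollars, >= 0). Vectorised.
#' @param E effort magnitude (minutes or N-back load, >= 0). Vectorised.
#' @param k discount rate (>= 0), on the family's own scale.
#' @param p_sigmoid inflection point (effort units); required for the
#'   sigmoid family, ignored otherwise.
#' @return subjective value in dollars, clipped below at 0.
#' @details The sigmoid family is rescaled so that SV(0) = M exactly:
#'   `SV = M * (1 - (g(E) - g(0)) / (1 - g(0)))` with
#'   `g(E) = 1 / (1 + exp(-k (E - p)))`.
#' @examples
#' subjective_value("hyperbolic", 10, 5, 0.2)   # 5
#' subjective_value("quadratic", 10, 30, 1/900) # 0
#' @export
subjective_value <- function(family, M, E, k, p_sigmoid = NULL) {
  family <- match.arg(family, discount_families())
  if (any(M < 0)) stop_ef("amounts must be non-negative")
  if (any(E < 0)) stop_ef("effort must be non-negative")
  if (any(k < 0)) stop_ef("discount rate k must be non-negative")
  sv <- switch(family,
    hyperbolic  = M / (1 + k * E),
    exponential = M * exp(-k * E),
    linear      = M * (1 - k * E),
    quadratic   = M * (1 - k * E^2),
    sigmoid     = {
      if (is.null(p_sigmoid)) stop_ef("sigmoid family requires p_sigmoid")
      g  <- stats::plogis(k * (E - p_sigmoid))
      g0 <- stats::plogis(-k * p_sigmoid)
      denom <- 1 - g0
      # k = 0 makes the rescaling 0/0; the limit is no discounting
      if (k == 0 || denom <= 0) M else M * (1 - (g - g0) / denom)
    }
  )
  pmax(sv, 0)
}

# Subjective values of both options of a choice trial under one parameter set.
# Loss-frame trials are valued on their NET outcomes, which the pegging rule
# makes identical to the matched gain trial, so a single value function
# serves both frames with a frame-specific k.
trial_values <- function(trials, family, k, p_sigmoid = NULL) {
  list(
    low  = subjective_value(family, trials$amount_low,  trials$effort_low,  k, p_sigmoid),
    high = subjective_value(family, trials$amount_high, trials$effort_high, k, p_sigmoid)
  )
}

#' Log-likelihood of observed choices under a softmax discounting model
#'
#' @param trials data frame with columns `amount_low`, `amount_high`,
#'   `effort_low`, `effort_high` (net outcomes; see [peg_loss_trial()]).
#' @param choices character vector, `"low_effort"` or `"high_effort"`,
#'   one per trial.
#' @param family discount family.
#' @param k,beta discount rate and softmax inverse temperature.
#' @param p_sigmoid sigmoid inflection (sigmoid family only).
#' @return sum over trials of `log P(observed choice)`, with
#'   `P(high) = logistic(beta * (SV_high - SV_low))`.
#' @export
choice_loglik <- function(trials, choices, family, k, beta, p_sigmoid = NULL) {
  if (nrow(trials) == 0L) stop_ef("choice_loglik needs at least one trial")
  if (length(choices) != nrow(trials))
    stop_ef("choices must match trials one-to-one")
  if (beta < 0) stop_ef("beta must be non-negative")
  sv <- trial_values(trials, family, k, p_sigmoid)
  p_high <- stats::plogis(beta * (sv$high - sv$low))
  p <- ifelse(choices == "high_effort", p_high, 1 - p_high)
  sum(log(pmax(p, .Machine$double.xmin)))
}

# Deterministic multi-start grids. Starts and bounds are scaled by the
# largest effort in the data so that k * E^order spans the informative
# range whatever the effort units (minutes vs N-back load).
fit_start_grid <- function(family, e_max) {
  ord <- if (family == "quadratic") 2 else 1
  scale <- e_max^ord
  list(
    k_starts = c(0.02, 0.1, 0.5, 2, 10) / scale,
    k_max    = 50 / scale,
    beta_starts = c(0.5, 5, 50),
    beta_bounds = c(0.01, 100),
    p_starts = c(0.3, 0.6) * e_max,
    p_bounds = c(0.05, e_max)
  )
}

#' Fit one discount family to trial-level choices by maximum likelihood
#'
#' Softmax MLE over `(k, beta[, p_sigmoid])` using a deterministic
#' multi-start bounded `optim(..., method = "L-BFGS-B")`; the start grid is
#' documented in [fit_start_grid()] internals and scaled to the data's
#' effort range, so the fit is reproducible with no RNG involvement.
#'
#' @inheritParams choice_loglik
#' @param subject_id,frame carried into the returned record.
#' @return an object of class `discount_fit`: list with `family`, `k`,
#'   `beta`, `p_sigmoid`, `loglik`, `n_trials`, `n_params`, `bic`,
#'   `converged`.
#' @export
fit_discount_model <- function(trials, choices, family,
                               subject_id = NA_character_, frame = NA_character_) {
  family <- match.arg(family, discount_families())
  np <- n_params_family(family)
  if (nrow(trials) < np + 1L)
    stop_ef("need at least %d trials to fit a %d-parameter model", np + 1L, np)
  grid <- fit_start_grid(family, max(trials$effort_high))
  has_p <- family == "sigmoid"

  nll <- function(par) {
    -choice_loglik(trials, choices, family,
                   k = par[1L], beta = par[2L],
                   p_sigmoid = if (has_p) par[3L] else NULL)
  }
  lower <- c(0, grid$beta_bounds[1L], if (has_p) grid$p_bounds[1L])
  upper <- c(grid$k_max, grid$beta_bounds[2L], if (has_p) grid$p_bounds[2L])

  starts <- expand.grid(k = grid$k_starts, beta = grid$beta_starts,
                        p = if (has_p) grid$p_starts else NA_real_)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    par0 <- c(starts$k[i], starts$beta[i], if (has_p) starts$p[i])
    # parscale matters: k lives orders of magnitude below beta
    pscale <- c(max(grid$k_max / 50, 1e-8), 10, if (has_p) grid$p_bounds[2L] / 2)
    fit <- tryCatch(
      stats::optim(par0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500L, parscale = pscale)),
      error = function(e) NULL)
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop_ef("all optimizer starts failed for family '%s'", family)

  loglik <- -best$value
  n <- nrow(trials)
  structure(list(
    subject_id = subject_id, frame = frame, family = family,
    k = best$par[1L], beta = best$par[2L],
    p_sigmoid = if (has_p) best$par[3L] else NA_real_,
    loglik = loglik, n_trials = n, n_params = np,
    bic = np * log(n) - 2 * loglik,
    converged = any_conv
  ), class = "discount_fit")
}

#' @export
print.discount_fit <- function(x, ...) {
  cat(sprintf("<discount_fit> %s  k=%.5g beta=%.3g loglik=%.3f BIC=%.2f (n=%d)\n",
              x$family, x$k, x$beta, x$loglik, x$bic, x$n_trials))
  invisible(x)
}

#' Fit all five discount families to one subject's choices
#'
#' @inheritParams fit_discount_model
#' @return named list of `discount_fit`, in [discount_families()] order.
#' @export
fit_all_families <- function(trials, choices,
                             subject_id = NA_character_, frame = NA_character_) {
  fams <- discount_families()
  stats::setNames(lapply(fams, function(f)
    fit_discount_model(trials, choices, f, subject_id, frame)), fams)
}

#' Compare fitted discount families by BIC
#'
#' Per-subject winner is the lowest BIC; ties go to the family with fewer
#' parameters, then to the fixed order of [discount_families()]. The group
#' table sums BIC per family across subjects and tallies winners.
#'
#' @param fits_by_subject list (one element per subject) of named lists of
#'   `discount_fit`, as returned by [fit_all_families()]. All families
#'   within one subject must be fitted on the identical trial set.
#' @return list with `per_subject` (data frame subject/winner), `group`
#'   (data frame family/sum_bic/n_wins) and `group_winner`.
#' @export
compare_models <- function(fits_by_subject) {
  fams <- discount_families()
  rows <- lapply(seq_along(fits_by_subject), function(i) {
    fits <- fits_by_subject[[i]]
    if (!setequal(names(fits), fams))
      stop_ef("subject %d is missing fits for some families", i)
    n_tr <- vapply(fits, function(f) f$n_trials, integer(1L))
    if (length(unique(n_tr)) != 1L)
      stop_ef("subject %d: families were fitted on different trial sets", i)
    bic <- vapply(fits[fams], function(f) f$bic, numeric(1L))
    np  <- vapply(fits[fams], function(f) f$n_params, integer(1L))
    ord <- order(bic, np, seq_along(fams))
    data.frame(subject = fits[[1L]]$subject_id %||% i,
               winner = fams[ord[1L]],
               t(bic), check.names = FALSE, stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  sum_bic <- colSums(as.matrix(per_subject[, fams, drop = FALSE]))
  n_wins <- vapply(fams, function(f) sum(per_subject$winner == f), integer(1L))
  group <- data.frame(family = fams, sum_bic = as.numeric(sum_bic),
                      n_wins = as.integer(n_wins), row.names = NULL)
  gord <- order(group$sum_bic,
                vapply(fams, n_params_family, integer(1L)),
                seq_along(fams))
  list(per_subject = per_subject, group = group,
       group_winner = fams[gord[1L]])
}

#' Area under the effort-discounting curve
#'
#' Indifference points are normalised (`x = E / max(E)`,
#' `y = indifference / amount_high`) and integrated by the trapezoid rule
#' over `[x_first, x_last]`, then divided by `x_last - x_first` so the
#' result lies in `[0, 1]`; larger AUC denotes less discounting. The
#' reference (lowest) effort level anchors the curve at y = 1 and must be
#' included: [auc_from_indifference()] adds it for you.
#'
#' @param effort effort magnitudes, strictly increasing, including the
#'   reference level.
#' @param indifference indifference points in dollars, same length.
#' @param amount_high the fixed large amount (default 10).
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(effort, indifference, amount_high = 10) {
  if (length(effort) != length(indifference) || length(effort) < 2L)
    stop_ef("need >= 2 (effort, indifference) pairs")
  if (is.unsorted(effort, strictly = TRUE))
    stop_ef("effort levels must be strictly increasing")
  if (any(is.na(indifference)))
    stop_ef("missing indifference point")
  if (any(indifference < 0 | indifference > amount_high))
    stop_ef("indifference points must lie in [0, amount_high]")
  x <- effort / max(effort)
  y <- indifference / amount_high
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  area / (x[length(x)] - x[1L])
}

#' AUC from an indifference table row-set, adding the reference anchor
#'
#' @param effort measured (non-reference) effort levels.
#' @param indifference their indifference points.
#' @param reference_effort the low-effort reference level (1 min / 1-back).
#' @inheritParams compute_auc
#' @export
auc_from_indifference <- function(effort, indifference,
                                  reference_effort = 1, amount_high = 10) {
  ord <- order(effort)
  compute_auc(c(reference_effort, effort[ord]),
              c(amount_high, indifference[ord]),
              amount_high = amount_high)
}

#' Paired gain-loss contrast of a per-subject metric
#'
#' Computes per-subject differences (loss minus gain), the mean difference,
#' and a two-sided paired t test with `df = n - 1`. For discount rates the
#' square-root transform is applied first to correct for non-normality
#' (`transform = "sqrt"`).
#'
#' @param gain,loss numeric vectors, paired by subject.
#' @param transform `"identity"` or `"sqrt"`.
#' @return list with `differences`, `mean_diff`, `t`, `df`, `p`,
#'   `degenerate` (TRUE when all differences are identical and non-zero,
#'   which yields an infinite t rather than NaN).
#' @export
gain_loss_contrast <- function(gain, loss, transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  if (length(gain) != length(loss)) stop_ef("gain and loss must be paired")
  n <- length(gain)
  if (n < 3L) stop_ef("need at least 3 paired subjects")
  if (transform == "sqrt") {
    if (any(gain < 0 | loss < 0)) stop_ef("sqrt transform needs non-negative values")
    gain <- sqrt(gain); loss <- sqrt(loss)
  }
  d <- loss - gain
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    degenerate <- any(d != 0)
    tval <- if (degenerate) sign(md) * Inf else 0
    p <- if (degenerate) 0 else 1
  } else {
    degenerate <- FALSE
    tval <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(tval), df = n - 1L)
  }
  list(differences = d, mean_diff = md, t = tval, df = n - 1L, p = p,
       degenerate = degenerate)
}
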