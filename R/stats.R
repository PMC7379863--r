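#' One-way repeated-measures ANOVA
#'
#' Classical within-subject F for a complete subject x condition matrix:
#' `F = MS_condition / MS_(condition x subject)`, with
#' `df = (c - 1, (c - 1)(n - 1))`. No sphericity correction is applied by
#' default (Greenhouse-Geisser available behind a flag); with balanced
#' complete data Type II and Type III sums of squares coincide.
#'
#' @param values numeric matrix or data frame, rows = subjects,
#'   columns = conditions; no missing cells.
#' @param gg logical; apply the Greenhouse-Geisser epsilon correction to
#'   the degrees of freedom (and hence the p value).
#' @return list with `F`, `df1`, `df2`, `p`, `epsilon` and the grand/cell
#'   means, of class `ef_stat`.
#' @export
rm_anova <- function(values, gg = FALSE) {
  x <- as.matrix(values)
  if (any(!is.finite(x))) stop_ef("rm_anova requires complete cases")
  n <- nrow(x); c <- ncol(x)
  if (n < 2L || c < 2L) stop_ef("need >= 2 subjects and >= 2 conditions")
  gm <- mean(x)
  col_m <- colMeans(x); row_m <- rowMeans(x)
  ss_cond <- n * sum((col_m - gm)^2)
  ss_subj <- c * sum((row_m - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- c - 1L; df2 <- (c - 1L) * (n - 1L)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  Fv <- if (ms_err == 0) { if (ms_cond == 0) 0 else Inf } else ms_cond / ms_err
  eps <- 1
  if (gg) {
    S <- stats::cov(x)
    dbar <- mean(diag(S)); sbar <- mean(S)
    num <- (c * (dbar - sbar))^2
    den <- (c - 1) * (sum(S^2) - 2 * c * sum(rowMeans(S)^2) + c^2 * sbar^2)
    eps <- if (den > 0) min(1, num / den) else 1
  }
  p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  structure(list(test = "rm_anova", F = Fv, df1 = df1 * eps, df2 = df2 * eps,
                 p = p, epsilon = eps, cell_means = col_m),
            class = "ef_stat")
}

#' @export
print.ef_stat <- function(x, ...) {
  cat(sprintf("<%s> F(%.3g, %.3g) = %.4g, p = %.4g\n",
              x$test, x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' Incentive x Order mixed ANOVA interaction
#'
#' Tests whether the within-subject gain/loss difference depends on the
#' between-subjects order group (gain-first vs loss-first). For a 2
#' (within) x 2 (between) design the interaction F equals the squared
#' two-sample t on per-subject difference scores, with
#' `df = (1, n - 2)`. Per-group paired-t follow-ups are included.
#'
#' @param gain,loss per-subject values, paired.
#' @param order factor/character of length n with two levels identifying
#'   each subject's condition order.
#' @return list with interaction `F`, `df1`, `df2`, `p` and a `follow_up`
#'   data frame of within-group paired t tests, class `ef_stat`.
#' @export
mixed_anova_order <- function(gain, loss, order) {
  n <- length(gain)
  if (length(loss) != n || length(order) != n)
    stop_ef("gain, loss and order must be the same length")
  order <- as.factor(order)
  if (nlevels(order) != 2L) stop_ef("order must have exactly two groups")
  if (any(table(order) < 2L)) stop_ef("each order group needs >= 2 subjects")
  d <- loss - gain
  g1 <- d[order == levels(order)[1L]]
  g2 <- d[order == levels(order)[2L]]
  sp2 <- ((length(g1) - 1L) * stats::var(g1) +
          (length(g2) - 1L) * stats::var(g2)) / (n - 2L)
  se <- sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  tval <- if (se == 0) { if (mean(g1) == mean(g2)) 0 else Inf }
          else (mean(g1) - mean(g2)) / se
  Fv <- tval^2
  p <- stats::pf(Fv, 1, n - 2L, lower.tail = FALSE)
  # incentive main effect on the same within-subject error; swapping the
  # gain/loss labels inside one group exchanges this with the interaction
  t_main <- if (se == 0) { if (mean(g1) + mean(g2) == 0) 0 else Inf }
            else (mean(g1) + mean(g2)) / 2 / (se / 2)
  F_main <- t_main^2
  p_main <- stats::pf(F_main, 1, n - 2L, lower.tail = FALSE)
  follow <- do.call(rbind, lapply(levels(order), function(lv) {
    dd <- d[order == lv]
    m <- mean(dd); s <- stats::sd(dd)
    tv <- if (s == 0) { if (m == 0) 0 else sign(m) * Inf }
          else m / (s / sqrt(length(dd)))
    data.frame(order = lv, n = length(dd), mean_diff = m, t = tv,
               df = length(dd) - 1L,
               p = 2 * stats::pt(-abs(tv), df = length(dd) - 1L))
  }))
  structure(list(test = "mixed_anova_order", F = Fv, df1 = 1L, df2 = n - 2L,
                 p = p, F_main = F_main, p_main = p_main,
                 follow_up = follow),
            class = "ef_stat")
}
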