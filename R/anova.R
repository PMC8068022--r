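# Closed-form balanced ANOVA. The study design has exactly one observation
# per subject x task cell, so the two-way model is necessarily additive (no
# interaction term is estimable) and the sums of squares have closed forms.

#' Two-way additive ANOVA for a complete balanced table
#'
#' For a T x S table (rows = tasks, columns = subjects) with one observation
#' per cell, the additive decomposition is
#' `SS_task = S * sum_t (rowmean_t - grand)^2`,
#' `SS_subject = T * sum_s (colmean_s - grand)^2`,
#' `SS_residual = SS_total - SS_task - SS_subject`, with degrees of freedom
#' T-1, S-1 and (T-1)(S-1). F statistics use the residual mean square; a
#' perfectly additive table (zero residual) yields infinite F, flagged with
#' p = 0.
#'
#' @param values Numeric matrix, rows = levels of the first factor (task),
#'   columns = levels of the second (subject). No missing cells allowed.
#' @return An `anova_result` data.frame with rows task/subject/residual and
#'   columns `ss`, `df`, `ms`, `f`, `p`.
#' @export
two_way_anova <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("table has missing or non-finite cells; imputation is not supported")
  t_n <- nrow(values)
  s_n <- ncol(values)
  if (t_n < 2 || s_n < 2)
    stop("both factors need at least 2 levels, got ", t_n, " x ", s_n)
  grand <- mean(values)
  ss_task <- s_n * sum((rowMeans(values) - grand)^2)
  ss_subj <- t_n * sum((colMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_res <- ss_tot - ss_task - ss_subj
  ss_res <- max(ss_res, 0)  # guard tiny negative rounding
  df_task <- t_n - 1
  df_subj <- s_n - 1
  df_res <- df_task * df_subj
  ms_res <- ss_res / df_res
  f_of <- function(ss, df) {
    ms <- ss / df
    if (ms_res == 0) if (ms == 0) 0 else Inf else ms / ms_res
  }
  f_task <- f_of(ss_task, df_task)
  f_subj <- f_of(ss_subj, df_subj)
  res <- data.frame(
    effect = c("task", "subject", "residual"),
    ss = c(ss_task, ss_subj, ss_res),
    df = c(df_task, df_subj, df_res),
    ms = c(ss_task / df_task, ss_subj / df_subj, ms_res),
    f = c(f_task, f_subj, NA),
    p = c(p_upper_f(f_task, df_task, df_res),
          p_upper_f(f_subj, df_subj, df_res), NA))
  class(res) <- c("anova_result", "data.frame")
  res
}

#' One-way ANOVA
#'
#' Standard between/within decomposition with F on (k-1, N-k) degrees of
#' freedom; used for the effect of sex on the (unscaled) grip force.
#'
#' @param values Numeric vector of observations.
#' @param groups Parallel factor (at least 2 levels, N >= 3).
#' @return An `anova_result` data.frame with rows group/residual.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) < 3) stop("need at least 3 observations")
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  gn <- tabulate(groups)
  ss_between <- sum(gn * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  ms_w <- ss_within / df_w
  f <- if (ms_w == 0) if (ss_between == 0) 0 else Inf else
    (ss_between / df_b) / ms_w
  res <- data.frame(
    effect = c("group", "residual"),
    ss = c(ss_between, ss_within),
    df = c(df_b, df_w),
    ms = c(ss_between / df_b, ms_w),
    f = c(f, NA),
    p = c(p_upper_f(f, df_b, df_w), NA))
  class(res) <- c("anova_result", "data.frame")
  res
}

p_upper_f <- function(f, df1, df2) {
  if (!is.finite(f)) return(if (is.infinite(f)) 0 else NA_real_)
  stats::pf(f, df1, df2, lower.tail = FALSE)
}
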