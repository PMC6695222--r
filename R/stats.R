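#' Independent-samples t test between two groups
#'
#' Two-tailed independent-samples t test for a difference in means,
#' Student's pooled-variance version by default (`welch = TRUE` for the
#' unequal-variance form). The statistic is computed for
#' `group_a` minus `group_b`, so with the control group first a negative t
#' means the second (primed) group scored higher.
#'
#' @param group_a,group_b Numeric vectors, each with at least two finite
#'   values.
#' @param welch Use Welch's unequal-variance t test.
#' @return A one-row tibble: `mean_a`, `mean_b`, `t`, `df`, `p_two_tailed`.
#' @examples
#' ttest_independent(c(0, 2), c(1, 3))  # t = -1, df = 2
#' @export
ttest_independent <- function(group_a, group_b, welch = FALSE) {
  check_group <- function(x, nm) {
    if (length(x) < 2 || any(!is.finite(x))) {
      stop(sprintf("`%s` needs >= 2 finite values", nm), call. = FALSE)
    }
  }
  check_group(group_a, "group_a")
  check_group(group_b, "group_b")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      # degenerate but well-defined null case: no difference, no variance
      return(tibble::tibble(mean_a = mean(group_a), mean_b = mean(group_b),
                            t = 0, df = length(group_a) + length(group_b) - 2,
                            p_two_tailed = 1))
    }
    stop("zero variance in both groups: t statistic undefined",
         call. = FALSE)
  }
  fit <- stats::t.test(group_a, group_b, var.equal = !welch,
                       alternative = "two.sided")
  tibble::tibble(
    mean_a = mean(group_a), mean_b = mean(group_b),
    t = unname(fit$statistic), df = unname(fit$parameter),
    p_two_tailed = fit$p.value
  )
}

#' Cohen's d standardized mean difference
#'
#' `(mean(group_b) - mean(group_a)) / s_pooled`, with the pooled standard
#' deviation using `n - 1` weights. With the control group passed first,
#' positive d means the primed group scored higher — the sign convention
#' used in reports.
#'
#' @inheritParams ttest_independent
#' @return Cohen's d (scalar).
#' @examples
#' cohens_d(c(0, 2), c(1, 3))  # 1/sqrt(2)
#' @export
cohens_d <- function(group_a, group_b) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  stopifnot(n1 >= 2, n2 >= 2, all(is.finite(c(group_a, group_b))))
  sp2 <- ((n1 - 1) * stats::var(group_a) + (n2 - 1) * stats::var(group_b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(group_a) == mean(group_b)) return(0)
    stop("zero pooled variance: Cohen's d undefined", call. = FALSE)
  }
  (mean(group_b) - mean(group_a)) / sqrt(sp2)
}

#' Bonferroni-adjusted alpha level
#'
#' Divides the family-wise alpha by the number of comparisons. With
#' `alpha = 0.05` and `m = 7` comparisons the adjusted level is 0.05/7,
#' reported as 0.007 at three decimals.
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons (>= 1).
#' @return The adjusted alpha, with attribute `"reported"` giving the
#'   3-decimal rounding used in text.
#' @examples
#' bonferroni_alpha(0.05, 7)
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 7) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  adj <- alpha / m
  structure(adj, reported = round(adj, 3))
}

#' One-way ANOVA pooling check with Scheffe post-hoc contrasts
#'
#' Before pooling experimental sub-conditions into a single "primed" group,
#' checks each behavioral variable for differences among the sub-conditions
#' with a one-way ANOVA, followed by Scheffe pairwise contrasts (the
#' conservative any-contrast post-hoc). No significant differences justify
#' pooling.
#'
#' @param metrics A [player_metrics()] table whose `condition` column holds
#'   the sub-condition labels.
#' @param variables Variables to test (default: the seven behavioral ones).
#' @param alpha Significance level for flagging.
#' @return A list with `anova`: tibble of `variable`, `F`, `df1`, `df2`,
#'   `p`; and `scheffe`: tibble of pairwise contrasts with Scheffe p-values.
#'   Conditions with fewer than two players are dropped with a warning.
#' @export
condition_pooling_check <- function(metrics,
                                    variables = behavioral_variables(),
                                    alpha = 0.05) {
  counts <- table(metrics$condition)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning("dropping conditions with n < 2: ",
            paste(small, collapse = ", "), call. = FALSE)
    metrics <- metrics[!metrics$condition %in% small, ]
  }
  cond <- factor(metrics$condition)
  k <- nlevels(cond)
  if (k < 2) stop("need at least two conditions", call. = FALSE)

  anova_rows <- list()
  scheffe_rows <- list()
  for (v in variables) {
    y <- metrics[[v]]
    fit <- stats::aov(y ~ cond)
    s <- summary(fit)[[1]]
    F_stat <- s[["F value"]][1]
    df1 <- s[["Df"]][1]
    df2 <- s[["Df"]][2]
    mse <- s[["Mean Sq"]][2]
    anova_rows[[v]] <- tibble::tibble(
      variable = v, F = F_stat, df1 = df1, df2 = df2,
      p = s[["Pr(>F)"]][1]
    )
    means <- tapply(y, cond, mean)
    ns <- tapply(y, cond, length)
    pairs <- utils::combn(levels(cond), 2)
    for (c_i in seq_len(ncol(pairs))) {
      a <- pairs[1, c_i]
      b <- pairs[2, c_i]
      diff <- means[[b]] - means[[a]]
      se2 <- mse * (1 / ns[[a]] + 1 / ns[[b]])
      F_pair <- diff^2 / (se2 * (k - 1))
      scheffe_rows[[paste(v, a, b)]] <- tibble::tibble(
        variable = v, condition_a = a, condition_b = b,
        diff = diff, F = F_pair,
        p = stats::pf(F_pair, k - 1, df2, lower.tail = FALSE),
        significant = stats::pf(F_pair, k - 1, df2,
                                lower.tail = FALSE) < alpha
      )
    }
  }
  list(anova = dplyr::bind_rows(anova_rows),
       scheffe = dplyr::bind_rows(scheffe_rows))
}

#' Compare the seven behavioral variables between two groups
#'
#' Runs the full comparison the experiment reports: for each behavioral
#' variable, an independent-samples t test (control vs primed), Cohen's d
#' (positive = primed higher), and significance at both the unadjusted and
#' the Bonferroni-adjusted alpha.
#'
#' @param metrics A [player_metrics()] table.
#' @param control,primed Condition labels of the two groups. Any condition
#'   label other than `control` is treated as primed when
#'   `pool_primed = TRUE`.
#' @param pool_primed Pool all non-control conditions into one primed group.
#' @param alpha Family-wise alpha before Bonferroni adjustment.
#' @param welch Use Welch's t test instead of Student's.
#' @param variables Variables to compare.
#' @return A tibble with one row per variable: group means, `t`, `df`,
#'   `p_two_tailed`, `cohens_d`, `alpha_used` (the Bonferroni-adjusted
#'   level), `significant_unadjusted` and `significant_at_alpha`.
#' @export
compare_groups <- function(metrics, control = "control", primed = "primed",
                           pool_primed = TRUE, alpha = 0.05, welch = FALSE,
                           variables = behavioral_variables()) {
  is_control <- metrics$condition == control
  is_primed <- if (pool_primed) !is_control else metrics$condition == primed
  if (sum(is_control) < 2 || sum(is_primed) < 2) {
    stop("each group needs at least two players", call. = FALSE)
  }
  adj <- bonferroni_alpha(alpha, length(variables))
  rows <- lapply(variables, function(v) {
    a <- metrics[[v]][is_control]
    b <- metrics[[v]][is_primed]
    tt <- ttest_independent(a, b, welch = welch)
    tibble::tibble(
      variable = v,
      n_control = length(a), n_primed = length(b),
      mean_control = tt$mean_a, mean_primed = tt$mean_b,
      t = tt$t, df = tt$df, p_two_tailed = tt$p_two_tailed,
      cohens_d = cohens_d(a, b),
      alpha_used = as.numeric(adj),
      significant_unadjusted = tt$p_two_tailed < alpha,
      significant_at_alpha = tt$p_two_tailed < as.numeric(adj)
    )
  })
  dplyr::bind_rows(rows)
}

#' One-command group comparison from a session log
#'
#' Chains [player_metrics()] and [compare_groups()]: the reproduction path
#' from a (simulated or imported) session log to the seven-variable report.
#'
#' @param log A session log with condition labels.
#' @param ... Passed to [compare_groups()].
#' @param include_practice,per_event,accounting Passed to
#'   [player_metrics()].
#' @return See [compare_groups()].
#' @export
reproduce_report <- function(log, include_practice = FALSE,
                             per_event = FALSE, accounting = "net", ...) {
  metrics <- player_metrics(log, include_practice = include_practice,
                            per_event = per_event, accounting = accounting)
  compare_groups(metrics, ...)
}
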