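test_that("pooled t test matches the closed-form toy case", {
  # means 1 vs 2, pooled sd sqrt(2), se sqrt(2)*sqrt(1/2 + 1/2):
  # t = -1/sqrt(2), matching d = 1/sqrt(2) through the pooled identity
  out <- ttest_independent(c(0, 2), c(1, 3))
  expect_equal(out$t, -1 / sqrt(2))
  expect_equal(out$df, 2)
  # identical groups: no difference
  same <- ttest_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_two_tailed, 1)
  # swapping the groups flips t, leaves p unchanged
  swapped <- ttest_independent(c(1, 3), c(0, 2))
  expect_equal(swapped$t, 1 / sqrt(2))
  expect_equal(swapped$p_two_tailed, out$p_two_tailed)
})

test_that("degenerate inputs are flagged, not silently NaN", {
  expect_error(ttest_independent(c(1), c(1, 2)), ">= 2 finite")
  expect_error(ttest_independent(c(1, NA), c(1, 2)), ">= 2 finite")
  expect_error(ttest_independent(c(2, 2), c(3, 3)), "zero variance")
})

test_that("Cohen's d matches hand computation and is translation invariant", {
  expect_equal(cohens_d(c(0, 2), c(1, 3)), 1 / sqrt(2))
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(0, 2) + 10, c(1, 3) + 10), cohens_d(c(0, 2), c(1, 3)))
})

test_that("t and d satisfy the pooled-variance identity", {
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    n1 <- length(a)
    n2 <- length(b)
    d <- cohens_d(a, b)
    t <- ttest_independent(a, b)$t
    expect_equal(t, -d * sqrt(n1 * n2 / (n1 + n2)))
  }
})

test_that("Bonferroni adjustment divides alpha by the number of comparisons", {
  adj <- bonferroni_alpha(0.05, 7)
  expect_equal(as.numeric(adj), 0.05 / 7)
  expect_equal(attr(adj, "reported"), 0.007)
  expect_equal(as.numeric(bonferroni_alpha(0.05, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_alpha(0.10, 5)), 0.02)
})

test_that("two-tailed pooled t test rejects at the nominal rate under the null", {
  set.seed(123)
  n_rep <- 4000
  rejections <- vapply(seq_len(n_rep), function(i) {
    ttest_independent(rnorm(15), rnorm(25))$p_two_tailed < 0.05
  }, logical(1))
  rate <- mean(rejections)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("ANOVA pooling check: identical conditions give F near zero, planted shifts are flagged", {
  set.seed(55)
  metrics <- tibble::tibble(
    player_id = sprintf("p%03d", 1:80),
    condition = rep(c("a", "b", "c", "d"), each = 20),
    repetitive_giving = rnorm(80, mean = 2),
    repetitive_asking = rnorm(80, mean = 2),
    mean_amount_requested = rnorm(80),
    mean_amount_given = rnorm(80),
    n_requests_made = rnorm(80, 5),
    n_requests_answered_positively = rnorm(80, 3),
    matching_abs_diff = rnorm(80, 4)
  )
  # two literally identical conditions: F exactly 0 for that contrast
  dup <- metrics[metrics$condition %in% c("a", "b"), ]
  dup$repetitive_giving[dup$condition == "b"] <-
    dup$repetitive_giving[dup$condition == "a"]
  chk <- condition_pooling_check(dup, variables = "repetitive_giving")
  expect_lt(chk$scheffe$F[1], 1e-20)

  # a planted large shift in one condition is flagged on exactly its contrasts
  shifted <- metrics
  shifted$mean_amount_given[shifted$condition == "d"] <-
    shifted$mean_amount_given[shifted$condition == "d"] + 5
  chk <- condition_pooling_check(shifted, variables = "mean_amount_given")
  sch <- chk$scheffe
  involves_d <- sch$condition_a == "d" | sch$condition_b == "d"
  expect_true(all(sch$significant[involves_d]))
  expect_false(any(sch$significant[!involves_d]))
  expect_lt(chk$anova$p[1], 1e-6)

  # under one common distribution nothing is systematically flagged
  chk_null <- condition_pooling_check(metrics)
  expect_equal(nrow(chk_null$anova), 7)
  expect_warning(
    condition_pooling_check(rbind(metrics,
                                  transform(metrics[1, ], condition = "e"))),
    "n < 2"
  )
})

test_that("Scheffe rejection rate is conservative at the nominal level under the null", {
  set.seed(99)
  n_rep <- 300
  any_flag <- vapply(seq_len(n_rep), function(i) {
    m <- tibble::tibble(
      player_id = as.character(1:60),
      condition = rep(c("a", "b", "c"), each = 20),
      mean_amount_given = rnorm(60)
    )
    chk <- condition_pooling_check(m, variables = "mean_amount_given")
    any(chk$scheffe$significant)
  }, logical(1))
  # family-wise by construction: the any-contrast rate stays at or below ~alpha
  rate <- mean(any_flag)
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("compare_groups reports all seven variables with the adjusted alpha", {
  set.seed(7)
  metrics <- tibble::tibble(
    player_id = sprintf("p%03d", 1:60),
    condition = rep(c("control", "primed"), c(20, 40)),
    repetitive_giving = rnorm(60, mean = rep(c(0, 1), c(20, 40))),
    repetitive_asking = rnorm(60),
    mean_amount_requested = rnorm(60),
    mean_amount_given = rnorm(60, mean = rep(c(0, 1), c(20, 40))),
    n_requests_made = rnorm(60, 5),
    n_requests_answered_positively = rnorm(60, 3),
    matching_abs_diff = rnorm(60, 4)
  )
  rep <- compare_groups(metrics)
  expect_equal(nrow(rep), 7)
  expect_equal(rep$variable, behavioral_variables())
  expect_equal(unique(rep$alpha_used), 0.05 / 7)
  planted <- rep$variable %in% c("repetitive_giving", "mean_amount_given")
  expect_true(all(rep$t[planted] < 0))       # primed higher -> negative t
  expect_true(all(rep$cohens_d[planted] > 0)) # and positive d
  # Welch variant runs and keeps the same signs
  repw <- compare_groups(metrics, welch = TRUE)
  expect_equal(sign(repw$t), sign(rep$t))
})
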