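# Three hand-computed toy logs exercise all seven behavioral variables.

test_that("toy log 1: open debts make asks and gives repetitive", {
  # t1: A asks 6, B gives 5.  t3: A asks 4 (still owing), B gives 4 (unrepaid).
  # t4: A gives 2 back.  t5: B asks 3, A gives nothing.
  log <- two_player_log(
    req_a = c(6, 0, 4, 0, 0), give_a = c(0, 0, 0, 2, 0),
    req_b = c(0, 0, 0, 0, 3), give_b = c(5, 0, 4, 0, 0)
  )
  m <- player_metrics(log)
  a <- m[m$player_id == "A", ]
  b <- m[m$player_id == "B", ]
  expect_equal(a$repetitive_asking, 1)    # t3, 5 units still owed
  expect_equal(a$repetitive_giving, 0)    # t4 give is repayment, not credit
  expect_equal(b$repetitive_giving, 1)    # t3, gave again before repayment
  expect_equal(b$repetitive_asking, 0)    # t5, B holds credit, not debt
  expect_equal(a$mean_amount_requested, 10 / 5)
  expect_equal(a$mean_amount_given, 2 / 5)
  expect_equal(b$mean_amount_given, 9 / 5)
  expect_equal(a$n_requests_made, 2)
  expect_equal(b$n_requests_made, 1)
  expect_equal(b$n_requests_answered_positively, 2) # answered both of A's asks
  expect_equal(a$n_requests_answered_positively, 0) # ignored B's ask
  expect_equal(a$matching_abs_diff, 7)    # |2 - 9|
  expect_equal(b$matching_abs_diff, 7)
  expect_equal(a$periods_survived, 5)
})

test_that("toy log 2: full repayment closes the debt before the next gift", {
  # t1: A gives 3.  t2: B repays 3.  t4: A gives 2 with a clean slate.
  log <- two_player_log(
    req_a = rep(0, 5), give_a = c(3, 0, 0, 2, 0),
    req_b = rep(0, 5), give_b = c(0, 3, 0, 0, 0)
  )
  m <- player_metrics(log)
  a <- m[m$player_id == "A", ]
  expect_equal(a$repetitive_giving, 0)
  expect_equal(a$mean_amount_given, 5 / 5)
  expect_equal(a$matching_abs_diff, 2)
  expect_equal(a$n_requests_made, 0)
  # unprompted gifts are not positive responses to requests
  expect_equal(m$n_requests_answered_positively, c(0, 0))
})

test_that("toy log 3: a no-transfer log is zero on everything but survival", {
  log <- two_player_log(
    req_a = rep(0, 6), give_a = rep(0, 6),
    req_b = rep(0, 6), give_b = rep(0, 6),
    alive_a = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  m <- player_metrics(log)
  vars <- behavioral_variables()
  expect_true(all(as.matrix(m[, vars]) == 0))
  expect_equal(m$periods_survived[m$player_id == "A"], 4)
  expect_equal(m$periods_survived[m$player_id == "B"], 6)
})

test_that("net and gift accounting diverge only on over-repayment", {
  # A gives 5; B over-repays with 7; A then asks.
  log <- two_player_log(
    req_a = c(0, 0, 3, 0), give_a = c(5, 0, 0, 0),
    req_b = rep(0, 4), give_b = c(0, 7, 0, 0)
  )
  net <- player_metrics(log, accounting = "net")
  gift <- player_metrics(log, accounting = "gift")
  # net: the extra 2 units leave A in debt, so the t3 ask is repetitive
  expect_equal(net$repetitive_asking[net$player_id == "A"], 1)
  # gift: over-repayment unties the knot without creating a reverse debt
  expect_equal(gift$repetitive_asking[gift$player_id == "A"], 0)
})

test_that("single-player accessors agree with the table and reject unknown ids", {
  log <- two_player_log(
    req_a = c(6, 0, 4), give_a = c(0, 0, 0),
    req_b = c(0, 0, 0), give_b = c(5, 0, 4)
  )
  expect_equal(compute_repetitive_asking(log, "A"), 1)
  expect_equal(compute_repetitive_giving(log, "B"), 1)
  expect_equal(compute_mean_amounts(log, "A")[["mean_requested"]], 10 / 3)
  expect_equal(compute_request_counts(log, "B")[["n_answered_positively"]], 2)
  expect_equal(compute_matching(log, "A"), 9)
  expect_error(compute_matching(log, "Z"), "unknown player")
})

test_that("per-event means divide by events, not periods", {
  log <- two_player_log(
    req_a = c(6, 0, 4, 0, 0), give_a = rep(0, 5),
    req_b = rep(0, 5), give_b = c(5, 0, 0, 0, 0)
  )
  m <- player_metrics(log, per_event = TRUE)
  expect_equal(m$mean_amount_requested[m$player_id == "A"], 5) # 10 / 2 asks
  expect_equal(m$mean_amount_given[m$player_id == "B"], 5)     # 5 / 1 give
  expect_true(is.na(m$mean_amount_given[m$player_id == "A"]))
})

test_that("naive replay oracle agrees with the ledger implementation on random logs", {
  set.seed(77)
  for (i in 1:200) {
    log <- random_small_log()
    m <- player_metrics(log)
    for (pl in c("A", "B")) {
      oracle <- naive_player_metrics(log, pl)
      row <- m[m$player_id == pl, ]
      for (v in names(oracle)) {
        expect_equal(row[[v]], oracle[[v]],
                     info = sprintf("rep %d player %s metric %s", i, pl, v))
      }
    }
  }
})

test_that("transfer symmetry and count bounds hold on simulated sessions", {
  cfg <- game_config(n_rounds = 2, periods_per_round = 15,
                     practice_periods = 0,
                     regimes_by_round = rep(list(high_volatility_regime()), 2),
                     shock = shock_model("normal", 5))
  pols <- replicate(6, strategy("stochastic", strategy_params(
    ask_propensity = 0.9, give_propensity = 0.8, debt_sensitivity = 0.3
  )), simplify = FALSE)
  log <- run_session(cfg, pols, seed = 13)
  expect_gt(sum(log$given), 0) # the scenario actually exercises transfers
  expect_equal(sum(log$given), sum(log$received))
  m <- player_metrics(log)
  gives_per_player <- log |>
    dplyr::filter(round > 0, given > 0) |>
    dplyr::count(player_id)
  for (pl in gives_per_player$player_id) {
    expect_lte(m$repetitive_giving[m$player_id == pl],
               gives_per_player$n[gives_per_player$player_id == pl])
  }
  expect_true(all(m$repetitive_asking <= m$n_requests_made))
})
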