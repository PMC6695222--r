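high <- high_volatility_regime()

test_that("step_period applies harvest, growth, transfers and shock in order", {
  st <- list(player_state(18), player_state(18))
  ac <- list(list(harvest = 2, request = 0, give = 0),
             list(harvest = 0, request = 0, give = 0))
  out <- step_period(st, ac, high, c(0, 0))
  # 18 - 2 = 16; growth(16) = 1.44; no transfers or shock
  expect_equal(out$records$stock_post[1], 17.44)
  expect_equal(out$states[[1]]$harvested_total, 2)
})

test_that("stock at a critical value with no actions stays put", {
  st <- list(player_state(8), player_state(8))
  zero <- list(harvest = 0, request = 0, give = 0)
  out <- step_period(st, list(zero, zero), high, c(0, 0))
  expect_equal(out$records$stock_post, c(8, 8))
})

test_that("transfers conserve total stock net of growth and shocks", {
  set.seed(4)
  for (i in 1:20) {
    s1 <- runif(1, 10, 24)
    s2 <- runif(1, 14, 24)
    st <- list(player_state(s1), player_state(s2))
    h <- c(runif(1, 0, 2), runif(1, 0, 2))
    gives <- c(0, runif(1, 0, 3))
    sh <- rnorm(2)
    ac <- list(list(harvest = h[1], request = 2, give = gives[1]),
               list(harvest = h[2], request = 0, give = gives[2]))
    out <- step_period(st, ac, high, sh)
    grw <- growth(c(s1, s2) - h, high)
    expect_equal(sum(out$records$stock_post),
                 sum(c(s1, s2) - h + grw + sh))
    expect_equal(out$records$received, rev(out$records$given))
    expect_equal(out$states[[2]]$ledger_balance, gives[2] - gives[1])
  }
})

test_that("illegal actions are rejected naming the offending player", {
  st <- list(player_state(5), player_state(10))
  zero <- list(harvest = 0, request = 0, give = 0)
  expect_error(
    step_period(st, list(list(harvest = 6, request = 0, give = 0), zero),
                high, c(0, 0)),
    "player 1.*harvest"
  )
  expect_error(
    step_period(st, list(zero, list(harvest = 0, request = 0, give = 50)),
                high, c(0, 0)),
    "player 2.*give"
  )
  dead <- player_state(5, alive = FALSE)
  expect_error(
    step_period(list(dead, player_state(10)),
                list(list(harvest = 1, request = 0, give = 0), zero),
                high, c(0, 0)),
    "player 1 is out of the game"
  )
})

test_that("a dead player's stock is frozen through growth and shocks", {
  dead <- player_state(5, alive = FALSE)
  zero <- list(harvest = 0, request = 0, give = 0)
  out <- step_period(list(dead, player_state(18)), list(zero, zero),
                     high, c(3, 3))
  expect_equal(out$records$stock_post[1], 5) # no growth, no shock
  expect_equal(out$records$shock[1], 0)
})

test_that("survival rule requires consecutive below-threshold periods", {
  thr <- 8
  walk <- function(stocks) {
    st <- player_state(stocks[1])
    for (s in stocks) {
      st$stock <- s
      st <- update_survival(st, thr, grace = 3)
    }
    st
  }
  # below, below, at-or-above: counter resets, still alive
  st <- walk(c(5, 5, 8))
  expect_true(st$alive)
  expect_equal(st$consecutive_below, 0)
  # three consecutive below: out of the game
  expect_false(walk(c(5, 5, 5))$alive)
  # two below is tolerated
  expect_true(walk(c(5, 5))$alive)
  # always at or above: alive through twenty periods
  expect_true(walk(rep(10, 20))$alive)
  # death is permanent within the round
  st <- walk(c(5, 5, 5, 20, 20))
  expect_false(st$alive)
})

test_that("run_session bookkeeping: rows, determinism, partner rotation", {
  cfg <- quick_config()
  pols <- list(strategy("need_based"), strategy("none"))
  log <- run_session(cfg, pols, seed = 5)
  expect_equal(nrow(log), 2 * 20)
  expect_identical(log, run_session(cfg, pols, seed = 5))

  cfg4 <- game_config(practice_periods = 0, shock = shock_model(scale = 0))
  pols40 <- replicate(40, strategy("need_based"), simplify = FALSE)
  log40 <- run_session(cfg4, pols40, seed = 9)
  partners <- dplyr::distinct(log40, player_id, round, partner_id) |>
    dplyr::count(player_id)
  expect_true(all(partners$n == 4)) # four distinct partners over four rounds
  expect_error(run_session(cfg, pols[1]), "even number")
})

test_that("practice periods are recorded as round zero and excluded from metrics", {
  cfg <- game_config(n_rounds = 1, periods_per_round = 10,
                     practice_periods = 7,
                     regimes_by_round = list(high_volatility_regime()),
                     shock = shock_model(scale = 0))
  log <- run_session(cfg, list(strategy("need_based"), strategy("none")),
                     seed = 2)
  expect_equal(sum(log$round == 0), 2 * 7)
  m <- player_metrics(log)
  expect_true(all(m$periods_survived <= 10))
})

test_that("earnings follow the show-up plus harvest rule", {
  cfg <- game_config()
  expect_equal(earnings(0, cfg), 5)
  expect_equal(earnings(30, cfg), 7)
  expect_equal(earnings(15, cfg), 6)
  log <- run_session(quick_config(),
                     list(strategy("need_based"), strategy("need_based")),
                     seed = 3)
  e <- session_earnings(log, cfg)
  expect_equal(e$earnings, 5 + e$harvested_total / 15)
})
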