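# Fixture builders and independent oracles shared across the test files.

# Build a valid two-player session log from per-period request/give vectors.
# Stocks are schematic (the metrics never read them beyond validity checks);
# transfer symmetry is enforced by construction.
two_player_log <- function(req_a, give_a, req_b, give_b,
                           alive_a = NULL, alive_b = NULL,
                           round = 1L, condition = c("control", "control")) {
  n <- length(req_a)
  stopifnot(length(give_a) == n, length(req_b) == n, length(give_b) == n)
  if (is.null(alive_a)) alive_a <- rep(TRUE, n)
  if (is.null(alive_b)) alive_b <- rep(TRUE, n)
  row_block <- function(id, pid, cond, req, giv, rec, alive) {
    tibble::tibble(
      round = as.integer(round), period = seq_len(n),
      player_id = id, partner_id = pid, condition = cond,
      regime_label = "high", stock_pre = 15, harvest = 0,
      requested = req, received = rec, given = giv, shock = 0,
      stock_post = 15, alive_post = alive
    )
  }
  dplyr::bind_rows(
    row_block("A", "B", condition[1], req_a, give_a, give_b, alive_a),
    row_block("B", "A", condition[2], req_b, give_b, give_a, alive_b)
  ) |> dplyr::arrange(period, player_id)
}

# Random small two-player log for oracle comparisons: sparse requests and
# gifts that are either repaid in full or not at all.
random_small_log <- function(n_periods = 8) {
  req_a <- sample(c(0, 0, 0, 2, 4), n_periods, replace = TRUE)
  req_b <- sample(c(0, 0, 0, 2, 4), n_periods, replace = TRUE)
  give_a <- ifelse(stats::runif(n_periods) < 0.4,
                   sample(c(1, 2, 3), n_periods, replace = TRUE), 0)
  give_b <- ifelse(stats::runif(n_periods) < 0.4,
                   sample(c(1, 2, 3), n_periods, replace = TRUE), 0)
  two_player_log(req_a, give_a, req_b, give_b)
}

# Independent naive replay oracle for one player's seven metrics: a
# period-by-period walk with explicit FIFO gift queues instead of a net
# ledger. Kept deliberately separate from the package implementation.
naive_player_metrics <- function(log, player) {
  log <- log[log$round > 0, ]
  mine <- log[log$player_id == player, ]
  mine <- mine[order(mine$round, mine$period), ]
  partner_req <- numeric(nrow(mine))
  for (i in seq_len(nrow(mine))) {
    p <- log[log$player_id == mine$partner_id[i] &
               log$round == mine$round[i] & log$period == mine$period[i], ]
    partner_req[i] <- p$requested
  }
  rep_give <- 0
  rep_ask <- 0
  for (r in unique(mine$round)) {
    rows <- mine[mine$round == r, ]
    queue_out <- numeric(0) # my unrepaid gifts to partner
    queue_in <- numeric(0)  # partner's unrepaid gifts to me
    for (i in seq_len(nrow(rows))) {
      if (rows$given[i] > 0 && sum(queue_out) > 1e-9) rep_give <- rep_give + 1
      if (rows$requested[i] > 0 && sum(queue_in) > 1e-9) rep_ask <- rep_ask + 1
      g <- rows$given[i]
      while (g > 1e-9 && length(queue_in) > 0) {
        pay <- min(g, queue_in[1])
        queue_in[1] <- queue_in[1] - pay
        g <- g - pay
        if (queue_in[1] <= 1e-9) queue_in <- queue_in[-1]
      }
      if (g > 1e-9) queue_out <- c(queue_out, g)
      x <- rows$received[i]
      while (x > 1e-9 && length(queue_out) > 0) {
        pay <- min(x, queue_out[1])
        queue_out[1] <- queue_out[1] - pay
        x <- x - pay
        if (queue_out[1] <= 1e-9) queue_out <- queue_out[-1]
      }
      if (x > 1e-9) queue_in <- c(queue_in, x)
    }
  }
  alive_pre <- c(TRUE, utils::head(mine$alive_post, -1))
  # survival resets at round boundaries
  first_of_round <- !duplicated(mine$round)
  alive_pre[first_of_round] <- TRUE
  periods <- sum(alive_pre)
  list(
    repetitive_giving = rep_give,
    repetitive_asking = rep_ask,
    mean_amount_requested = sum(mine$requested) / periods,
    mean_amount_given = sum(mine$given) / periods,
    n_requests_made = sum(mine$requested > 0),
    n_requests_answered_positively = sum(partner_req > 0 & mine$given > 0),
    matching_abs_diff = abs(sum(mine$given) - sum(mine$received)),
    periods_survived = periods
  )
}

# Small, fast game config for engine tests.
quick_config <- function(...) {
  game_config(n_rounds = 1, periods_per_round = 20, practice_periods = 0,
              regimes_by_round = list(high_volatility_regime()),
              shock = shock_model(scale = 0), ...)
}
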