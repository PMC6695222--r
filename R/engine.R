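#' Player state
#'
#' The per-player bookkeeping carried through a round: current stock, whether
#' the player is still in the game, how many consecutive periods the stock
#' has been below the survival threshold, total resources harvested (the
#' basis for earnings), and the net transfer ledger with the current partner
#' (positive = this player has given more than received).
#'
#' @param stock Current resource stock (non-negative).
#' @param alive Whether the player is still in the game.
#' @param consecutive_below Consecutive periods below the survival threshold.
#' @param harvested_total Cumulative harvested resources.
#' @param ledger_balance Net given minus received with the current partner.
#' @return An object of class `player_state`.
#' @export
player_state <- function(stock, alive = TRUE, consecutive_below = 0,
                         harvested_total = 0, ledger_balance = 0) {
  stopifnot(is.numeric(stock), is.finite(stock), stock >= 0)
  structure(
    list(stock = stock, alive = alive,
         consecutive_below = consecutive_below,
         harvested_total = harvested_total,
         ledger_balance = ledger_balance),
    class = "player_state"
  )
}

#' Advance one pair of players by one period
#'
#' Applies the per-period update for a pair: each player's stock changes by
#' the amount harvested, a natural growth increment, transfers received and
#' given, and a random shock. The ordered update per player is
#' `s' = s - harvest`, `s'' = s' + growth(s', regime)`,
#' `s''' = s'' + received - given + shock`, floored at zero. Growth acts on
#' the post-harvest stock; transfers and the shock are applied after growth,
#' so a player's capacity to give is their post-growth stock. A player who is
#' out of the game is frozen: no harvest, growth, transfers or shock.
#'
#' @param states List of two [player_state()] objects.
#' @param actions List of two lists, each with `harvest`, `request`, `give`
#'   (non-negative resource units). A dead player's actions must be all zero.
#' @param regime A [volatility_regime()].
#' @param shocks Numeric vector of two shock draws (see [draw_shocks()]).
#' @param integer_stocks Round post-update stocks to integers.
#' @return A list with `states` (updated pair) and `records`: a list of
#'   per-player vectors `stock_pre`, `harvest`, `requested`, `received`,
#'   `given`, `shock`, `stock_post`.
#' @examples
#' st <- list(player_state(18), player_state(18))
#' ac <- list(list(harvest = 2, request = 0, give = 0),
#'            list(harvest = 0, request = 0, give = 0))
#' step_period(st, ac, high_volatility_regime(), c(0, 0))$records$stock_post
#' @export
step_period <- function(states, actions, regime, shocks,
                        integer_stocks = FALSE) {
  stopifnot(length(states) == 2, length(actions) == 2, length(shocks) == 2)
  eps <- 1e-9
  for (k in 1:2) {
    a <- actions[[k]]
    if (any(!is.finite(c(a$harvest, a$request, a$give))) ||
        a$harvest < 0 || a$request < 0 || a$give < 0) {
      stop(sprintf("player %d: actions must be finite and non-negative", k),
           call. = FALSE)
    }
    if (!states[[k]]$alive && (a$harvest > 0 || a$request > 0 || a$give > 0)) {
      stop(sprintf("player %d is out of the game and cannot act", k),
           call. = FALSE)
    }
    if (a$harvest > states[[k]]$stock + eps) {
      stop(sprintf("player %d: harvest %g exceeds stock %g",
                   k, a$harvest, states[[k]]$stock), call. = FALSE)
    }
  }

  stock_pre <- vapply(states, `[[`, numeric(1), "stock")
  alive <- vapply(states, `[[`, logical(1), "alive")
  harvest <- vapply(actions, `[[`, numeric(1), "harvest")
  request <- vapply(actions, `[[`, numeric(1), "request")
  give <- vapply(actions, `[[`, numeric(1), "give")

  post_harvest <- stock_pre - harvest
  avail <- ifelse(alive, post_harvest + growth(post_harvest, regime),
                  stock_pre)
  for (k in 1:2) {
    if (give[k] > avail[k] + eps) {
      stop(sprintf("player %d: give %g exceeds available stock %g",
                   k, give[k], avail[k]), call. = FALSE)
    }
  }

  shocks <- ifelse(alive, shocks, 0)
  received <- rev(give)
  stock_post <- pmax(avail + received - give + shocks, 0)
  if (integer_stocks) stock_post <- round(stock_post)
  stock_post <- ifelse(alive, stock_post, stock_pre)

  for (k in 1:2) {
    states[[k]]$stock <- stock_post[k]
    states[[k]]$harvested_total <- states[[k]]$harvested_total + harvest[k]
    states[[k]]$ledger_balance <- states[[k]]$ledger_balance +
      give[k] - received[k]
  }

  list(
    states = states,
    records = list(
      stock_pre = stock_pre, harvest = harvest, requested = request,
      received = received, given = give, shock = shocks,
      stock_post = stock_post
    )
  )
}

#' Apply the survival (death) rule
#'
#' After each period update, a player's consecutive-below counter increments
#' when the post-update stock is below the threshold and resets to zero
#' otherwise. Once the counter reaches `grace` consecutive periods the player
#' is out of the game for the rest of the round: unable to harvest, request,
#' or respond to requests. The flag never flips back within a round.
#'
#' @param state A [player_state()].
#' @param threshold Survival threshold (resource units).
#' @param grace Consecutive below-threshold periods tolerated (default 3).
#' @return The updated [player_state()].
#' @export
update_survival <- function(state, threshold, grace = 3) {
  if (!state$alive) return(state)
  if (state$stock < threshold) {
    state$consecutive_below <- state$consecutive_below + 1
    if (state$consecutive_below >= grace) state$alive <- FALSE
  } else {
    state$consecutive_below <- 0
  }
  state
}

#' Dollar earnings for a player
#'
#' Players earn the show-up fee plus one dollar for every
#' `units_per_dollar` resource units harvested. Fractional dollars are
#' retained; rounding is left to reporting.
#'
#' @param harvested_total Total resources harvested, or a [player_state()].
#' @param config A [game_config()].
#' @return Earnings in dollars.
#' @examples
#' earnings(30, game_config())  # $7
#' @export
earnings <- function(harvested_total, config = game_config()) {
  if (inherits(harvested_total, "player_state")) {
    harvested_total <- harvested_total$harvested_total
  }
  stopifnot(is.numeric(harvested_total), all(harvested_total >= 0))
  config$show_up_fee + harvested_total / config$units_per_dollar
}

# Round-robin partner schedule (circle method) over a fixed ordering of
# player indices: player 1 stays put, the rest rotate, so every player faces
# a distinct partner in each of the first n-1 rounds.
partner_schedule <- function(order, round) {
  n <- length(order)
  others <- order[-1]
  k <- (round - 1L) %% (n - 1L)
  rotated <- c(utils::tail(others, k), utils::head(others, n - 1L - k))
  arr <- c(order[1], rotated)
  cbind(arr[seq_len(n / 2)], rev(arr[(n / 2 + 1):n]))
}

#' Run a full session of the risk pooling game
#'
#' Simulates a seven-period practice block followed by the scored rounds for
#' an even number of players. At the start of every round all stocks reset to
#' the same initial value, transfer ledgers clear, players re-enter the game,
#' and partners are reassigned (a round-robin rotation over a randomly
#' shuffled ordering, so no pair meets twice while rounds remain). Within a
#' period each player first chooses a harvest and whether to request help
#' (observing pre-harvest stocks), then responds to the partner's request
#' out of post-growth stock; transfers and a random shock close the period,
#' followed by the survival rule.
#'
#' Earnings accrue from harvests in scored rounds only; practice play
#' (recorded with `round = 0`) is excluded from behavioral metrics by
#' default.
#'
#' @param config A [game_config()].
#' @param policies A list of [strategy()] objects, one per player (even
#'   count). Names, if present, become player ids.
#' @param conditions Optional character vector of condition labels per player
#'   (e.g. `"control"`, `"primed"`); recycled if length 1.
#' @param seed Optional integer seed; identical seeds, config and policies
#'   give identical logs.
#' @param session Session identifier used to disambiguate player ids when
#'   concatenating logs (prefixing ids as `s<session>_<id>`). `NULL` leaves
#'   ids untouched.
#' @return A tibble session log, one row per player-period, with columns
#'   `round` (0 = practice), `period`, `player_id`, `partner_id`,
#'   `condition`, `regime_label`, `stock_pre`, `harvest`, `requested`,
#'   `received`, `given`, `shock`, `stock_post`, `alive_post`.
#' @examples
#' cfg <- game_config(n_rounds = 1, periods_per_round = 5,
#'                    practice_periods = 0, shock = shock_model(scale = 0))
#' log <- run_session(cfg, list(strategy("need_based"), strategy("none")),
#'                    seed = 1)
#' @export
run_session <- function(config, policies, conditions = NULL, seed = NULL,
                        session = NULL) {
  stopifnot(inherits(config, "game_config"))
  n <- length(policies)
  if (n < 2 || n %% 2 != 0) {
    stop("`policies` must list an even number (>= 2) of players",
         call. = FALSE)
  }
  stopifnot(all(vapply(policies, inherits, logical(1), "strategy")))
  if (is.null(conditions)) conditions <- "unlabeled"
  conditions <- rep_len(as.character(conditions), n)
  ids <- names(policies)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(n))
  if (!is.null(session)) ids <- sprintf("s%s_%s", session, ids)
  if (anyDuplicated(ids)) stop("player ids must be unique", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  order <- sample.int(n)
  rounds <- if (config$practice_periods > 0) 0:config$n_rounds else
    seq_len(config$n_rounds)
  n_rows <- n * (config$practice_periods +
                   config$n_rounds * config$periods_per_round)

  col <- function(x) vector(mode = x, length = n_rows)
  out <- list(
    round = col("integer"), period = col("integer"),
    player_id = col("character"), partner_id = col("character"),
    condition = col("character"), regime_label = col("character"),
    stock_pre = col("numeric"), harvest = col("numeric"),
    requested = col("numeric"), received = col("numeric"),
    given = col("numeric"), shock = col("numeric"),
    stock_post = col("numeric"), alive_post = col("logical")
  )
  row <- 0L

  for (r in rounds) {
    practice <- r == 0L
    regime <- if (practice) config$practice_regime else
      config$regimes_by_round[[r]]
    threshold <- active_death_threshold(config, regime)
    n_periods <- if (practice) config$practice_periods else
      config$periods_per_round
    pairs <- partner_schedule(order, max(r, 1L))
    states <- lapply(seq_len(n), function(i) player_state(config$initial_stock))

    for (p in seq_len(n_periods)) {
      for (pr in seq_len(nrow(pairs))) {
        i <- pairs[pr, 1]
        j <- pairs[pr, 2]
        pair_states <- states[c(i, j)]
        alive <- vapply(pair_states, `[[`, logical(1), "alive")
        stocks <- vapply(pair_states, `[[`, numeric(1), "stock")
        balances <- vapply(pair_states, `[[`, numeric(1), "ledger_balance")
        zero <- list(harvest = 0, request = 0, give = 0)

        # Phase 1: harvest + request, observing pre-harvest stocks.
        phase1 <- lapply(1:2, function(k) {
          if (!alive[k]) return(zero)
          pol <- policies[[c(i, j)[k]]]
          a <- pol$decide(observation(
            stock = stocks[k], regime = regime,
            partner_stock = stocks[3 - k], balance = balances[k]
          ))
          a$harvest <- min(max(a$harvest, 0), stocks[k])
          a$request <- max(a$request, 0)
          a
        })

        # Phase 2: respond to the partner's request out of post-growth stock.
        post <- stocks - vapply(phase1, `[[`, numeric(1), "harvest")
        avail <- ifelse(alive, post + growth(post, regime), stocks)
        gives <- vapply(1:2, function(k) {
          if (!alive[k]) return(0)
          pol <- policies[[c(i, j)[k]]]
          g <- pol$decide(observation(
            stock = avail[k], regime = regime, partner_stock = avail[3 - k],
            balance = balances[k], requested = phase1[[3 - k]]$request
          ))$give
          min(max(g, 0), avail[k])
        }, numeric(1))

        actions <- lapply(1:2, function(k) {
          list(harvest = phase1[[k]]$harvest, request = phase1[[k]]$request,
               give = gives[k])
        })
        shocks <- ifelse(alive, draw_shocks(config$shock, 2), 0)
        stepped <- step_period(pair_states, actions, regime, shocks,
                               integer_stocks = config$integer_stocks)
        states[c(i, j)] <- lapply(stepped$states, update_survival,
                                  threshold = threshold,
                                  grace = config$death_grace)
        rows <- row + 1:2
        out$round[rows] <- r
        out$period[rows] <- p
        out$player_id[rows] <- ids[c(i, j)]
        out$partner_id[rows] <- ids[c(j, i)]
        out$condition[rows] <- conditions[c(i, j)]
        out$regime_label[rows] <- regime$label
        out$stock_pre[rows] <- stepped$records$stock_pre
        out$harvest[rows] <- stepped$records$harvest
        out$requested[rows] <- stepped$records$requested
        out$received[rows] <- stepped$records$received
        out$given[rows] <- stepped$records$given
        out$shock[rows] <- stepped$records$shock
        out$stock_post[rows] <- stepped$records$stock_post
        out$alive_post[rows] <- vapply(states[c(i, j)], `[[`, logical(1),
                                       "alive")
        row <- row + 2L
      }
    }
  }

  tibble::as_tibble(out)
}

#' Per-player earnings from a session log
#'
#' Sums harvests over the scored rounds of a session log and applies the
#' earnings rule.
#'
#' @param log A session log from [run_session()].
#' @param config A [game_config()].
#' @return A tibble with `player_id`, `harvested_total`, `earnings`.
#' @export
session_earnings <- function(log, config = game_config()) {
  log |>
    dplyr::filter(.data$round > 0) |>
    dplyr::group_by(.data$player_id) |>
    dplyr::summarise(harvested_total = sum(.data$harvest), .groups = "drop") |>
    dplyr::mutate(earnings = earnings(.data$harvested_total, config))
}
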