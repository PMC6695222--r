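#' Game configuration
#'
#' Bundles the structural parameters of a session of the risk pooling game:
#' the round/period structure, the volatility regime schedule, the survival
#' (death) rule, starting stocks and the earnings rule.
#'
#' Defaults mirror the laboratory design: a seven-period practice session
#' followed by four rounds of twenty periods, half under high and half under
#' low volatility; players drop out after three consecutive periods with
#' stock below the survival threshold; $5 show-up fee plus $1 per 15 units
#' harvested.
#'
#' The survival threshold is taken per round from the active regime's lower
#' critical value `L` unless `death_threshold` is given, since `L` is the
#' boundary below which stocks start shrinking. Starting stock defaults to 15
#' units, inside the growth-positive band of both regimes.
#'
#' @param n_rounds Number of scored rounds.
#' @param periods_per_round Periods per round.
#' @param practice_periods Practice periods played before round 1 (recorded
#'   with `round = 0`, excluded from metrics by default).
#' @param regimes_by_round List of [volatility_regime()] of length `n_rounds`.
#'   The default alternates high and low volatility; pass the reversed order
#'   to counterbalance.
#' @param practice_regime Regime for the practice block.
#' @param death_threshold Survival threshold in resource units, or `NULL` to
#'   use each round's regime `lower` value.
#' @param death_grace Consecutive below-threshold periods tolerated before a
#'   player is out of the round.
#' @param initial_stock Stock every player starts each round with.
#' @param units_per_dollar Harvested units per dollar of earnings.
#' @param show_up_fee Dollars earned for participating.
#' @param shock A [shock_model()].
#' @param integer_stocks If `TRUE`, stocks are rounded to integers after each
#'   period update.
#' @return An object of class `game_config`.
#' @export
game_config <- function(n_rounds = 4,
                        periods_per_round = 20,
                        practice_periods = 7,
                        regimes_by_round = NULL,
                        practice_regime = low_volatility_regime(),
                        death_threshold = NULL,
                        death_grace = 3,
                        initial_stock = 15,
                        units_per_dollar = 15,
                        show_up_fee = 5,
                        shock = shock_model("normal", 2),
                        integer_stocks = FALSE) {
  if (is.null(regimes_by_round)) {
    regimes_by_round <- rep(
      list(high_volatility_regime(), low_volatility_regime()),
      length.out = n_rounds
    )
  }
  stopifnot(
    n_rounds >= 1, periods_per_round >= 1, practice_periods >= 0,
    death_grace >= 1, initial_stock > 0, units_per_dollar > 0,
    inherits(shock, "shock_model"),
    length(regimes_by_round) == n_rounds,
    all(vapply(regimes_by_round, inherits, logical(1), "volatility_regime"))
  )
  if (!is.null(death_threshold)) {
    stopifnot(is.numeric(death_threshold), death_threshold >= 0)
    if (initial_stock <= death_threshold) {
      stop("`initial_stock` must exceed `death_threshold`", call. = FALSE)
    }
  }
  structure(
    list(
      n_rounds = n_rounds,
      periods_per_round = periods_per_round,
      practice_periods = practice_periods,
      regimes_by_round = regimes_by_round,
      practice_regime = practice_regime,
      death_threshold = death_threshold,
      death_grace = death_grace,
      initial_stock = initial_stock,
      units_per_dollar = units_per_dollar,
      show_up_fee = show_up_fee,
      shock = shock,
      integer_stocks = integer_stocks
    ),
    class = "game_config"
  )
}

#' @export
print.game_config <- function(x, ...) {
  labs <- vapply(x$regimes_by_round, `[[`, character(1), "label")
  cat(sprintf(
    paste0(
      "<game_config> %d rounds x %d periods (+%d practice)\n",
      "  regimes: %s | shock: %s(scale = %g)\n",
      "  death: %s for %d consecutive periods | start stock: %g\n",
      "  earnings: $%g + $1 per %g units harvested\n"
    ),
    x$n_rounds, x$periods_per_round, x$practice_periods,
    paste(labs, collapse = ", "),
    x$shock$distribution, x$shock$scale,
    if (is.null(x$death_threshold)) "stock < regime L" else
      sprintf("stock < %g", x$death_threshold),
    x$death_grace, x$initial_stock, x$show_up_fee, x$units_per_dollar
  ))
  invisible(x)
}

# Survival threshold in force for a given regime.
active_death_threshold <- function(config, regime) {
  if (is.null(config$death_threshold)) regime$lower else config$death_threshold
}

#' Read and write game configurations as YAML
#'
#' Serialises a [game_config()] to a structured text file and back, so that
#' simulation runs are reproducible from a config file plus a seed.
#'
#' @param config A [game_config()].
#' @param path File path.
#' @return `write_game_config()` returns `path` invisibly;
#'   `read_game_config()` returns a [game_config()].
#' @export
write_game_config <- function(config, path) {
  stopifnot(inherits(config, "game_config"))
  x <- list(
    n_rounds = config$n_rounds,
    periods_per_round = config$periods_per_round,
    practice_periods = config$practice_periods,
    regimes_by_round = lapply(config$regimes_by_round, unclass),
    practice_regime = unclass(config$practice_regime),
    death_threshold = config$death_threshold,
    death_grace = config$death_grace,
    initial_stock = config$initial_stock,
    units_per_dollar = config$units_per_dollar,
    show_up_fee = config$show_up_fee,
    shock = unclass(config$shock),
    integer_stocks = config$integer_stocks
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_game_config
#' @export
read_game_config <- function(path) {
  x <- yaml::read_yaml(path)
  regime_of <- function(r) volatility_regime(r$rate, r$lower, r$upper, r$label)
  game_config(
    n_rounds = x$n_rounds,
    periods_per_round = x$periods_per_round,
    practice_periods = x$practice_periods,
    regimes_by_round = lapply(x$regimes_by_round, regime_of),
    practice_regime = regime_of(x$practice_regime),
    death_threshold = x$death_threshold,
    death_grace = x$death_grace,
    initial_stock = x$initial_stock,
    units_per_dollar = x$units_per_dollar,
    show_up_fee = x$show_up_fee,
    shock = shock_model(x$shock$distribution, x$shock$scale),
    integer_stocks = isTRUE(x$integer_stocks)
  )
}
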