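#' @importFrom rlang .data
NULL

# Annotate a session log with the per-row context the metrics need: the
# partner's request in the same period, the player's transfer balance with
# the current partner carried into the period, and whether the player was
# still in the game at the period start.
annotate_log <- function(log, include_practice = FALSE) {
  validate_session_log(log)
  if (!include_practice) log <- dplyr::filter(log, .data$round > 0)
  partner <- dplyr::select(log, "round", "period",
                           partner_id = "player_id",
                           partner_requested = "requested")
  log |>
    dplyr::left_join(partner, by = c("round", "period", "partner_id")) |>
    dplyr::group_by(.data$player_id, .data$round) |>
    dplyr::arrange(.data$period, .by_group = TRUE) |>
    dplyr::mutate(
      balance_before = dplyr::lag(cumsum(.data$given - .data$received),
                                  default = 0),
      alive_pre = dplyr::lag(.data$alive_post, default = TRUE)
    ) |>
    dplyr::ungroup()
}

# Gift-by-gift ledger walk for one player-round: outstanding credit (what the
# partner still owes this player) and outstanding debt (what this player
# still owes), where a transfer repays the giver's open debt first and any
# over-repayment "unties the knot" without creating a reverse debt. Returns
# the pre-period open-credit/open-debt flags.
gift_ledger_flags <- function(given, received) {
  credit <- 0 # partner owes me
  debt <- 0   # I owe partner
  n <- length(given)
  open_credit <- logical(n)
  open_debt <- logical(n)
  tol <- 1e-9
  for (t in seq_len(n)) {
    open_credit[t] <- credit > tol
    open_debt[t] <- debt > tol
    if (given[t] > 0) {
      if (debt > tol) debt <- max(debt - given[t], 0) else
        credit <- credit + given[t]
    }
    if (received[t] > 0) {
      if (credit > tol) credit <- max(credit - received[t], 0) else
        debt <- debt + received[t]
    }
  }
  list(open_credit = open_credit, open_debt = open_debt)
}

#' Seven behavioral variables per player
#'
#' Computes, for every player in a session log, the behavioral variables
#' used to distinguish need-based from debt-based (account-keeping) play:
#'
#' * `repetitive_giving` — periods in which the player gave although the
#'   partner had not yet repaid a previous gift;
#' * `repetitive_asking` — periods in which the player asked although their
#'   own previous gift received was not yet repaid;
#' * `mean_amount_requested`, `mean_amount_given` — amounts averaged over
#'   all periods of play (zeros included), or over request/give events when
#'   `per_event = TRUE`;
#' * `n_requests_made` — periods with a positive request;
#' * `n_requests_answered_positively` — times the player, when asked, gave
#'   something;
#' * `matching_abs_diff` — absolute difference between total given and total
#'   received (small values = tit-for-tat matching);
#'
#' plus `periods_survived`, the number of periods the player was in the
#' game.
#'
#' "Not yet repaid" is judged on the transfer ledger with the current
#' partner at the period start. Under `accounting = "net"` (default) a debt
#' is open while the net balance (given minus received within the pairing)
#' is positive in the relevant direction; exact zero counts as repaid. Under
#' `accounting = "gift"` each transfer first repays the giver's own open
#' debt and over-repayment closes the debt without creating a reverse one.
#' The two conventions agree whenever gifts are repaid in full or not at
#' all.
#'
#' @param log A session log from [run_session()] / [generate_experiment()].
#' @param include_practice Include practice periods (`round = 0`)?
#' @param per_event Average amounts over request/give events instead of
#'   periods of play (events absent gives `NA`).
#' @param accounting `"net"` or `"gift"` debt bookkeeping (see Details).
#' @return A tibble with one row per player: `player_id`, `condition`, the
#'   seven variables above and `periods_survived`.
#' @export
player_metrics <- function(log, include_practice = FALSE, per_event = FALSE,
                           accounting = c("net", "gift")) {
  accounting <- match.arg(accounting)
  ann <- annotate_log(log, include_practice)
  if (nrow(ann) == 0) stop("log has no scored periods", call. = FALSE)
  tol <- 1e-9

  if (accounting == "net") {
    ann <- dplyr::mutate(ann,
      open_credit = .data$balance_before > tol,
      open_debt = .data$balance_before < -tol
    )
  } else {
    ann <- ann |>
      dplyr::group_by(.data$player_id, .data$round) |>
      dplyr::arrange(.data$period, .by_group = TRUE) |>
      dplyr::mutate(
        open_credit = gift_ledger_flags(.data$given,
                                        .data$received)$open_credit,
        open_debt = gift_ledger_flags(.data$given,
                                      .data$received)$open_debt
      ) |>
      dplyr::ungroup()
  }

  res <- ann |>
    dplyr::group_by(.data$player_id, .data$condition) |>
    dplyr::summarise(
      repetitive_giving = sum(.data$given > tol & .data$open_credit),
      repetitive_asking = sum(.data$requested > tol & .data$open_debt),
      total_requested = sum(.data$requested),
      total_given = sum(.data$given),
      total_received = sum(.data$received),
      n_requests_made = sum(.data$requested > tol),
      n_gives = sum(.data$given > tol),
      n_requests_answered_positively =
        sum(.data$partner_requested > tol & .data$given > tol),
      periods_survived = sum(.data$alive_pre),
      .groups = "drop"
    )
  if (any(res$periods_survived == 0)) {
    stop("player with zero periods of play: means undefined", call. = FALSE)
  }
  denom_req <- if (per_event) res$n_requests_made else res$periods_survived
  denom_giv <- if (per_event) res$n_gives else res$periods_survived
  res |>
    dplyr::mutate(
      mean_amount_requested = ifelse(denom_req > 0,
                                     .data$total_requested / denom_req,
                                     if (per_event) NA_real_ else 0),
      mean_amount_given = ifelse(denom_giv > 0,
                                 .data$total_given / denom_giv,
                                 if (per_event) NA_real_ else 0),
      matching_abs_diff = abs(.data$total_given - .data$total_received)
    ) |>
    dplyr::select(
      "player_id", "condition", "repetitive_giving", "repetitive_asking",
      "mean_amount_requested", "mean_amount_given", "n_requests_made",
      "n_requests_answered_positively", "matching_abs_diff",
      "periods_survived"
    )
}

#' The seven behavioral variable names
#'
#' Column names of the behavioral variables in [player_metrics()] output, in
#' reporting order.
#' @return Character vector of length 7.
#' @export
behavioral_variables <- function() {
  c("repetitive_asking", "repetitive_giving",
    "mean_amount_requested", "mean_amount_given",
    "n_requests_made", "n_requests_answered_positively",
    "matching_abs_diff")
}

metric_for_player <- function(log, player, column, ...) {
  m <- player_metrics(log, ...)
  if (!player %in% m$player_id) {
    stop(sprintf("unknown player id '%s'", player), call. = FALSE)
  }
  m[[column]][m$player_id == player]
}

#' Single-player metric accessors
#'
#' Convenience accessors for one player's behavioral variables; see
#' [player_metrics()] for definitions.
#'
#' @param log A session log.
#' @param player A player id present in the log.
#' @param ... Passed on to [player_metrics()].
#' @return A scalar (or, for [compute_mean_amounts()] and
#'   [compute_request_counts()], a named numeric vector of length 2).
#' @export
compute_repetitive_giving <- function(log, player, ...) {
  metric_for_player(log, player, "repetitive_giving", ...)
}

#' @rdname compute_repetitive_giving
#' @export
compute_repetitive_asking <- function(log, player, ...) {
  metric_for_player(log, player, "repetitive_asking", ...)
}

#' @rdname compute_repetitive_giving
#' @export
compute_mean_amounts <- function(log, player, ...) {
  c(mean_requested = metric_for_player(log, player, "mean_amount_requested",
                                       ...),
    mean_given = metric_for_player(log, player, "mean_amount_given", ...))
}

#' @rdname compute_repetitive_giving
#' @export
compute_request_counts <- function(log, player, ...) {
  c(n_made = metric_for_player(log, player, "n_requests_made", ...),
    n_answered_positively =
      metric_for_player(log, player, "n_requests_answered_positively", ...))
}

#' @rdname compute_repetitive_giving
#' @export
compute_matching <- function(log, player, ...) {
  metric_for_player(log, player, "matching_abs_diff", ...)
}
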