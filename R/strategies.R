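#' Strategy parameters
#'
#' Parameters shared by the transfer policies. `need_threshold` triggers a
#' request; `safe_level` is both the target stock a requester tops up to and
#' the floor below which a donor will not give. The three propensities govern
#' the stochastic human-like policy: `ask_propensity` is the chance a needed
#' request is actually made, `give_propensity` the chance of answering a
#' request positively, and `debt_sensitivity` the chance that an open debt
#' (an unrepaid net balance with the current partner) suppresses an ask or a
#' give — the account-keeping knob that separates debt-based from need-based
#' play.
#'
#' @param need_threshold Stock below which a player asks for help (resource
#'   units; must not exceed `safe_level`).
#' @param safe_level Target stock after help; donor floor (resource units).
#' @param ask_propensity,give_propensity,debt_sensitivity Probabilities in
#'   `[0, 1]`.
#' @return An object of class `strategy_params`.
#' @export
strategy_params <- function(need_threshold = 8,
                            safe_level = 12,
                            ask_propensity = 1,
                            give_propensity = 1,
                            debt_sensitivity = 0) {
  probs <- c(ask_propensity, give_propensity, debt_sensitivity)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("propensities must lie in [0, 1]", call. = FALSE)
  }
  if (need_threshold > safe_level) {
    stop("`need_threshold` must not exceed `safe_level`", call. = FALSE)
  }
  structure(
    list(
      need_threshold = need_threshold, safe_level = safe_level,
      ask_propensity = ask_propensity, give_propensity = give_propensity,
      debt_sensitivity = debt_sensitivity
    ),
    class = "strategy_params"
  )
}

#' Build an observation for a policy
#'
#' The information a player can act on in one period: their own stock, the
#' partner's stock (holdings are mutually visible, as livestock are among
#' pastoralists), the net transfer balance with the current partner
#' (positive = the partner owes this player), the partner's pending request,
#' and the active volatility regime.
#'
#' @param stock Own resource stock at the moment of the decision.
#' @param regime A [volatility_regime()].
#' @param partner_stock Partner's stock (informational).
#' @param balance Net amount given minus received with the current partner.
#' @param requested Partner's pending request this period (for give decisions).
#' @return A list of class `observation`.
#' @export
observation <- function(stock, regime, partner_stock = NA_real_,
                        balance = 0, requested = 0) {
  structure(
    list(stock = stock, regime = regime, partner_stock = partner_stock,
         balance = balance, requested = requested),
    class = "observation"
  )
}

# Shared harvest rule: skim stock above the regime's growth optimum so that
# post-harvest stock sits where growth is fastest. Shared across policies so
# that survival differences isolate the transfer rules.
harvest_rule <- function(obs) {
  max(0, obs$stock - growth_optimum(obs$regime))
}

#' Need-based (osotua-style) transfer policy
#'
#' Requests only out of genuine need — when stock falls below
#' `need_threshold` — and only the amount needed to return to `safe_level`.
#' Answers requests with whatever can be spared above `safe_level`. Keeps no
#' accounts: the transfer balance never affects a decision, and gifts create
#' no debt.
#'
#' @param obs An [observation()].
#' @param params A [strategy_params()].
#' @return A list with components `harvest`, `request` and `give`
#'   (resource units, all non-negative).
#' @examples
#' p <- strategy_params(need_threshold = 8, safe_level = 12)
#' need_based_policy(observation(6, high_volatility_regime()), p)$request  # 6
#' @export
need_based_policy <- function(obs, params = strategy_params()) {
  request <- if (obs$stock < params$need_threshold) {
    max(0, params$safe_level - obs$stock)
  } else 0
  give <- min(obs$requested, max(0, obs$stock - params$safe_level))
  list(harvest = harvest_rule(obs), request = request, give = give)
}

#' Debt-based (esile-style) transfer policy
#'
#' Like [need_based_policy()] but account-keeping: a gift creates a debt that
#' is expected to be repaid before further credit. The policy refuses to give
#' while the asker has an unrepaid balance, does not ask while its own debt
#' to the partner is outstanding, and when holding a debt and a surplus it
#' repays `min(debt, surplus)` unprompted.
#'
#' @inheritParams need_based_policy
#' @return A list with `harvest`, `request` and `give`.
#' @export
debt_based_policy <- function(obs, params = strategy_params()) {
  in_need <- obs$stock < params$need_threshold
  own_debt_open <- obs$balance < 0
  request <- if (in_need && !own_debt_open) {
    max(0, params$safe_level - obs$stock)
  } else 0
  surplus <- max(0, obs$stock - params$safe_level)
  response <- if (obs$balance > 0) 0 else min(obs$requested, surplus)
  repayment <- if (own_debt_open) min(-obs$balance, surplus - response) else 0
  list(harvest = harvest_rule(obs), request = request,
       give = response + repayment)
}

#' No-transfer policy
#'
#' Never requests and never gives; harvests like the other policies.
#'
#' @inheritParams need_based_policy
#' @return A list with `harvest`, `request = 0` and `give = 0`.
#' @export
no_transfer_policy <- function(obs, params = strategy_params()) {
  list(harvest = harvest_rule(obs), request = 0, give = 0)
}

#' Stochastic human-like policy
#'
#' A noisy blend of the need-based and debt-based rules used to emulate
#' human participants. Requests triggered by need are emitted with
#' probability `ask_propensity` and suppressed with probability
#' `debt_sensitivity` when the player's own debt to the partner is open;
#' positive responses to a request occur with probability `give_propensity`
#' and are suppressed with probability `debt_sensitivity` when the asker's
#' debt is open. With `ask_propensity = give_propensity = 1` and
#' `debt_sensitivity = 0` it reduces exactly to [need_based_policy()]; with
#' `debt_sensitivity = 1` it never re-asks or re-gives across an open debt,
#' so both repetitive-asking and repetitive-giving are zero by construction.
#'
#' Draws use R's global RNG; seed the session for reproducibility.
#'
#' @inheritParams need_based_policy
#' @return A list with `harvest`, `request` and `give`.
#' @export
stochastic_human_policy <- function(obs, params = strategy_params()) {
  base <- need_based_policy(obs, params)
  request <- base$request
  if (request > 0) {
    p_ask <- params$ask_propensity *
      (if (obs$balance < 0) 1 - params$debt_sensitivity else 1)
    if (stats::runif(1) >= p_ask) request <- 0
  }
  give <- base$give
  if (give > 0) {
    p_give <- params$give_propensity *
      (if (obs$balance > 0) 1 - params$debt_sensitivity else 1)
    if (stats::runif(1) >= p_give) give <- 0
  }
  list(harvest = base$harvest, request = request, give = give)
}

#' Construct a named strategy
#'
#' Policies are named plugins selectable per player:
#' `"need_based"`, `"debt_based"`, `"none"` or `"stochastic"`.
#'
#' @param type Policy name.
#' @param params A [strategy_params()].
#' @return An object of class `strategy`: a list with `type`, `params` and
#'   the policy function `decide(obs)`.
#' @examples
#' s <- strategy("need_based")
#' s$decide(observation(6, high_volatility_regime()))
#' @export
strategy <- function(type = c("need_based", "debt_based", "none", "stochastic"),
                     params = strategy_params()) {
  type <- match.arg(type)
  stopifnot(inherits(params, "strategy_params"))
  fn <- switch(type,
    need_based = need_based_policy,
    debt_based = debt_based_policy,
    none = no_transfer_policy,
    stochastic = stochastic_human_policy
  )
  structure(
    list(type = type, params = params,
         decide = function(obs) fn(obs, params)),
    class = "strategy"
  )
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf(
    "<strategy '%s'> need < %g, safe %g, ask %.2f, give %.2f, debt %.2f\n",
    x$type, x$params$need_threshold, x$params$safe_level,
    x$params$ask_propensity, x$params$give_propensity,
    x$params$debt_sensitivity
  ))
  invisible(x)
}
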