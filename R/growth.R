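#' Volatility regimes for the resource growth rule
#'
#' A volatility regime bundles the parameters of the natural growth rule: a
#' dimensionless rate parameter and the lower and upper critical values
#' (`L`, `U`) between which a player's resource stock grows. Stocks shrink
#' below `L` (a strong Allee effect) and above `U` (overcrowding).
#'
#' The game uses two regimes. Under high volatility the rate is 0.25 with
#' critical values 8 and 25; under low volatility the rate is 0.05 with
#' critical values 2 and 25. High volatility makes both growth and collapse
#' faster, so mistakes and bad shocks are harder to recover from.
#'
#' @param rate Growth rate per period (dimensionless, > 0).
#' @param lower Lower critical value `L` in resource units (0 < `lower` < `upper`).
#' @param upper Upper critical value `U` in resource units.
#' @param label Regime label, conventionally `"high"` or `"low"`.
#' @return An object of class `volatility_regime`.
#' @examples
#' high_volatility_regime()
#' growth(16, high_volatility_regime())
#' @export
volatility_regime <- function(rate, lower, upper, label = "custom") {
  stopifnot(is.numeric(rate), is.numeric(lower), is.numeric(upper))
  if (!is.finite(rate) || rate <= 0) {
    stop("`rate` must be a positive finite number", call. = FALSE)
  }
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || lower >= upper) {
    stop("critical values must satisfy 0 < lower < upper", call. = FALSE)
  }
  structure(
    list(rate = rate, lower = lower, upper = upper, label = as.character(label)),
    class = "volatility_regime"
  )
}

#' @rdname volatility_regime
#' @export
high_volatility_regime <- function() volatility_regime(0.25, 8, 25, "high")

#' @rdname volatility_regime
#' @export
low_volatility_regime <- function() volatility_regime(0.05, 2, 25, "low")

#' @export
print.volatility_regime <- function(x, ...) {
  cat(sprintf(
    "<volatility_regime '%s'> rate = %g, critical values L = %g, U = %g\n",
    x$label, x$rate, x$lower, x$upper
  ))
  invisible(x)
}

#' Natural growth increment of a resource stock
#'
#' Computes the per-period change in a resource stock due to natural growth,
#' before transfers and shocks. The rule is the cubic strong-Allee form
#' \deqn{g(s) = r \, s \, (s/L - 1) (1 - s/U),}
#' which is zero exactly at the critical values `L` and `U`, positive strictly
#' between them, and negative below `L` and above `U`. Its maximum over stock
#' sits at \eqn{(U + L + \sqrt{U^2 - UL + L^2})/3}: about 18.37 units under
#' the high-volatility regime and 17.02 under low volatility, which is why
#' players are advised to hold their stock near 18 (high) or 17 (low) units.
#'
#' @param stock Resource stock after harvest (non-negative, finite). Vectorised.
#' @param regime A [volatility_regime()].
#' @return Growth increment(s) in resource units; may be negative.
#' @examples
#' growth(16, high_volatility_regime())  # 1.44
#' growth(8, high_volatility_regime())   # 0: lower critical value
#' @export
growth <- function(stock, regime) {
  stopifnot(inherits(regime, "volatility_regime"))
  if (!is.numeric(stock) || any(!is.finite(stock)) || any(stock < 0)) {
    stop("`stock` must be finite and non-negative", call. = FALSE)
  }
  regime$rate * stock * (stock / regime$lower - 1) * (1 - stock / regime$upper)
}

#' Stock level at which growth is fastest
#'
#' Closed-form argmax of [growth()] over stock:
#' \eqn{(U + L + \sqrt{U^2 - UL + L^2})/3}.
#'
#' @param regime A [volatility_regime()].
#' @return The stock (resource units) maximising the growth increment.
#' @examples
#' growth_optimum(high_volatility_regime())  # ~18.37
#' growth_optimum(low_volatility_regime())   # ~17.02
#' @export
growth_optimum <- function(regime) {
  stopifnot(inherits(regime, "volatility_regime"))
  L <- regime$lower
  U <- regime$upper
  (U + L + sqrt(U^2 - U * L + L^2)) / 3
}

#' Random shock models
#'
#' Shocks perturb stocks each period. They average zero, can be positive or
#' negative, and are independent of stock size. Three families are provided:
#' `normal` (mean 0, sd = `scale`), `uniform` (on `[-scale, scale]`) and
#' `discrete` (uniform on the integers `-scale, ..., scale`).
#'
#' @param distribution One of `"normal"`, `"uniform"`, `"discrete"`.
#' @param scale Scale in resource units: the sd for `normal`, the half-width
#'   for the uniform families. `scale = 0` disables shocks.
#' @return An object of class `shock_model`.
#' @export
shock_model <- function(distribution = c("normal", "uniform", "discrete"),
                        scale = 2) {
  distribution <- match.arg(distribution)
  if (!is.numeric(scale) || !is.finite(scale) || scale < 0) {
    stop("`scale` must be a finite non-negative number", call. = FALSE)
  }
  if (distribution == "discrete") scale <- round(scale)
  structure(list(distribution = distribution, scale = scale),
            class = "shock_model")
}

#' Draw shocks from a shock model
#'
#' @param model A [shock_model()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, mean-zero by construction.
#' @export
draw_shocks <- function(model, n) {
  stopifnot(inherits(model, "shock_model"), n >= 0)
  if (model$scale == 0) return(rep(0, n))
  switch(model$distribution,
    normal = stats::rnorm(n, mean = 0, sd = model$scale),
    uniform = stats::runif(n, min = -model$scale, max = model$scale),
    discrete = sample(seq(-model$scale, model$scale), n, replace = TRUE)
  )
}
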