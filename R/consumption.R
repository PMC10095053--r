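#' Oxygen consumption model for respiring tissue
#'
#' Bundles the lumped parameters of the tissue oxygen-uptake law. Steady-state
#' tension profiles depend on the maximal consumption rate `Q0` and the tissue
#' Krogh coefficient `K` only through the ratio `Q0/K`, written `2a` and called
#' the curvature (units mmHg/um^2): it is the curvature of the tension parabola
#' where consumption is maximal. Below the critical tension `P*` consumption
#' falls linearly to zero at zero tension; the smooth Michaelis-Menten
#' alternative with half-maximum constant `KM` (default `P*/2`) is available
#' for comparison.
#'
#' @param q0_over_k curvature scale `2a = Q0/K` in mmHg/um^2 (non-negative).
#' @param p_star critical tension `P*` in mmHg (non-negative).
#' @param km Michaelis constant in mmHg; defaults to `p_star/2`.
#' @param hill_n Hill exponent for the generalised Michaelis form (>= 1).
#' @return An object of class `consumption_model`.
#' @examples
#' m <- consumption_model(q0_over_k = 4e-3, p_star = 10)
#' consumption_rate(5, m, q0 = 1)   # half-maximal
#' @export
consumption_model <- function(q0_over_k, p_star, km = p_star / 2, hill_n = 1) {
  stopifnot(is.numeric(q0_over_k), length(q0_over_k) == 1L, q0_over_k >= 0,
            is.numeric(p_star), length(p_star) == 1L, p_star >= 0,
            is.numeric(hill_n), hill_n >= 1)
  structure(list(q0_over_k = q0_over_k, p_star = p_star,
                 km = km, hill_n = hill_n),
            class = "consumption_model")
}

#' Piecewise-linear consumption rate
#'
#' Consumption is maximal (`q0`) when tension exceeds the critical value and
#' falls linearly to zero below it: `Q(P) = (P/P*) q0` for `0 <= P <= P*`,
#' `q0` for `P > P*`. Continuous at the knee.
#'
#' @param p oxygen tension, mmHg (vectorised, non-negative).
#' @param model a [consumption_model()].
#' @param q0 maximal consumption rate (any rate unit; returned in kind).
#' @return Consumption rate, same unit as `q0`.
#' @export
consumption_rate <- function(p, model, q0 = 1) {
  stopifnot(inherits(model, "consumption_model"))
  if (any(p < 0)) stop("oxygen tension must be non-negative")
  if (model$p_star == 0) return(rep(q0, length(p)))
  q0 * pmin(p / model$p_star, 1)
}

#' Michaelis-Menten consumption rate
#'
#' Generalised hyperbolic uptake law `Q(P) = q0 P^n / (KM^n + P^n)`, the
#' smooth counterpart of the piecewise-linear model; with `KM = P*/2` the two
#' agree at zero, at half-maximum and asymptotically.
#'
#' @inheritParams consumption_rate
#' @return Consumption rate, same unit as `q0`.
#' @export
michaelis_rate <- function(p, model, q0 = 1) {
  stopifnot(inherits(model, "consumption_model"))
  if (any(p < 0)) stop("oxygen tension must be non-negative")
  if (!is.numeric(model$km) || model$km <= 0) stop("km must be positive")
  n <- model$hill_n
  q0 * p^n / (model$km^n + p^n)
}
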