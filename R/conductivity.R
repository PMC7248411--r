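#' Electroporation increase factor as a function of pulse number
#'
#' Evaluates `A(N) = a1 * (1 - (1 + N/b1)^(-c1))`. `A(0) = 0` (untreated
#' tissue), `A` increases strictly with `N` and approaches the asymptote
#' `a1` as the cumulative electroporation effect saturates. `N` may be
#' non-integer (the continuous extension used when fitting).
#'
#' @param N Pulse count, `>= 0`; vectorised.
#' @param model A [pulse_number_model()].
#' @return Dimensionless increase factor(s).
#' @export
increase_factor <- function(N, model) {
  stopifnot(inherits(model, "pulse_number_model"))
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 0)) {
    stop("`N` must be numeric and >= 0.", call. = FALSE)
  }
  if (!is.null(model$clamp_N)) N <- rep(model$clamp_N, length(N))
  model$a1 * (1 - (1 + N / model$b1)^(-model$c1))
}

#' Lower turning point of the conductivity curve vs pulse number
#'
#' Evaluates `E0(N) = a2 / N + b2 * exp(-c2 * N)` (V/m): the field at which
#' conductivity begins to rise. It decreases with pulse number (tissue gets
#' easier to porate) and tends to 0 as `N -> Inf`. At `N = 0` the reciprocal
#' term diverges -- no pulse has been applied, so no finite field has started
#' porating the tissue -- and the function returns `Inf` rather than raising
#' a numeric error.
#'
#' @param N Pulse count, `> 0` for a finite value (vectorised); `N = 0`
#'   yields `Inf`.
#' @param model A [pulse_number_model()].
#' @return Field magnitude(s) in V/m.
#' @export
lower_turning_point <- function(N, model) {
  stopifnot(inherits(model, "pulse_number_model"))
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 0)) {
    stop("`N` must be numeric and >= 0.", call. = FALSE)
  }
  if (!is.null(model$clamp_N)) N <- rep(model$clamp_N, length(N))
  out <- model$a2 / N + model$b2 * exp(-model$c2 * N)
  out[N == 0] <- Inf
  out
}

#' Tissue conductivity from the smoothed-Heaviside model
#'
#' Evaluates the field- and temperature-dependent conductivity for a single
#' pulse number. Two couplings of the temperature term are supported:
#' \describe{
#'   \item{additive (default)}{\eqn{\sigma = \sigma_0 (1 + A f + \alpha (T - T_0))},
#'     temperature effect referenced to the baseline conductivity;}
#'   \item{multiplicative}{\eqn{\sigma = \sigma_0 (1 + A f)(1 + \alpha (T - T_0))},
#'     temperature effect referenced to the electroporated conductivity.}
#' }
#' with \eqn{f = \mathrm{flc2hs}(E - E_{del}, E_{range})}. The variants agree
#' whenever `alpha = 0` or `T = T0`; the multiplicative form attributes more
#' of the observed rise to temperature, the additive form more to the
#' increase factor.
#'
#' @param E Electric field magnitude (V/m), `>= 0`; vectorised.
#' @param T Tissue temperature (degC); vectorised (recycled against `E`).
#' @param params A [heaviside_params()].
#' @param variant `"additive"` or `"multiplicative"`.
#' @return Conductivity in S/m.
#' @examples
#' p <- heaviside_params(sigma0 = 0.137, A = 2.3919, E0 = 3.7e4, E1 = 8e4)
#' conductivity(c(0, 5e4, 2e5), 24, p)
#' @export
conductivity <- function(E, T, params, variant = c("additive", "multiplicative")) {
  stopifnot(inherits(params, "heaviside_params"))
  variant <- match.arg(variant)
  if (!is.numeric(E) || any(E < 0, na.rm = TRUE)) {
    stop("`E` must be numeric and >= 0.", call. = FALSE)
  }
  f <- flc2hs(E - params$E_del, params$E_range)
  dT <- T - params$T0
  switch(variant,
    additive = params$sigma0 * (1 + params$A * f + params$alpha * dT),
    multiplicative = params$sigma0 * (1 + params$A * f) * (1 + params$alpha * dT)
  )
}

#' Multi-pulse tissue conductivity sigma(E, N, T)
#'
#' Composes the smoothed-Heaviside curve with the pulse-number parameter
#' functions: the curve evaluated at pulse `N` uses
#' `A = increase_factor(N)`, `E0 = lower_turning_point(N)` and the constant
#' upper turning point `E1_const`. At `N = 1` this reduces exactly to the
#' conventional single-pulse model sigma(E, T).
#'
#' @param E Field magnitude (V/m); vectorised.
#' @param N Pulse number, `>= 1`; scalar or vector recycled against `E`.
#' @param T Temperature (degC); vectorised.
#' @param model A [pulse_number_model()].
#' @param variant Temperature coupling, see [conductivity()].
#' @return Conductivity in S/m.
#' @examples
#' m <- liver_multipulse_model()
#' conductivity_multi_pulse(2.5e5, N = c(1, 30, 90), T = 24, model = m)
#' @export
conductivity_multi_pulse <- function(E, N, T, model,
                                     variant = c("additive", "multiplicative")) {
  stopifnot(inherits(model, "pulse_number_model"))
  variant <- match.arg(variant)
  if (!is.numeric(N) || any(!is.finite(N)) || any(N < 1)) {
    stop("`N` must be numeric and >= 1.", call. = FALSE)
  }
  n <- max(length(E), length(N), length(T))
  E <- rep_len(E, n); N <- rep_len(N, n); T <- rep_len(T, n)
  A <- increase_factor(N, model)
  E0 <- lower_turning_point(N, model)
  E_del <- (E0 + model$E1_const) / 2
  E_range <- (model$E1_const - E0) / 2
  if (any(E_range <= 0)) {
    stop("lower turning point must stay below `E1_const`.", call. = FALSE)
  }
  # vectorised over N: flc2hs scale differs per element
  t <- pmin(pmax((E - E_del) / E_range, -1), 1)
  f <- 0.5 + t * (0.9375 + t * t * (-0.625 + 0.1875 * t * t))
  dT <- T - model$T0
  switch(variant,
    additive = model$sigma0 * (1 + A * f + model$alpha * dT),
    multiplicative = model$sigma0 * (1 + A * f) * (1 + model$alpha * dT)
  )
}

#' Conventional single-pulse view of a multi-pulse model
#'
#' Returns a view of `model` whose pulse-number functions always evaluate at
#' `N = 1`: the conventional conductivity model sigma(E, T), in which all
#' conductivity growth over a pulse train is attributed to Joule heating
#' alone. Used as the comparison baseline in simulations.
#'
#' @param model A [pulse_number_model()].
#' @return A `pulse_number_model` with `N` clamped to 1.
#' @export
clamp_conventional <- function(model) {
  stopifnot(inherits(model, "pulse_number_model"))
  model$clamp_N <- 1
  model
}
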