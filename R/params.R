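#' Parameters of the smoothed-Heaviside conductivity curve at one pulse number
#'
#' Bundles the parameters of the field-conductivity curve
#' \deqn{\sigma(E, T) = \sigma_0 (1 + A\,\mathrm{flc2hs}(E - E_{del},
#'   E_{range}) + \alpha (T - T_0)),}
#' where the transition zone runs from the lower turning point `E0`
#' (conductivity starts to rise) to the upper turning point `E1` (the rise
#' saturates). The curve is parameterised here by the turning points, the
#' quantities that are modelled against pulse number; the step centre
#' `E_del = (E0 + E1)/2` and half-width `E_range = (E1 - E0)/2` are derived.
#'
#' @param sigma0 Baseline conductivity before treatment (S/m), positive.
#' @param A Dimensionless electroporation increase factor, `A >= 0`; fully
#'   porated tissue saturates at `sigma0 * (1 + A)`.
#' @param E0 Lower turning point of the curve (V/m), `0 <= E0 < E1`.
#' @param E1 Upper turning point (V/m).
#' @param alpha Temperature coefficient of conductivity (1/degC), `>= 0`;
#'   soft tissue is typically 0.01-0.03, default 0.02.
#' @param T0 Reference (pre-treatment) temperature (degC), default 24.
#' @return An object of class `heaviside_params` (a named list with the six
#'   fields plus derived `E_del`, `E_range`).
#' @seealso [conductivity()], [pulse_number_model()]
#' @examples
#' heaviside_params(sigma0 = 0.137, A = 2.39, E0 = 3.7e4, E1 = 8e4)
#' @export
heaviside_params <- function(sigma0, A, E0, E1, alpha = 0.02, T0 = 24) {
  stopifnot(
    is.numeric(sigma0), length(sigma0) == 1L,
    is.numeric(A), length(A) == 1L,
    is.numeric(E0), length(E0) == 1L,
    is.numeric(E1), length(E1) == 1L
  )
  if (!is.finite(sigma0) || sigma0 <= 0) {
    stop("`sigma0` must be positive.", call. = FALSE)
  }
  if (!is.finite(A) || A < 0) stop("`A` must be >= 0.", call. = FALSE)
  if (!is.finite(E0) || E0 < 0 || E0 >= E1) {
    stop("Turning points must satisfy 0 <= E0 < E1.", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha < 0) stop("`alpha` must be >= 0.", call. = FALSE)
  structure(
    list(
      sigma0 = sigma0, A = A, E0 = E0, E1 = E1,
      alpha = alpha, T0 = T0,
      E_del = (E0 + E1) / 2, E_range = (E1 - E0) / 2
    ),
    class = "heaviside_params"
  )
}

#' @export
print.heaviside_params <- function(x, ...) {
  cat("<heaviside_params>\n")
  cat(sprintf("  sigma0 = %.4g S/m, A = %.4g\n", x$sigma0, x$A))
  cat(sprintf("  E0 = %.4g V/m, E1 = %.4g V/m (E_del = %.4g, E_range = %.4g)\n",
              x$E0, x$E1, x$E_del, x$E_range))
  cat(sprintf("  alpha = %.3g /degC, T0 = %.3g degC\n", x$alpha, x$T0))
  invisible(x)
}

#' Pulse-number dependence of the conductivity-curve parameters
#'
#' A `pulse_number_model` extends the single-curve parameters to a pulse
#' train by letting the increase factor and the lower turning point evolve
#' with the pulse number `N`:
#' \deqn{A(N) = a_1 \left(1 - (1 + N/b_1)^{-c_1}\right), \qquad
#'       E_0(N) = a_2 / N + b_2\, e^{-c_2 N},}
#' while the upper turning point `E1_const` and the baseline `sigma0` stay
#' fixed. `A(N)` is a symmetric sigmoid in `log N`: zero before the first
#' pulse and saturating at `a1` as electroporation accumulates. `E0(N)`
#' decreases toward zero: the more pulses delivered, the lower the field
#' needed to start porating the tissue.
#'
#' @param a1,b1,c1 Coefficients of `A(N)`; all strictly positive
#'   (`a1` dimensionless asymptote, `b1` in pulses, `c1` dimensionless).
#' @param a2,b2,c2 Coefficients of `E0(N)`; all `>= 0`
#'   (`a2` in V m^-1 pulses, `b2` in V/m, `c2` in 1/pulse).
#' @param E1_const Upper turning point (V/m), constant across pulses.
#' @param sigma0,alpha,T0 As in [heaviside_params()].
#' @return An object of class `pulse_number_model`.
#' @seealso [increase_factor()], [lower_turning_point()],
#'   [conductivity_multi_pulse()], [liver_multipulse_model()]
#' @export
pulse_number_model <- function(a1, b1, c1, a2, b2, c2, E1_const,
                               sigma0, alpha = 0.02, T0 = 24) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop(sprintf("`%s` must be a single finite number.", nm), call. = FALSE)
    }
    x
  }
  for (nm in c("a1", "b1", "c1", "a2", "b2", "c2", "E1_const", "sigma0")) {
    num1(get(nm), nm)
  }
  if (a1 <= 0 || b1 <= 0 || c1 <= 0) {
    stop("A(N) coefficients a1, b1, c1 must all be > 0.", call. = FALSE)
  }
  if (a2 < 0 || b2 < 0 || c2 < 0) {
    stop("E0(N) coefficients a2, b2, c2 must all be >= 0.", call. = FALSE)
  }
  if (E1_const <= 0) stop("`E1_const` must be > 0.", call. = FALSE)
  if (sigma0 <= 0) stop("`sigma0` must be > 0.", call. = FALSE)
  if (alpha < 0) stop("`alpha` must be >= 0.", call. = FALSE)
  structure(
    list(
      a1 = a1, b1 = b1, c1 = c1,
      a2 = a2, b2 = b2, c2 = c2,
      E1_const = E1_const, sigma0 = sigma0, alpha = alpha, T0 = T0,
      clamp_N = NULL
    ),
    class = "pulse_number_model"
  )
}

#' @export
print.pulse_number_model <- function(x, ...) {
  cat("<pulse_number_model>\n")
  if (!is.null(x$clamp_N)) {
    cat(sprintf("  [conventional view: N clamped to %g]\n", x$clamp_N))
  }
  cat(sprintf("  A(N)  = %.4g * (1 - (1 + N/%.4g)^-%.4g)\n", x$a1, x$b1, x$c1))
  cat(sprintf("  E0(N) = %.4g / N + %.4g * exp(-%.4g N)  [V/m]\n",
              x$a2, x$b2, x$c2))
  cat(sprintf("  E1 = %.4g V/m, sigma0 = %.4g S/m, alpha = %.3g /degC, T0 = %.3g degC\n",
              x$E1_const, x$sigma0, x$alpha, x$T0))
  invisible(x)
}

#' Reference rabbit-liver multi-pulse conductivity model
#'
#' The fitted parameter set for ex vivo rabbit liver under 90 x 100 us
#' pulses at 1 Hz: baseline conductivity 0.137 S/m, increase factor
#' saturating at 2.3919, lower turning point decaying from ~3.7e4 V/m at the
#' first pulse toward zero, temperature coefficient 2 %/degC from 24 degC.
#' The upper turning point has no published value; the shipped default of
#' 8.0e4 V/m (800 V/cm) is this package's assumption, chosen inside the
#' characterised field range, and should be overridden when a fitted value
#' is available.
#'
#' This model is the default ground truth for the synthetic-data generator,
#' which makes the whole pipeline exercisable without treatment recordings.
#'
#' @param E1_const Upper turning point (V/m); see Details.
#' @return A [pulse_number_model()].
#' @examples
#' m <- liver_multipulse_model()
#' increase_factor(90, m)
#' @export
liver_multipulse_model <- function(E1_const = 8.0e4) {
  pulse_number_model(
    a1 = 2.3919, b1 = 0.0018, c1 = 0.2802,
    a2 = 8.0861e3, b2 = 2.9056e4, c2 = 0.0027,
    E1_const = E1_const, sigma0 = 0.137, alpha = 0.02, T0 = 24
  )
}

#' Materialise the conductivity curve of one pulse number
#'
#' Evaluates the pulse-number functions of a [pulse_number_model()] at `N`
#' and returns the resulting single-curve [heaviside_params()].
#'
#' @param model A [pulse_number_model()].
#' @param N Pulse number, `>= 1`.
#' @return A [heaviside_params()].
#' @export
params_at_pulse <- function(model, N) {
  stopifnot(inherits(model, "pulse_number_model"), length(N) == 1L)
  heaviside_params(
    sigma0 = model$sigma0,
    A = increase_factor(N, model),
    E0 = lower_turning_point(N, model),
    E1 = model$E1_const,
    alpha = model$alpha, T0 = model$T0
  )
}
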