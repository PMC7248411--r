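#' Smoothed Heaviside step with a continuous second derivative
#'
#' `flc2hs()` ramps from 0 to 1 over a finite transition zone of half-width
#' `scale` centred on `x = 0`. Inside the zone it is the unique odd-symmetric
#' quintic polynomial in `t = x / scale`,
#' \deqn{f(t) = 0.5 + 0.9375\,t - 0.625\,t^3 + 0.1875\,t^5,}
#' whose value, first and second derivative match the clamped constants at
#' both endpoints (`f(-1) = 0`, `f(1) = 1`, `f' = f'' = 0` there), making the
#' composite function twice continuously differentiable everywhere. The
#' coefficients follow from solving the three endpoint-matching conditions
#' for the odd part; this is the conventional C2 step used by finite-element
#' packages under the same name.
#'
#' In the conductivity model the argument is the signed field offset
#' `E - E_del` and the scale is the transition half-width `E_range`, so the
#' step carries the electroporation term from 0 (no poration, `E <= E0`) to
#' 1 (full poration, `E >= E1`).
#'
#' @param x Signed offset from the step centre (same units as `scale`,
#'   typically V/m). Vectorised.
#' @param scale Transition half-width; a single positive number.
#' @return A numeric vector in `[0, 1]`, the smoothed step evaluated at `x`.
#' @examples
#' flc2hs(0, 1)                    # 0.5 at the centre
#' flc2hs(c(-2, -1, 1, 2), 1)      # clamped to 0 / 1 outside the zone
#' @export
flc2hs <- function(x, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive finite number.", call. = FALSE)
  }
  t <- pmin(pmax(x / scale, -1), 1)
  0.5 + t * (0.9375 + t * t * (-0.625 + 0.1875 * t * t))
}
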