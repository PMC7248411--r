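#' Simulate a pulse train with the lumped uniform-field model
#'
#' For the plate-electrode sample the field is uniform, so the coupled
#' electro-thermal problem reduces to scalar recursions: at pulse `n`, with
#' start-of-pulse temperature `T_n`,
#' \deqn{E = U/L, \quad \sigma_n = \sigma(E, n, T_n), \quad
#'       I_n = \sigma_n E S,}
#' and the temperature advances by one [thermal_step()] of duty-scaled Joule
#' heating. In `"conventional"` mode the pulse-number argument is clamped to
#' 1 (the single-pulse model sigma(E, T)): any current growth over the train
#' then comes from Joule heating alone.
#'
#' @param model A [pulse_number_model()].
#' @param applied_voltage Pulse plateau voltage `U` (V).
#' @param geom A [sample_geometry()].
#' @param protocol A [protocol_config()].
#' @param heat_loss Lumped thermal loss rate (1/s).
#' @param mode `"multi_pulse"` or `"conventional"`.
#' @param variant Temperature coupling, see [conductivity()].
#' @param T_initial Tissue temperature before the first pulse (degC).
#' @return A tibble of class `pef_simulation` with one row per pulse:
#'   `pulse_index`, `I_A`, `T_C` (start-of-pulse), `sigma_S_per_m`;
#'   attributes `mode`, `applied_voltage`, `solver = "lumped"`.
#' @examples
#' sim <- simulate_lumped(liver_multipulse_model(), applied_voltage = 1250,
#'                        geom = sample_geometry(),
#'                        protocol = protocol_config(n_pulses = 10))
#' sim
#' @export
simulate_lumped <- function(model, applied_voltage, geom = sample_geometry(),
                            protocol = protocol_config(), heat_loss = 0.06,
                            mode = c("multi_pulse", "conventional"),
                            variant = "additive", T_initial = model$T0) {
  stopifnot(inherits(model, "pulse_number_model"),
            inherits(geom, "sample_geometry"),
            inherits(protocol, "protocol_config"),
            applied_voltage > 0)
  mode <- match.arg(mode)
  E <- applied_voltage / geom$L
  n <- protocol$n_pulses
  I <- Tt <- sig <- numeric(n)
  Tn <- T_initial
  for (i in seq_len(n)) {
    Tt[i] <- Tn
    Neff <- if (mode == "conventional") 1 else i
    sig[i] <- conductivity_multi_pulse(E, Neff, Tn, model, variant = variant)
    I[i] <- sig[i] * E * geom$S
    Tn <- thermal_step(Tn, sig[i], E, geom, protocol, heat_loss,
                       T_amb = model$T0)
  }
  out <- tibble::tibble(pulse_index = seq_len(n), I_A = I, T_C = Tt,
                        sigma_S_per_m = sig)
  structure(out,
            class = c("pef_simulation", class(out)),
            mode = mode, applied_voltage = applied_voltage, solver = "lumped")
}
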