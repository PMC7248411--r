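#' Advance the lumped sample temperature by one inter-pulse period
#'
#' A lumped surrogate of the bioheat equation for the small plate-electrode
#' sample: over one period `tau` the tissue gains the duty-scaled Joule heat
#' `sigma * E^2 * (d / tau) / (rho * c_p)` (d = pulse width) and loses heat
#' at a Newton-type rate `heat_loss` toward the ambient temperature,
#' \deqn{T' = T + \left[\frac{\sigma E^2 (d/\tau)}{\rho c_p}
#'   - h (T - T_{amb})\right] \tau.}
#' With `heat_loss = 0` this is adiabatic duty-averaged heating; for
#' `heat_loss * tau <= 1` the update cannot undershoot ambient.
#'
#' @param T Temperature at the start of the period (degC).
#' @param sigma Tissue conductivity during the pulse (S/m).
#' @param E Field magnitude during the pulse (V/m).
#' @param geom A [sample_geometry()] (supplies `rho`, `c_p`).
#' @param protocol A [protocol_config()] (supplies pulse width and period).
#' @param heat_loss Lumped loss rate toward ambient (1/s), `>= 0`.
#' @param T_amb Ambient / boundary temperature (degC, default 24).
#' @return Temperature after one period (degC).
#' @export
thermal_step <- function(T, sigma, E, geom, protocol, heat_loss, T_amb = 24) {
  stopifnot(inherits(geom, "sample_geometry"), inherits(protocol, "protocol_config"))
  if (!is.numeric(heat_loss) || heat_loss < 0) {
    stop("`heat_loss` must be >= 0.", call. = FALSE)
  }
  duty <- protocol$pulse_width / protocol$period
  q <- sigma * E^2 * duty / (geom$rho * geom$c_p)
  T + (q - heat_loss * (T - T_amb)) * protocol$period
}

#' Generate synthetic multi-pulse treatment recordings
#'
#' Simulates the characterisation experiment from a ground-truth
#' [pulse_number_model()] and the lumped electro-thermal plant: for every
#' field magnitude and replicate, a train of pulses is applied to a fresh
#' sample at the initial temperature. Each pulse `n` sees the uniform field
#' `E = U / L`, the conductivity `sigma_n = sigma(E, n, T_n)` from the truth
#' model, and delivers the end-of-pulse current
#' `I_n = sigma_n * E * S * (1 + eps_n)` with multiplicative Gaussian noise
#' `eps_n ~ N(0, noise)` on the current channel only (the voltage is a
#' set-point). Temperature advances between pulses with [thermal_step()] and
#' is reported at 1 Hz aligned to pulse firing times.
#'
#' The defaults (3 % current noise, `heat_loss = 0.06` /s giving a terminal
#' rise of roughly 13 degC at 2,500 V/cm) are the package's synthetic study
#' conditions; they are documented in the methods vignette and are not tuned
#' per run.
#'
#' @param truth Ground-truth [pulse_number_model()].
#' @param protocol A [protocol_config()].
#' @param geom A [sample_geometry()].
#' @param noise Relative s.d. of the multiplicative current noise
#'   (dimensionless, default 0.03).
#' @param heat_loss Lumped thermal loss rate (1/s, default 0.06).
#' @param seed Integer RNG seed; a fixed seed gives a bit-identical dataset.
#' @param T_initial Sample temperature before the first pulse (degC).
#' @param variant Temperature coupling of the truth model, see [conductivity()].
#' @return A tibble with one row per pulse:
#'   `magnitude_V_per_cm`, `replicate`, `pulse_index`, `U_avg_V`, `I_avg_A`,
#'   `T_C` (temperature at the pulse). Protocol, geometry, truth parameters
#'   and seed are attached as attribute `"manifest"`.
#' @examples
#' d <- generate_dataset(liver_multipulse_model(),
#'                       protocol_config(n_pulses = 10, field_magnitudes = c(400, 2000),
#'                                       replicates = 1),
#'                       sample_geometry(), noise = 0, seed = 1)
#' head(d)
#' @export
generate_dataset <- function(truth, protocol = protocol_config(),
                             geom = sample_geometry(),
                             noise = 0.03, heat_loss = 0.06, seed = 1L,
                             T_initial = 24, variant = "additive") {
  stopifnot(inherits(truth, "pulse_number_model"),
            inherits(protocol, "protocol_config"),
            inherits(geom, "sample_geometry"))
  if (!is.numeric(noise) || noise < 0) stop("`noise` must be >= 0.", call. = FALSE)
  if (heat_loss < 0) stop("`heat_loss` must be >= 0.", call. = FALSE)
  withr::local_seed(as.integer(seed))

  grid <- tidyr::expand_grid(
    magnitude_V_per_cm = protocol$field_magnitudes,
    replicate = seq_len(protocol$replicates)
  )
  series <- purrr::pmap(grid, function(magnitude_V_per_cm, replicate) {
    U <- magnitude_V_per_cm * 100 * geom$L   # V/cm -> V/m, times gap
    E <- U / geom$L
    n <- protocol$n_pulses
    T_tr <- sigma_tr <- numeric(n)
    Tn <- T_initial
    for (i in seq_len(n)) {
      T_tr[i] <- Tn
      sigma_tr[i] <- conductivity_multi_pulse(E, i, Tn, truth, variant = variant)
      Tn <- thermal_step(Tn, sigma_tr[i], E, geom, protocol, heat_loss,
                         T_amb = truth$T0)
    }
    eps <- if (noise > 0) stats::rnorm(n, 0, noise) else numeric(n)
    tibble::tibble(
      pulse_index = seq_len(n),
      U_avg_V = U,
      I_avg_A = sigma_tr * E * geom$S * (1 + eps),
      T_C = T_tr
    )
  })
  out <- dplyr::bind_cols(
    grid[rep(seq_len(nrow(grid)), each = protocol$n_pulses), ],
    dplyr::bind_rows(series)
  )
  attr(out, "manifest") <- list(
    truth = truth[c("a1", "b1", "c1", "a2", "b2", "c2",
                    "E1_const", "sigma0", "alpha", "T0")],
    protocol = unclass(protocol), geometry = unclass(geom)[c("L", "diameter", "S")],
    noise = noise, heat_loss = heat_loss, seed = as.integer(seed),
    T_initial = T_initial, variant = variant
  )
  out
}

#' Synthesise a raw voltage/current waveform for one pulse
#'
#' Emits a sampled 100 us flat-top pulse whose mean over the last-4-us
#' averaging window equals the record's `(U_avg, I_avg)` exactly: a linear
#' rise over `rise_time`, a flat top, and an optional capacitive current
#' spike at pulse onset that decays completely (time constant
#' `rise_time / 4`, i.e. to below 1e-12 of its amplitude) before the
#' averaging window opens. Used to exercise the waveform-averaging path of
#' the extraction stage.
#'
#' @param U_avg,I_avg End-of-pulse voltage (V) and current (A) plateaux.
#' @param pulse_width Pulse width (s, default 1e-4).
#' @param sample_rate Samples per second; must resolve the last 4 us with at
#'   least 8 samples (i.e. `>= 2e6`).
#' @param rise_time Linear rise time at onset (s, default 1e-6).
#' @param spike_amplitude Capacitive spike amplitude added to the current
#'   channel at onset (A, default 0).
#' @return A tibble `t_s`, `V`, `A` sampled at `sample_rate`.
#' @export
synthesize_waveform <- function(U_avg, I_avg, pulse_width = 1e-4,
                                sample_rate = 1e7, rise_time = 1e-6,
                                spike_amplitude = 0) {
  stopifnot(U_avg > 0, I_avg > 0, pulse_width > 0, rise_time > 0,
            rise_time < pulse_width / 2)
  window <- 4e-6
  if (sample_rate * window < 8) {
    stop("`sample_rate` must resolve the last 4 us with >= 8 samples.",
         call. = FALSE)
  }
  t <- seq(0, pulse_width, by = 1 / sample_rate)
  ramp <- pmin(t / rise_time, 1)
  spike_tau <- rise_time / 4
  tibble::tibble(
    t_s = t,
    V = U_avg * ramp,
    A = I_avg * ramp + spike_amplitude * exp(-t / spike_tau)
  )
}
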