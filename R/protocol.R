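#' Pulse-train treatment protocol
#'
#' Describes the pulsing protocol applied to each sample. The defaults are
#' the standard IRE-style characterisation protocol: 90 monopolar pulses of
#' 100 us width delivered at 1 Hz, with the training field magnitudes
#' 100-2,800 V/cm used to fit the conductivity model and the held-out
#' magnitudes 500/1,000/1,500/2,500 V/cm used to validate it. Magnitudes are
#' nominal applied fields in V/cm (the unit instruments are programmed in);
#' everything internal works in V/m.
#'
#' @param n_pulses Number of pulses per treatment (default 90).
#' @param pulse_width Pulse width in seconds (default 1e-4).
#' @param period Inter-pulse period in seconds (default 1).
#' @param field_magnitudes Nominal applied fields in V/cm.
#' @param replicates Samples treated per magnitude (default 3).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(n_pulses = 90L,
                            pulse_width = 1e-4,
                            period = 1,
                            field_magnitudes = training_magnitudes(),
                            replicates = 3L) {
  stopifnot(n_pulses >= 1, pulse_width > 0, period > 0, replicates >= 1)
  if (pulse_width >= period) {
    stop("`pulse_width` must be smaller than `period`.", call. = FALSE)
  }
  if (any(field_magnitudes <= 0)) {
    stop("All field magnitudes must be positive.", call. = FALSE)
  }
  structure(
    list(
      n_pulses = as.integer(n_pulses), pulse_width = pulse_width,
      period = period, field_magnitudes = field_magnitudes,
      replicates = as.integer(replicates)
    ),
    class = "protocol_config"
  )
}

#' Standard training and validation field magnitudes
#'
#' The eleven magnitudes used to fit the conductivity model and the four
#' held-out magnitudes used to validate it, in V/cm.
#'
#' @return Numeric vector of nominal fields (V/cm).
#' @export
training_magnitudes <- function() {
  c(100, 200, 400, 600, 800, 1200, 1400, 1600, 1800, 2000, 2800)
}

#' @rdname training_magnitudes
#' @export
validation_magnitudes <- function() {
  c(500, 1000, 1500, 2500)
}

#' Cylindrical sample geometry and material constants
#'
#' The tissue sample is a cylinder held in an insulating mold between flat
#' plate electrodes, giving a uniform field `E = U / L`. Defaults match the
#' characterisation setup: 1 cm diameter, 5 mm height, liver thermal
#' constants (density 1,079 kg/m^3, heat capacity 3,540 J/kg/K, thermal
#' conductivity 0.52 W/m/K). `mold_diameter` and the mold constants are only
#' used by the axisymmetric grid solver.
#'
#' @param L Sample thickness / electrode gap (m, default 5e-3).
#' @param diameter Sample diameter (m, default 1e-2).
#' @param rho Tissue density (kg/m^3).
#' @param c_p Tissue heat capacity (J/kg/K).
#' @param k Tissue thermal conductivity (W/m/K).
#' @param mold_diameter Outer diameter of the insulating mold (m, default 2e-2).
#' @param mold Named list of mold material constants
#'   (`rho`, `c_p`, `k`, `sigma`); defaults are PLA.
#' @return An object of class `sample_geometry`; field `S` is the derived
#'   cross-sectional area `pi * (diameter/2)^2`.
#' @export
sample_geometry <- function(L = 5e-3, diameter = 1e-2,
                            rho = 1079, c_p = 3540, k = 0.52,
                            mold_diameter = 2e-2,
                            mold = list(rho = 1252, c_p = 1590, k = 0.11,
                                        sigma = 1e-16)) {
  stopifnot(L > 0, diameter > 0, rho > 0, c_p > 0, k > 0,
            mold_diameter > diameter)
  structure(
    list(
      L = L, diameter = diameter, S = pi * (diameter / 2)^2,
      rho = rho, c_p = c_p, k = k,
      mold_diameter = mold_diameter, mold = mold
    ),
    class = "sample_geometry"
  )
}
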