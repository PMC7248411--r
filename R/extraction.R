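#' Average a raw waveform over the end-of-pulse window
#'
#' The transient capacitive response at pulse onset is excluded from
#' conductivity calculations by averaging voltage and current over the last
#' 4 us of the pulse only. Both channels are averaged over the identical
#' sample set: all samples whose timestamps lie in
#' `[max(t) - window, max(t)]`.
#'
#' @param trace A data frame with columns `t_s` (s), `V` (V), `A` (A), e.g.
#'   from [synthesize_waveform()].
#' @param window Averaging window length (s, default 4e-6).
#' @return A tibble with one row: `U_avg_V`, `I_avg_A`, `n_samples`.
#' @export
average_last_window <- function(trace, window = 4e-6) {
  stopifnot(is.data.frame(trace), all(c("t_s", "V", "A") %in% names(trace)))
  if (window <= 0) stop("`window` must be positive.", call. = FALSE)
  t_end <- max(trace$t_s)
  keep <- trace$t_s >= t_end - window
  if (sum(keep) < 2L) {
    stop("Fewer than 2 samples fall in the end-of-pulse window.", call. = FALSE)
  }
  tibble::tibble(
    U_avg_V = mean(trace$V[keep]),
    I_avg_A = mean(trace$A[keep]),
    n_samples = sum(keep)
  )
}

#' Conductivity of a uniform-field sample from one pulse record
#'
#' For a cylindrical sample of thickness `L` and cross-section `S` between
#' flat plate electrodes the field is uniform, so the end-of-pulse averages
#' give the bulk conductivity directly through the shape factor `L / S`:
#' \deqn{\sigma = \frac{I \, L}{U \, S}, \qquad E = U / L.}
#'
#' @param U_avg End-of-pulse voltage average (V), `> 0`.
#' @param I_avg End-of-pulse current average (A), `> 0`.
#' @param geom A [sample_geometry()].
#' @return A tibble with one row: `E_V_per_m`, `sigma_S_per_m`.
#' @examples
#' conductivity_from_record(1000, 2.157, sample_geometry())
#' @export
conductivity_from_record <- function(U_avg, I_avg, geom) {
  stopifnot(inherits(geom, "sample_geometry"))
  if (!is.numeric(U_avg) || any(U_avg <= 0)) {
    stop("`U_avg` must be positive (open-circuit or failed pulse?).",
         call. = FALSE)
  }
  if (!is.numeric(I_avg) || any(I_avg <= 0)) {
    stop("`I_avg` must be positive.", call. = FALSE)
  }
  tibble::tibble(
    E_V_per_m = U_avg / geom$L,
    sigma_S_per_m = I_avg * geom$L / (U_avg * geom$S)
  )
}

#' Per-pulse conductivity observations from a recording table
#'
#' Applies the shape-factor conversion to every pulse of a recordings table
#' (the [generate_dataset()] schema: `magnitude_V_per_cm`, `replicate`,
#' `pulse_index`, `U_avg_V`, `I_avg_A`, `T_C`), pairing each pulse with its
#' 1 Hz temperature sample. Failed pulses (non-positive voltage or current)
#' are dropped with a warning rather than interpolated.
#'
#' @param data Recordings tibble, one row per pulse.
#' @param geom A [sample_geometry()].
#' @return A tibble of conductivity observations: `magnitude_V_per_cm`,
#'   `replicate`, `pulse_index`, `E_V_per_m`, `sigma_S_per_m`, `T_C`.
#' @examples
#' d <- generate_dataset(liver_multipulse_model(),
#'                       protocol_config(n_pulses = 5, field_magnitudes = 800,
#'                                       replicates = 1),
#'                       sample_geometry(), noise = 0)
#' extract_conductivity(d, sample_geometry())
#' @export
extract_conductivity <- function(data, geom) {
  stopifnot(is.data.frame(data), inherits(geom, "sample_geometry"))
  need <- c("magnitude_V_per_cm", "replicate", "pulse_index",
            "U_avg_V", "I_avg_A", "T_C")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("Recordings table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(data$U_avg_V) | data$U_avg_V <= 0 |
    !is.finite(data$I_avg_A) | data$I_avg_A <= 0
  if (any(bad)) {
    warning(sum(bad), " failed pulse(s) dropped from extraction.",
            call. = FALSE)
    data <- data[!bad, , drop = FALSE]
  }
  dplyr::transmute(
    data,
    .data$magnitude_V_per_cm, .data$replicate, .data$pulse_index,
    E_V_per_m = .data$U_avg_V / geom$L,
    sigma_S_per_m = .data$I_avg_A * geom$L / (.data$U_avg_V * geom$S),
    T_C = .data$T_C
  )
}
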