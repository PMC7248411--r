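#' Plot conductivity-field curves at selected pulse numbers
#'
#' Draws sigma(E) at a fixed temperature for several pulse numbers,
#' visualising how the transition zone moves left and the plateau
#' `sigma0 * (1 + A(N))` saturates as pulses accumulate.
#'
#' @param model A [pulse_number_model()].
#' @param pulses Pulse numbers to draw.
#' @param T Temperature at which to evaluate (degC); default `model$T0`
#'   isolates the electroporation term.
#' @param E_max Upper end of the field axis (V/m).
#' @return A ggplot object.
#' @export
plot_conductivity_curves <- function(model, pulses = c(1, 10, 30, 90),
                                     T = model$T0, E_max = 3e5) {
  stopifnot(inherits(model, "pulse_number_model"))
  grid <- tidyr::expand_grid(N = pulses, E = seq(0, E_max, length.out = 400))
  grid <- dplyr::mutate(
    grid,
    sigma = conductivity_multi_pulse(.data$E, .data$N, T, model),
    pulse = factor(.data$N)
  )
  ggplot2::ggplot(grid, ggplot2::aes(.data$E / 100, .data$sigma,
                                     colour = .data$pulse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Electric field (V/cm)", y = "Conductivity (S/m)",
                  colour = "Pulse number") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_per_pulse Autoplot method: per-pulse `A` and `E0`
#'   estimates against pulse number.
#' @param object A `per_pulse_fits` table.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.per_pulse_fits <- function(object, ...) {
  long <- object |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(c("A", "E0"), names_to = "parameter") |>
    dplyr::mutate(parameter = dplyr::recode(.data$parameter,
                                            A = "increase factor A",
                                            E0 = "lower turning point E0 (V/m)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$pulse_index, .data$value,
                                     shape = .data$converged)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Pulse number", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn simulate_lumped Autoplot method: per-pulse current and
#'   temperature traces.
#' @param object A `pef_simulation` tibble.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.pef_simulation <- function(object, ...) {
  long <- object |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(c("I_A", "T_C"), names_to = "channel") |>
    dplyr::mutate(channel = dplyr::recode(.data$channel,
                                          I_A = "current (A)",
                                          T_C = "temperature (degC)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$pulse_index, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Pulse number", y = NULL,
                  title = sprintf("%s / %s", attr(object, "solver"),
                                  attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_models Autoplot method: RMSE of both model modes per
#'   validation magnitude.
#' @param object A `comparison_report`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.comparison_report <- function(object, ...) {
  long <- object |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(c("rmse_multi_A", "rmse_conventional_A"),
                        names_to = "model", values_to = "rmse") |>
    dplyr::mutate(model = dplyr::recode(.data$model,
                                        rmse_multi_A = "multi-pulse",
                                        rmse_conventional_A = "conventional"))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$magnitude_V_per_cm),
                                     .data$rmse, fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Field magnitude (V/cm)", y = "RMSE (A)", fill = NULL) +
    ggplot2::theme_minimal()
}
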