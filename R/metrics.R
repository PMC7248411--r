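#' Root-mean-square error between simulated and observed sequences
#'
#' \deqn{\mathrm{RMSE} = \sqrt{\sum_i (f_i - y_i)^2 / n}.}
#' A smaller RMSE indicates closer agreement between the simulated and the
#' observed per-pulse currents.
#'
#' @param simulated,observed Equal-length numeric vectors.
#' @return A single nonnegative number in the units of the inputs.
#' @examples
#' rmse(c(1, 2), c(0, 0))  # sqrt(2.5)
#' @export
rmse <- function(simulated, observed) {
  if (length(simulated) != length(observed)) {
    stop("`simulated` and `observed` must have equal length.", call. = FALSE)
  }
  if (length(simulated) < 1L) stop("Empty sequences.", call. = FALSE)
  sqrt(mean((simulated - observed)^2))
}

#' Per-pulse relative errors against the observed mean
#'
#' `|f_i - ybar_i| / ybar_i` for each pulse, where `ybar` is the observed
#' value averaged over replicates.
#'
#' @param simulated Simulated per-pulse values.
#' @param observed_mean Replicate-averaged observed values; all `> 0`.
#' @return A vector of dimensionless relative errors.
#' @export
relative_errors <- function(simulated, observed_mean) {
  if (length(simulated) != length(observed_mean)) {
    stop("Sequences must have equal length.", call. = FALSE)
  }
  if (any(observed_mean <= 0)) {
    stop("`observed_mean` entries must be positive.", call. = FALSE)
  }
  abs(simulated - observed_mean) / observed_mean
}
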