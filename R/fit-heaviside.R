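# Per-pulse-number fitting of the smoothed-Heaviside conductivity curve.
# Internal parameterisation is (sigma0, A, E0, dE) with dE = E1 - E0 > 0 so
# the box constraints of the Levenberg-Marquardt solver enforce E0 < E1.

heaviside_residuals <- function(theta, E, sigma, T, alpha, T0, E1_fixed) {
  sigma0 <- theta[["sigma0"]]
  A <- theta[["A"]]
  E0 <- theta[["E0"]]
  E1 <- if (is.null(E1_fixed)) E0 + theta[["dE"]] else E1_fixed
  f <- flc2hs(E - (E0 + E1) / 2, (E1 - E0) / 2)
  sigma - sigma0 * (1 + A * f + alpha * (T - T0))
}

# Deterministic initial guesses: sigma0 from the two lowest magnitudes,
# A from the dynamic range, E0 from the field of steepest observed rise.
heaviside_start <- function(E, sigma, E1_fixed) {
  agg <- stats::aggregate(sigma, list(E = E), mean)
  agg <- agg[order(agg$E), ]
  sigma0 <- mean(agg$x[seq_len(min(2L, nrow(agg)))])
  A <- max((max(agg$x) - sigma0) / sigma0, 0.1)
  slopes <- diff(agg$x) / diff(agg$E)
  imax <- which.max(slopes)
  E0 <- (agg$E[imax] + agg$E[imax + 1L]) / 2
  if (!is.null(E1_fixed)) E0 <- min(E0, 0.8 * E1_fixed)
  list(sigma0 = sigma0, A = A, E0 = E0, dE = E0)
}

fit_heaviside_once <- function(start, E, sigma, T, alpha, T0, E1_fixed) {
  free <- is.null(E1_fixed)
  par <- unlist(start[c("sigma0", "A", "E0", if (free) "dE")])
  lower <- c(sigma0 = 1e-8, A = 0, E0 = 0, if (free) c(dE = 1))
  upper <- c(sigma0 = Inf, A = Inf,
             E0 = if (free) Inf else E1_fixed - 1, if (free) c(dE = Inf))
  minpack.lm::nls.lm(
    par = par, lower = lower, upper = upper,
    fn = function(p) heaviside_residuals(p, E, sigma, T, alpha, T0, E1_fixed),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
}

#' Fit the smoothed-Heaviside conductivity curve at one pulse number
#'
#' Nonlinear least squares of the conductivity model
#' `sigma = sigma0 * (1 + A * flc2hs(E - E_del, E_range) + alpha * (T - T0))`
#' to observations spanning the field range at a single pulse number. The
#' temperature coefficient and reference temperature are fixed inputs
#' (`alpha = 0.02` /degC from the soft-tissue literature, `T0 = 24` degC);
#' the free parameters are `sigma0`, `A`, `E0` and (unless `E1` is supplied)
#' `E1`, estimated under the box constraints `sigma0 > 0`, `A >= 0`,
#' `0 <= E0 < E1` by bounded Levenberg-Marquardt. Initial guesses are
#' deterministic: `sigma0` from the two lowest magnitudes, `A` from the
#' dynamic range, `E0` from the field of steepest observed rise; a small set
#' of fallback starts is tried if the first does not converge.
#'
#' @param obs A data frame of observations at one pulse number with columns
#'   `E_V_per_m`, `sigma_S_per_m`, `T_C` (see [extract_conductivity()]).
#' @param alpha Fixed temperature coefficient (1/degC).
#' @param T0 Reference temperature (degC).
#' @param E1 `NULL` to estimate the upper turning point freely, or a number
#'   (V/m) to fix it.
#' @return An object of class `heaviside_fit`: the estimated
#'   [heaviside_params()] plus `r_squared`, `residuals`, `converged` and
#'   bookkeeping fields. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_heaviside_curve <- function(obs, alpha = 0.02, T0 = 24, E1 = NULL) {
  stopifnot(is.data.frame(obs),
            all(c("E_V_per_m", "sigma_S_per_m", "T_C") %in% names(obs)))
  E <- obs$E_V_per_m; sigma <- obs$sigma_S_per_m; T <- obs$T_C
  if (length(unique(E)) < 5L) {
    stop("Need >= 5 distinct field magnitudes to identify the curve.",
         call. = FALSE)
  }
  start <- heaviside_start(E, sigma, E1)
  fit <- fit_heaviside_once(start, E, sigma, T, alpha, T0, E1)
  ss_tot <- sum((sigma - mean(sigma))^2)
  ok <- function(f) f$info %in% 1:4
  # fallback starts: shift the guessed transition zone
  if (!ok(fit) || (ss_tot > 0 && fit$deviance / ss_tot > 0.15)) {
    for (fac in c(0.5, 2, 4)) {
      alt <- start
      alt$E0 <- start$E0 * fac
      alt$dE <- alt$E0
      if (!is.null(E1)) alt$E0 <- min(alt$E0, 0.8 * E1)
      cand <- fit_heaviside_once(alt, E, sigma, T, alpha, T0, E1)
      if (ok(cand) && cand$deviance < fit$deviance) fit <- cand
    }
  }
  p <- fit$par
  E0_hat <- p[["E0"]]
  E1_hat <- if (is.null(E1)) E0_hat + p[["dE"]] else E1
  params <- heaviside_params(
    sigma0 = p[["sigma0"]], A = p[["A"]], E0 = E0_hat, E1 = E1_hat,
    alpha = alpha, T0 = T0
  )
  structure(
    list(
      params = params,
      r_squared = if (ss_tot > 0) 1 - fit$deviance / ss_tot else NA_real_,
      residuals = fit$fvec,
      converged = ok(fit),
      fixed_E1 = !is.null(E1),
      n_obs = length(E),
      deviance = fit$deviance,
      info = fit$info
    ),
    class = "heaviside_fit"
  )
}

#' @export
print.heaviside_fit <- function(x, ...) {
  cat(sprintf(
    "<heaviside_fit> R^2 = %.4f, %s, E1 %s\n", x$r_squared,
    if (x$converged) "converged" else "NOT converged",
    if (x$fixed_E1) "fixed" else "free"
  ))
  print(x$params)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.heaviside_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma0", "A", "E0", "E1"),
    estimate = c(x$params$sigma0, x$params$A, x$params$E0, x$params$E1),
    unit = c("S/m", "", "V/m", "V/m")
  )
}

#' @exportS3Method generics::glance
glance.heaviside_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, deviance = x$deviance,
    nobs = x$n_obs, converged = x$converged
  )
}

#' Fit the conductivity curve at every pulse number
#'
#' Runs [fit_heaviside_curve()] once per pulse number of an observations
#' table, pooling replicates at each magnitude. The default `E1_mode =
#' "pool"` performs two passes: first with the upper turning point free,
#' then -- because `E1` varies little with pulse number (< 5 %) -- a refit of
#' every pulse with `E1` fixed to the mean of the converged first-pass
#' estimates.
#'
#' @param obs Observations tibble from [extract_conductivity()].
#' @param alpha,T0 Fixed temperature coefficient and reference temperature.
#' @param E1_mode `"pool"` (two-pass, default), `"free"` (per-pulse `E1`),
#'   or `"fixed"` (use `E1_fixed`).
#' @param E1_fixed Upper turning point (V/m) when `E1_mode = "fixed"`.
#' @return A tibble of class `per_pulse_fits`, one row per pulse number:
#'   `pulse_index`, `sigma0`, `A`, `E0`, `E1`, `r_squared`, `converged`.
#'   Non-converged fits are retained in the table but flagged, and excluded
#'   from pooling and downstream parameter-model fits.
#' @export
fit_per_pulse <- function(obs, alpha = 0.02, T0 = 24,
                          E1_mode = c("pool", "free", "fixed"),
                          E1_fixed = NULL) {
  E1_mode <- match.arg(E1_mode)
  if (E1_mode == "fixed" && is.null(E1_fixed)) {
    stop("`E1_fixed` is required when `E1_mode = \"fixed\"`.", call. = FALSE)
  }
  one_pass <- function(E1) {
    obs |>
      dplyr::group_by(.data$pulse_index) |>
      dplyr::group_modify(function(d, key) {
        f <- fit_heaviside_curve(d, alpha = alpha, T0 = T0, E1 = E1)
        tibble::tibble(
          sigma0 = f$params$sigma0, A = f$params$A,
          E0 = f$params$E0, E1 = f$params$E1,
          r_squared = f$r_squared, converged = f$converged
        )
      }) |>
      dplyr::ungroup()
  }
  fits <- switch(E1_mode,
    free = one_pass(NULL),
    fixed = one_pass(E1_fixed),
    pool = {
      pass1 <- one_pass(NULL)
      conv <- dplyr::filter(pass1, .data$converged)
      if (nrow(conv) == 0L) {
        stop("No per-pulse fit converged in the free-E1 pass.", call. = FALSE)
      }
      one_pass(mean(conv$E1))
    }
  )
  if (any(!fits$converged)) {
    warning(sum(!fits$converged),
            " per-pulse fit(s) did not converge; flagged and excluded downstream.",
            call. = FALSE)
  }
  low_r2 <- sum(fits$converged & fits$r_squared < 0.85, na.rm = TRUE)
  if (low_r2 > 0) {
    warning(low_r2, " converged per-pulse fit(s) have R^2 < 0.85.",
            call. = FALSE)
  }
  class(fits) <- c("per_pulse_fits", class(fits))
  attr(fits, "alpha") <- alpha
  attr(fits, "T0") <- T0
  attr(fits, "E1_mode") <- E1_mode
  fits
}

#' Pooled baseline conductivity
#'
#' The baseline conductivity entering the pulse-number model is the
#' arithmetic mean of the per-pulse `sigma0` estimates over converged fits;
#' per-pulse baselines should not vary systematically with pulse number, so
#' pooling reduces their estimation noise.
#'
#' @param fits A [fit_per_pulse()] table.
#' @return Pooled baseline conductivity (S/m).
#' @export
pool_sigma0 <- function(fits) {
  stopifnot(is.data.frame(fits), all(c("sigma0", "converged") %in% names(fits)))
  conv <- fits$sigma0[fits$converged]
  if (length(conv) == 0L) {
    stop("No converged fits to pool `sigma0` over.", call. = FALSE)
  }
  mean(conv)
}
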