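# Fits of the pulse-number parameter functions A(N) and E0(N) to the
# per-pulse curve estimates. Both are bounded Levenberg-Marquardt nonlinear
# least squares; A(N) uses a deterministic multi-start grid because the
# (b1, c1) pair creates shallow valleys, E0(N) starts from a variable-
# projection solution (linear in a2, b2 given c2).

pulse_curve_fit <- function(fit, coef_names, r_squared, n, degenerate = FALSE,
                            boundary = FALSE, label) {
  est <- stats::setNames(fit$par, coef_names)
  p <- length(est)
  dof <- n - p
  se <- rep(NA_real_, p)
  s2 <- fit$deviance / max(dof, 1L)
  cov <- try(s2 * solve(fit$hessian), silent = TRUE)
  if (!inherits(cov, "try-error") && all(is.finite(diag(cov))) &&
      all(diag(cov) >= 0)) {
    se <- sqrt(diag(cov))
  } else {
    degenerate <- TRUE
  }
  tq <- stats::qt(0.975, max(dof, 1L))
  structure(
    list(
      coef = est, se = stats::setNames(se, coef_names),
      conf.low = est - tq * se, conf.high = est + tq * se,
      r_squared = r_squared, n = n, deviance = fit$deviance,
      converged = fit$info %in% 1:4 && !degenerate,
      degenerate = degenerate, boundary = boundary, label = label
    ),
    class = "pulse_curve_fit"
  )
}

#' @export
print.pulse_curve_fit <- function(x, ...) {
  cat(sprintf("<pulse_curve_fit> %s  (R^2 = %.4f, n = %d%s%s)\n",
              x$label, x$r_squared, x$n,
              if (x$degenerate) ", DEGENERATE" else "",
              if (x$boundary) ", boundary solution" else ""))
  print(tidy.pulse_curve_fit(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pulse_curve_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coef), estimate = unname(x$coef),
    std.error = unname(x$se),
    conf.low = unname(x$conf.low), conf.high = unname(x$conf.high)
  )
}

#' @exportS3Method generics::glance
glance.pulse_curve_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, deviance = x$deviance, nobs = x$n,
    converged = x$converged, degenerate = x$degenerate
  )
}

r_squared_of <- function(obs, dev) {
  ss <- sum((obs - mean(obs))^2)
  if (ss > 0) 1 - dev / ss else NA_real_
}

#' Fit the increase-factor sigmoid A(N)
#'
#' Fits `A(N) = a1 * (1 - (1 + N/b1)^(-c1))` to per-pulse increase-factor
#' estimates by bounded nonlinear least squares over a deterministic
#' multi-start grid (the `b1`/`c1` pair trades off along a shallow valley,
#' so a single start is unreliable). All three coefficients are constrained
#' positive. 95 % confidence intervals come from the linearised covariance
#' at the optimum. Inputs with (numerically) constant `A` are flagged as
#' degenerate -- `c1` is then unidentifiable.
#'
#' @param data A data frame with columns `N` (pulse number) and `A`.
#' @return A `pulse_curve_fit` with coefficients `a1`, `b1`, `c1`; supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
fit_A_vs_N <- function(data) {
  stopifnot(is.data.frame(data), all(c("N", "A") %in% names(data)))
  N <- data$N; A <- data$A
  if (length(N) < 10L) stop("Need >= 10 (N, A) points.", call. = FALSE)
  if (stats::sd(A) < 1e-10 * max(abs(A), 1)) {
    warning("`A` is constant in N; sigmoid coefficients are unidentifiable.",
            call. = FALSE)
    fit <- list(par = c(mean(A), 1, 1), deviance = sum((A - mean(A))^2),
                hessian = diag(3) * NA_real_, info = 1L)
    return(pulse_curve_fit(fit, c("a1", "b1", "c1"),
                           r_squared_of(A, fit$deviance), length(N),
                           degenerate = TRUE, label = "A(N) sigmoid"))
  }
  resid_fn <- function(p) A - p[1] * (1 - (1 + N / p[2])^(-p[3]))
  starts <- expand.grid(
    a1 = max(A) * c(1.02, 1.2),
    b1 = 10^c(-3.5, -2, -0.5, 1),
    c1 = c(0.1, 0.3, 1)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    cand <- try(minpack.lm::nls.lm(
      par = as.numeric(starts[i, ]), lower = rep(1e-8, 3),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                           ptol = 1e-14)
    ), silent = TRUE)
    if (inherits(cand, "try-error")) next
    if (is.null(best) || cand$deviance < best$deviance) best <- cand
  }
  if (is.null(best)) {
    stop("A(N) fit failed to converge from any start.", call. = FALSE)
  }
  pulse_curve_fit(best, c("a1", "b1", "c1"),
                  r_squared_of(A, best$deviance), length(N),
                  label = "A(N) sigmoid")
}

#' Fit the lower-turning-point decay E0(N)
#'
#' Fits `E0(N) = a2 / N + b2 * exp(-c2 * N)` to per-pulse lower-turning-
#' point estimates. The model is linear in `(a2, b2)` given `c2`, so the
#' starting point comes from variable projection (a 1-D search over `c2`
#' with a nonnegative linear solve inside), followed by a bounded
#' Levenberg-Marquardt polish with all coefficients constrained
#' nonnegative. A solution with `c2` at (numerically) zero is flagged as a
#' boundary solution -- the exponential term has degenerated to a constant.
#'
#' @param data A data frame with columns `N` and `E0` (V/m).
#' @return A `pulse_curve_fit` with coefficients `a2`, `b2`, `c2`.
#' @export
fit_E0_vs_N <- function(data) {
  stopifnot(is.data.frame(data), all(c("N", "E0") %in% names(data)))
  N <- data$N; E0 <- data$E0
  if (length(N) < 10L) stop("Need >= 10 (N, E0) points.", call. = FALSE)

  lin_solve <- function(c2) {
    X <- cbind(inv = 1 / N, ex = exp(-c2 * N))
    cf <- stats::coef(stats::lm.fit(X, E0))
    if (any(cf < 0)) {  # clamp to the nonnegative orthant
      cf_try <- lapply(1:2, function(j) {
        v <- c(0, 0)
        v[j] <- max(sum(X[, j] * E0) / sum(X[, j]^2), 0)
        v
      })
      dev <- vapply(cf_try, function(v) sum((E0 - X %*% v)^2), numeric(1))
      cf <- cf_try[[which.min(dev)]]
    }
    list(coef = cf, dev = sum((E0 - X %*% cf)^2))
  }
  # the projected SSE is multimodal in c2: scan a log-spaced grid first,
  # then refine locally around the best grid point
  c2_grid <- c(0, 10^seq(-4, log10(0.5), length.out = 60))
  dev_grid <- vapply(c2_grid, function(c2) lin_solve(c2)$dev, numeric(1))
  i_best <- which.min(dev_grid)
  lo <- c2_grid[max(i_best - 1L, 1L)]
  hi <- c2_grid[min(i_best + 1L, length(c2_grid))]
  opt <- stats::optimize(function(c2) lin_solve(c2)$dev,
                         interval = c(lo, hi), tol = 1e-12)
  if (opt$objective > dev_grid[i_best]) {
    opt <- list(minimum = c2_grid[i_best], objective = dev_grid[i_best])
  }
  st <- lin_solve(opt$minimum)
  resid_fn <- function(p) E0 - (p[1] / N + p[2] * exp(-p[3] * N))
  best <- minpack.lm::nls.lm(
    par = c(max(st$coef[1], 1e-8), max(st$coef[2], 1e-8),
            max(opt$minimum, 1e-10)),
    lower = rep(0, 3), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  boundary <- best$par[3] < 1e-8
  if (boundary) {
    warning("E0(N) fit hit the c2 = 0 boundary (exponential term constant).",
            call. = FALSE)
  }
  pulse_curve_fit(best, c("a2", "b2", "c2"),
                  r_squared_of(E0, best$deviance), length(N),
                  boundary = boundary, label = "E0(N) decay")
}

#' Assemble a pulse-number conductivity model from per-pulse fits
#'
#' The final modelling stage: pools the baseline conductivity, fits `A(N)`
#' and `E0(N)` to the converged per-pulse estimates, and assembles the
#' resulting [pulse_number_model()]. Non-converged per-pulse fits are
#' excluded from every stage.
#'
#' @param fits A [fit_per_pulse()] table.
#' @return An object of class `pulse_model_fit`: a list with the assembled
#'   `model`, the component `fit_A` and `fit_E0` curve fits, `sigma0_pooled`
#'   and `E1_const`. Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_pulse_number_model <- function(fits) {
  stopifnot(inherits(fits, "per_pulse_fits"))
  conv <- dplyr::filter(fits, .data$converged)
  sigma0 <- pool_sigma0(fits)
  fit_A <- fit_A_vs_N(dplyr::tibble(N = conv$pulse_index, A = conv$A))
  fit_E0 <- fit_E0_vs_N(dplyr::tibble(N = conv$pulse_index, E0 = conv$E0))
  E1_const <- mean(conv$E1)
  model <- pulse_number_model(
    a1 = fit_A$coef[["a1"]], b1 = fit_A$coef[["b1"]], c1 = fit_A$coef[["c1"]],
    a2 = max(fit_E0$coef[["a2"]], 0), b2 = max(fit_E0$coef[["b2"]], 0),
    c2 = max(fit_E0$coef[["c2"]], 0),
    E1_const = E1_const, sigma0 = sigma0,
    alpha = attr(fits, "alpha") %||% 0.02,
    T0 = attr(fits, "T0") %||% 24
  )
  structure(
    list(model = model, fit_A = fit_A, fit_E0 = fit_E0,
         sigma0_pooled = sigma0, E1_const = E1_const, per_pulse = fits),
    class = "pulse_model_fit"
  )
}

#' @export
print.pulse_model_fit <- function(x, ...) {
  cat("<pulse_model_fit>\n")
  cat(sprintf("  pooled sigma0 = %.4g S/m, E1 = %.4g V/m\n",
              x$sigma0_pooled, x$E1_const))
  cat(sprintf("  A(N):  R^2 = %.4f | E0(N): R^2 = %.4f\n",
              x$fit_A$r_squared, x$fit_E0$r_squared))
  print(x$model)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pulse_model_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy.pulse_curve_fit(x$fit_A), component = "A(N)"),
    dplyr::mutate(tidy.pulse_curve_fit(x$fit_E0), component = "E0(N)"),
    tibble::tibble(term = "sigma0", estimate = x$sigma0_pooled,
                   std.error = NA_real_, conf.low = NA_real_,
                   conf.high = NA_real_, component = "pooled"),
    tibble::tibble(term = "E1_const", estimate = x$E1_const,
                   std.error = NA_real_, conf.low = NA_real_,
                   conf.high = NA_real_, component = "pooled")
  )
}

#' @exportS3Method generics::glance
glance.pulse_model_fit <- function(x, ...) {
  tibble::tibble(
    sigma0_pooled = x$sigma0_pooled, E1_const = x$E1_const,
    r.squared.A = x$fit_A$r_squared, r.squared.E0 = x$fit_E0$r_squared,
    min.r.squared.per.pulse = min(x$per_pulse$r_squared[x$per_pulse$converged]),
    n_pulses = nrow(x$per_pulse),
    n_converged = sum(x$per_pulse$converged)
  )
}
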