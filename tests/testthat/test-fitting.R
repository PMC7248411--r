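make_obs <- function(params, E_cm = training_magnitudes(), T = 24,
                     variant = "additive") {
  E <- E_cm * 100
  tibble::tibble(
    E_V_per_m = E,
    sigma_S_per_m = conductivity(E, T, params, variant),
    T_C = T
  )
}

test_that("noiseless curves are recovered to optimizer precision", {
  p <- heaviside_params(sigma0 = 0.137, A = 2.1, E0 = 3.2e4, E1 = 8e4)
  fit <- fit_heaviside_curve(make_obs(p))
  expect_true(fit$converged)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$params$sigma0, 0.137, tolerance = 1e-6)
  expect_equal(fit$params$A, 2.1, tolerance = 1e-6)
  expect_equal(fit$params$E0, 3.2e4, tolerance = 1e-4)
  expect_equal(fit$params$E1, 8e4, tolerance = 1e-4)
  # fixing E1 to truth recovers the remaining parameters too
  fit2 <- fit_heaviside_curve(make_obs(p), E1 = 8e4)
  expect_equal(fit2$params$E0, 3.2e4, tolerance = 1e-6)
})

test_that("unporated tissue fits to A at its lower bound", {
  p <- heaviside_params(sigma0 = 0.15, A = 0, E0 = 3e4, E1 = 8e4)
  obs <- make_obs(p)
  fit <- fit_heaviside_curve(obs, E1 = 8e4)
  expect_lt(fit$params$A, 1e-8)
  expect_equal(fit$params$sigma0, 0.15, tolerance = 1e-8)
})

test_that("too few distinct magnitudes is an error", {
  p <- heaviside_params(sigma0 = 0.137, A = 2, E0 = 3e4, E1 = 8e4)
  expect_error(fit_heaviside_curve(make_obs(p, E_cm = c(100, 400, 800, 2000))),
               "5 distinct")
})

test_that("pooled sigma0 averages converged per-pulse baselines", {
  fits <- tibble::tibble(sigma0 = c(0.13, 0.14, 9), converged = c(TRUE, TRUE, FALSE))
  expect_equal(pool_sigma0(fits), 0.135)
  expect_equal(pool_sigma0(tibble::tibble(sigma0 = rep(0.2, 4),
                                          converged = TRUE)), 0.2)
  expect_error(pool_sigma0(tibble::tibble(sigma0 = 1, converged = FALSE)),
               "No converged")
})

test_that("A(N) refit recovers the reference coefficients from noiseless samples", {
  m <- truth_model()
  fit <- fit_A_vs_N(data.frame(N = 1:90, A = increase_factor(1:90, m)))
  expect_true(fit$converged)
  expect_equal(fit$coef[["a1"]], 2.3919, tolerance = 1e-3)
  expect_equal(fit$coef[["b1"]], 0.0018, tolerance = 1e-3)
  expect_equal(fit$coef[["c1"]], 0.2802, tolerance = 1e-3)
  expect_error(fit_A_vs_N(data.frame(N = 1:5, A = 1:5)), ">= 10")
})

test_that("constant A input is flagged as degenerate", {
  expect_warning(fit <- fit_A_vs_N(data.frame(N = 1:30, A = rep(1.5, 30))),
                 "unidentifiable")
  expect_true(fit$degenerate)
  expect_false(fit$converged)
})

test_that("E0(N) refit recovers the reference coefficients and is monotone", {
  m <- truth_model()
  fit <- fit_E0_vs_N(data.frame(N = 1:90, E0 = lower_turning_point(1:90, m)))
  expect_true(fit$converged)
  expect_equal(fit$coef[["a2"]], 8086.1, tolerance = 1e-3)
  expect_equal(fit$coef[["b2"]], 29056, tolerance = 1e-3)
  expect_equal(fit$coef[["c2"]], 0.0027, tolerance = 1e-3)
  # analytic derivative of the fitted curve is negative over N in [1, 90]
  N <- seq(1, 90, by = 0.5)
  a2 <- fit$coef[["a2"]]; b2 <- fit$coef[["b2"]]; c2 <- fit$coef[["c2"]]
  deriv <- -a2 / N^2 - b2 * c2 * exp(-c2 * N)
  expect_true(all(deriv < 0))
})

test_that("constant E0 input collapses to a boundary solution", {
  expect_warning(fit <- fit_E0_vs_N(data.frame(N = 1:30, E0 = rep(3e4, 30))),
                 "boundary")
  expect_true(fit$boundary)
  expect_equal(fit$coef[["b2"]], 3e4, tolerance = 0.05)
})

test_that("noiseless end-to-end fitting recovers the ground truth", {
  m <- truth_model()
  geom <- sample_geometry()
  d <- generate_dataset(m, protocol_config(replicates = 1), geom,
                        noise = 0, seed = 1)
  obs <- extract_conductivity(d, geom)
  pp <- fit_per_pulse(obs)
  expect_s3_class(pp, "per_pulse_fits")
  expect_equal(nrow(pp), 90)
  expect_true(all(pp$converged))
  expect_true(all(pp$r_squared > 0.999))
  expect_equal(pool_sigma0(pp), 0.137, tolerance = 0.02)
  mf <- fit_pulse_number_model(pp)
  expect_equal(mf$fit_A$coef[["a1"]], 2.3919, tolerance = 0.02)
  expect_equal(mf$fit_E0$coef[["a2"]], 8086.1, tolerance = 0.05)
  expect_equal(mf$E1_const, 8e4, tolerance = 0.02)
  # coefficient estimates respect the printed sign constraints
  expect_true(all(unlist(mf$fit_A$coef) > 0))
  expect_true(all(unlist(mf$fit_E0$coef) >= 0))
  # tidy/glance interfaces
  td <- tidy(mf)
  expect_true(all(c("term", "estimate", "component") %in% names(td)))
  expect_true(glance(mf)$min.r.squared.per.pulse > 0.99)
})

test_that("confidence intervals of the sigmoid fit exclude zero under noise", {
  m <- truth_model()
  geom <- sample_geometry()
  d <- generate_dataset(m, protocol_config(), geom, noise = 0.03, seed = 42)
  pp <- fit_per_pulse(extract_conductivity(d, geom))
  mf <- fit_pulse_number_model(pp)
  td <- tidy(mf$fit_A)
  expect_gt(td$conf.low[td$term == "a1"], 0)
})
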