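test_that("increase factor has the published limits and values", {
  m <- truth_model()
  expect_equal(increase_factor(0, m), 0)
  expect_equal(increase_factor(1e40, m), 2.3919, tolerance = 1e-9)
  # frozen scalar evaluation at the first pulse (independent calculator)
  expect_equal(increase_factor(1, m), 1.9850339, tolerance = 1e-6)
  # strictly increasing
  A <- increase_factor(seq(0, 200, by = 0.5), m)
  expect_true(all(diff(A) > 0))
  expect_error(increase_factor(-1, m), ">= 0")
})

test_that("lower turning point decays from its first-pulse value toward zero", {
  m <- truth_model()
  expect_equal(lower_turning_point(1, m), 37063.755, tolerance = 1e-6)
  expect_lt(lower_turning_point(1e9, m), 1e-3)
  expect_identical(lower_turning_point(0, m), Inf)
  expect_error(lower_turning_point(-2, m), ">= 0")
  N <- 1:200
  expect_true(all(diff(lower_turning_point(N, m)) < 0))
})

test_that("conductivity reproduces baseline, midpoint and saturation", {
  p <- heaviside_params(sigma0 = 0.137, A = 2.3919, E0 = 3.7e4, E1 = 8e4)
  expect_equal(conductivity(0, 24, p), 0.137)
  # saturated plateau sigma0 * (1 + A) = 0.465 S/m to 3 s.f.
  expect_equal(round(conductivity(2.5e5, 24, p), 3), 0.465)
  # midpoint of the transition zone carries half the increase factor
  expect_equal(conductivity(p$E_del, 24, p), 0.137 * (1 + 2.3919 / 2))
  expect_error(conductivity(-1, 24, p), ">= 0")
})

test_that("temperature-coupling variants agree when the temperature term vanishes", {
  withr::local_seed(11)
  for (i in 1:20) {
    m <- random_model()
    p <- params_at_pulse(m, sample(1:90, 1))
    E <- runif(5, 0, 2.5e5)
    expect_equal(conductivity(E, p$T0, p, "additive"),
                 conductivity(E, p$T0, p, "multiplicative"))
    p0 <- heaviside_params(p$sigma0, p$A, p$E0, p$E1, alpha = 0, T0 = p$T0)
    Thot <- p$T0 + runif(1, 0, 20)
    expect_equal(conductivity(E, Thot, p0, "additive"),
                 conductivity(E, Thot, p0, "multiplicative"))
  }
})

test_that("conductivity with A = 0 and alpha = 0 is flat at sigma0", {
  p <- heaviside_params(sigma0 = 0.2, A = 0, E0 = 1e4, E1 = 5e4, alpha = 0)
  E <- seq(0, 3e5, length.out = 50)
  expect_equal(conductivity(E, 60, p), rep(0.2, 50))
})

test_that("conductivity is nondecreasing in E, T and pulse number", {
  withr::local_seed(42)
  for (i in 1:20) {
    m <- random_model()
    E <- seq(0, 3e5, length.out = 100)
    sig_E <- conductivity_multi_pulse(E, 5, 30, m)
    expect_true(all(diff(sig_E) >= 0))
    Tseq <- seq(24, 50, length.out = 30)
    sig_T <- conductivity_multi_pulse(1e5, 5, Tseq, m)
    expect_true(all(diff(sig_T) >= 0))
    N <- 1:90
    sig_N <- conductivity_multi_pulse(1e5, N, 30, m)
    expect_true(all(diff(sig_N) >= -1e-12))
  }
})

test_that("multi-pulse model at N = 1 equals the conventional view", {
  m <- truth_model()
  conv <- clamp_conventional(m)
  E <- seq(0, 3e5, length.out = 30)
  expect_equal(conductivity_multi_pulse(E, 1, 30, m),
               conductivity_multi_pulse(E, 57, 30, conv))
  # clamped view is constant in N
  expect_equal(increase_factor(c(1, 20, 90), conv),
               rep(increase_factor(1, m), 3))
  expect_equal(lower_turning_point(c(1, 20, 90), conv),
               rep(lower_turning_point(1, m), 3))
})

test_that("composed multi-pulse conductivity matches the frozen chain evaluation", {
  # sigma(E = 2.5e5 V/m, N = 90, T = T0) with the reference coefficients and
  # E1 = 8e4 V/m, chained through A(N), E0(N) and the step by an
  # independent scalar oracle
  m <- truth_model()
  expect_equal(conductivity_multi_pulse(2.5e5, 90, 24, m), 0.44888474,
               tolerance = 1e-7)
  expect_equal(conductivity_multi_pulse(0, 90, 24, m), m$sigma0)
})

test_that("parameter constructors enforce their invariants", {
  expect_error(heaviside_params(-0.1, 1, 1e4, 5e4), "positive")
  expect_error(heaviside_params(0.1, -1, 1e4, 5e4), ">= 0")
  expect_error(heaviside_params(0.1, 1, 5e4, 5e4), "E0 < E1")
  p <- heaviside_params(0.137, 2, 2e4, 6e4)
  expect_identical(p$E_del - p$E_range, p$E0)
  expect_identical(p$E_del + p$E_range, p$E1)
  expect_error(pulse_number_model(0, 1, 1, 1, 1, 1, 1e5, 0.1), "> 0")
  expect_error(pulse_number_model(1, 1, 1, -1, 1, 1, 1e5, 0.1), ">= 0")
})
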