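test_that("thermal step reproduces adiabatic heating and relaxation limits", {
  geom <- sample_geometry()
  prot <- protocol_config()
  # frozen duty-scaled adiabatic rise: sigma E^2 d / (rho c_p)
  dT <- thermal_step(30, 0.465, 2.5e5, geom, prot, heat_loss = 0) - 30
  expect_equal(dT, 0.7608662, tolerance = 1e-6)
  # no field: pure relaxation toward ambient
  expect_equal(thermal_step(30, 0.137, 0, geom, prot, heat_loss = 0.1),
               30 - 0.1 * (30 - 24))
  expect_equal(thermal_step(24, 0.137, 0, geom, prot, heat_loss = 0.1), 24)
  # constant source, no loss: linear rise with pulse number
  temps <- Reduce(function(T, i) thermal_step(T, 0.3, 1e5, geom, prot, 0),
                  1:5, accumulate = TRUE, init = 24)
  expect_equal(diff(temps), rep(diff(temps)[1], 5))
  expect_error(thermal_step(24, 0.1, 1e4, geom, prot, heat_loss = -1), ">= 0")
})

test_that("fixed seed gives a bit-identical dataset", {
  m <- truth_model()
  d1 <- generate_dataset(m, small_protocol(), noise = 0.05, seed = 99)
  d2 <- generate_dataset(m, small_protocol(), noise = 0.05, seed = 99)
  expect_identical(d1, d2)
  d3 <- generate_dataset(m, small_protocol(), noise = 0.05, seed = 100)
  expect_false(identical(d1$I_avg_A, d3$I_avg_A))
})

test_that("noiseless generation inverts exactly through extraction", {
  m <- truth_model()
  geom <- sample_geometry()
  prot <- small_protocol(n_pulses = 20, magnitudes = c(200, 800, 2500))
  d <- generate_dataset(m, prot, geom, noise = 0, heat_loss = 0.06, seed = 1)
  obs <- extract_conductivity(d, geom)
  sigma_truth <- conductivity_multi_pulse(
    E = obs$E_V_per_m, N = obs$pulse_index, T = obs$T_C, model = m
  )
  expect_equal(obs$sigma_S_per_m, sigma_truth, tolerance = 1e-14)
})

test_that("isothermal low-field single pulse delivers sigma0 * E * S", {
  m <- truth_model()
  geom <- sample_geometry()
  prot <- small_protocol(n_pulses = 1, magnitudes = 100)  # E = 1e4 < E0(1)
  d <- generate_dataset(m, prot, geom, noise = 0, seed = 1)
  E <- d$U_avg_V / geom$L
  expect_equal(d$I_avg_A, m$sigma0 * E * geom$S)
  expect_equal(d$T_C, 24)
})

test_that("per-pulse currents increase with pulse number at high field", {
  m <- truth_model()
  prot <- small_protocol(n_pulses = 90, magnitudes = 2500)
  d <- generate_dataset(m, prot, noise = 0, seed = 1)
  expect_true(all(diff(d$I_avg_A) > 0))
})

test_that("temperature traces are bounded below and monotone without loss", {
  m <- truth_model()
  prot <- small_protocol(n_pulses = 60, magnitudes = c(500, 2500))
  d0 <- generate_dataset(m, prot, noise = 0, heat_loss = 0, seed = 1)
  expect_true(all(d0$T_C >= 24))
  for (mag in unique(d0$magnitude_V_per_cm)) {
    expect_true(all(diff(d0$T_C[d0$magnitude_V_per_cm == mag]) >= 0))
  }
  d1 <- generate_dataset(m, prot, noise = 0, heat_loss = 0.06, seed = 1)
  expect_true(all(d1$T_C >= 24))
})

test_that("synthesised waveforms preserve the end-of-pulse averages", {
  tr <- synthesize_waveform(1000, 2.157, spike_amplitude = 0)
  top <- tr[tr$t_s >= 2e-6, ]
  expect_true(all(top$V == 1000) && all(top$A == 2.157))
  avg <- average_last_window(tr)
  expect_equal(avg$U_avg_V, 1000)
  expect_equal(avg$I_avg_A, 2.157)
  # a capacitive onset spike leaves the last-4-us means untouched
  tr_spike <- synthesize_waveform(1000, 2.157, spike_amplitude = 50)
  avg_spike <- average_last_window(tr_spike)
  expect_equal(avg_spike$I_avg_A, avg$I_avg_A)
  expect_gt(max(tr_spike$A), 40)
  expect_error(synthesize_waveform(1000, 2, sample_rate = 1e6), "8 samples")
})
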