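test_that("end-of-pulse averaging handles constant, ramp and synthetic traces", {
  t <- seq(0, 1e-4, by = 1e-8)
  const <- tibble::tibble(t_s = t, V = 500, A = 1.2)
  avg <- average_last_window(const)
  expect_equal(avg$U_avg_V, 500)
  expect_equal(avg$I_avg_A, 1.2)
  # linear ramp over the window averages to the window midpoint value
  ramp <- tibble::tibble(t_s = t, V = t * 1e7, A = t * 1e4)
  avg_r <- average_last_window(ramp)
  expect_equal(avg_r$U_avg_V, (1e-4 - 2e-6) * 1e7, tolerance = 1e-6)
  expect_equal(avg_r$I_avg_A, (1e-4 - 2e-6) * 1e4, tolerance = 1e-6)
  # round trip through the waveform synthesiser to 6 s.f.
  tr <- synthesize_waveform(1234.5, 3.21, spike_amplitude = 10)
  avg_s <- average_last_window(tr)
  expect_equal(avg_s$U_avg_V, 1234.5, tolerance = 1e-6)
  expect_equal(avg_s$I_avg_A, 3.21, tolerance = 1e-6)
  expect_error(average_last_window(const[1:2, ], window = 1e-12), "2 samples")
})

test_that("shape-factor conversion matches hand arithmetic and is scale-free", {
  geom <- sample_geometry()
  out <- conductivity_from_record(1000, 2.157, geom)
  expect_equal(out$sigma_S_per_m, 0.1373189, tolerance = 1e-6)
  expect_equal(out$E_V_per_m, 1000 / 5e-3)
  # doubling both channels leaves sigma unchanged
  out2 <- conductivity_from_record(2000, 4.314, geom)
  expect_equal(out2$sigma_S_per_m, out$sigma_S_per_m)
  expect_error(conductivity_from_record(0, 1, geom), "positive")
  expect_error(conductivity_from_record(-5, 1, geom), "positive")
})

test_that("sigma scales linearly in I and inversely in U", {
  geom <- sample_geometry()
  base <- conductivity_from_record(800, 1.5, geom)$sigma_S_per_m
  expect_equal(conductivity_from_record(800, 3.0, geom)$sigma_S_per_m, 2 * base)
  expect_equal(conductivity_from_record(1600, 1.5, geom)$sigma_S_per_m, base / 2)
  # dimensional consistency: a geometry with doubled L and quadrupled S
  # leaves sigma unchanged for the same U, I up to the shape factor ratio
  geom2 <- sample_geometry(L = 1e-2, diameter = 2e-2, mold_diameter = 4e-2)
  expect_equal(conductivity_from_record(800, 1.5, geom2)$sigma_S_per_m,
               base / 2)
})

test_that("failed pulses are dropped with a warning, not interpolated", {
  m <- truth_model()
  geom <- sample_geometry()
  d <- generate_dataset(m, small_protocol(), geom, noise = 0, seed = 1)
  d$I_avg_A[3] <- 0
  d$U_avg_V[7] <- -1
  expect_warning(obs <- extract_conductivity(d, geom), "2 failed pulse")
  expect_equal(nrow(obs), nrow(d) - 2L)
  expect_error(extract_conductivity(d[, 1:3], geom), "lacks columns")
})
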