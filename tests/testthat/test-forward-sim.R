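test_that("multi-pulse and conventional lumped simulations coincide at pulse 1", {
  m <- truth_model()
  prot <- small_protocol(n_pulses = 30, magnitudes = 1500)
  s_multi <- simulate_lumped(m, 750, protocol = prot, mode = "multi_pulse")
  s_conv <- simulate_lumped(m, 750, protocol = prot, mode = "conventional")
  expect_equal(s_multi$I_A[1], s_conv$I_A[1])
  # under heating the conventional current grows strictly slower
  expect_true(all(s_multi$I_A[-1] > s_conv$I_A[-1]))
})

test_that("conventional mode with alpha = 0 is constant across pulses", {
  m <- truth_model()
  m$alpha <- 0
  s <- simulate_lumped(m, 1250, protocol = small_protocol(n_pulses = 20,
                                                          magnitudes = 2500),
                       mode = "conventional")
  expect_equal(s$I_A, rep(s$I_A[1], 20))
})

test_that("multi-pulse lumped current sequence is nondecreasing", {
  withr::local_seed(5)
  for (i in 1:5) {
    m <- random_model()
    s <- simulate_lumped(m, 1000, protocol = small_protocol(n_pulses = 40,
                                                            magnitudes = 2000))
    expect_true(all(diff(s$I_A) >= -1e-12))
  }
})

test_that("lumped energy bookkeeping is exact without heat loss", {
  m <- truth_model()
  geom <- sample_geometry()
  prot <- small_protocol(n_pulses = 25, magnitudes = 2500)
  s <- simulate_lumped(m, 1250, geom, prot, heat_loss = 0)
  E <- 1250 / geom$L
  duty <- prot$pulse_width / prot$period
  rises <- s$sigma_S_per_m * E^2 * duty / (geom$rho * geom$c_p)
  expect_equal(s$T_C, 24 + cumsum(c(0, rises[-length(rises)])))
})

test_that("uniform-conductivity grid solve matches the closed form", {
  m0 <- pulse_number_model(a1 = 1e-9, b1 = 1, c1 = 1, a2 = 8086.1,
                           b2 = 29056, c2 = 0.0027, E1_const = 8e4,
                           sigma0 = 0.137, alpha = 0, T0 = 24)
  geom <- sample_geometry()
  prot <- small_protocol(n_pulses = 2, magnitudes = 2500)
  s <- simulate_axisymmetric(m0, 1250, geom, prot)
  closed <- 0.137 * (1250 / geom$L) * geom$S
  expect_equal(s$I_A[1], closed, tolerance = 0.01)
  # Picard is a no-op when sigma does not depend on the field
  expect_true(all(attr(s, "picard_iters") == 1L))
})

test_that("mid-plane current equals the current through every other plane", {
  m <- truth_model()
  prot <- small_protocol(n_pulses = 3, magnitudes = 2500)
  s <- simulate_axisymmetric(m, 1250, protocol = prot, thermal = "conduction")
  pc <- attr(s, "plane_currents")
  spread <- apply(pc, 1, function(row) diff(range(row)) / mean(row))
  expect_true(all(spread < 1e-8))
})

test_that("grid and lumped solvers agree on the plate geometry", {
  m <- truth_model()
  geom <- sample_geometry()
  prot <- small_protocol(n_pulses = 15, magnitudes = 2500)
  s_grid <- simulate_axisymmetric(m, 1250, geom, prot, thermal = "lumped")
  s_lump <- simulate_lumped(m, 1250, geom, prot)
  expect_true(all(abs(s_grid$I_A - s_lump$I_A) / s_lump$I_A < 0.02))
})

test_that("halving the cell size changes the current by < 0.5 %", {
  m <- truth_model()
  prot <- small_protocol(n_pulses = 2, magnitudes = 1500)
  s_c <- simulate_axisymmetric(m, 750, protocol = prot, nr_tissue = 20, nz = 10)
  s_f <- simulate_axisymmetric(m, 750, protocol = prot, nr_tissue = 40, nz = 20)
  expect_true(all(abs(s_f$I_A - s_c$I_A) / s_c$I_A < 0.005))
})

test_that("conduction thermal mode heats the tissue and stays above ambient", {
  m <- truth_model()
  prot <- small_protocol(n_pulses = 8, magnitudes = 2500)
  s <- simulate_axisymmetric(m, 1250, protocol = prot, thermal = "conduction")
  expect_true(all(diff(s$T_C) > 0))
  expect_true(all(s$T_C >= 24))
})

test_that("solver input validation catches bad grids", {
  m <- truth_model()
  expect_error(simulate_axisymmetric(m, 1250, nr_tissue = 10), ">= 20")
  expect_error(simulate_axisymmetric(m, 1250, nz = 7), "even")
})
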