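# Shared fixtures: the reference liver truth model and small protocols used
# across test files. Everything is generated in code at test time.

truth_model <- function(...) liver_multipulse_model(...)

small_protocol <- function(n_pulses = 10L, magnitudes = c(400, 800, 2000),
                           replicates = 1L) {
  protocol_config(n_pulses = n_pulses, field_magnitudes = magnitudes,
                  replicates = replicates)
}

# random valid pulse-number models for property-style tests
random_model <- function() {
  pulse_number_model(
    a1 = stats::runif(1, 0.5, 4),
    b1 = 10^stats::runif(1, -3, 0),
    c1 = stats::runif(1, 0.1, 2),
    a2 = stats::runif(1, 1e3, 2e4),
    b2 = stats::runif(1, 5e3, 5e4),
    c2 = stats::runif(1, 0, 0.05),
    E1_const = stats::runif(1, 7.5e4, 2e5),
    sigma0 = stats::runif(1, 0.05, 0.5),
    alpha = stats::runif(1, 0, 0.03),
    T0 = 24
  )
}
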