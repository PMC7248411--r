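# pulsecond

Multi-pulse dynamic conductivity modelling for tissue treated with pulsed
electric fields.

## The problem

Irreversible electroporation (IRE) and related therapies deliver dozens of
~100 µs high-field pulses to tissue. Each pulse permeabilises cell
membranes, which raises the bulk electrical conductivity; the raised
conductivity redistributes the electric field, which is exactly the
quantity treatment-planning models need. Conventional planning models
characterise the conductivity from the **first pulse only** — σ(E, T) — and
attribute everything that happens later to Joule heating. That misses the
cumulative, saturating electroporation effect that dominates the first few
dozen pulses.

`pulsecond` implements the multi-pulse alternative for users who analyse
plate-electrode treatment recordings or build pulse-train simulators: a
conductivity model in which the pulse number N is a first-class argument,

```
σ(E, N, T) = σ₀ · (1 + A(N) · flc2hs(E − E_del(N), E_range(N)) + α·(T − T₀))
```

where `flc2hs` is the smoothed Heaviside step with a continuous second
derivative (a quintic ramp from 0 to 1 across the transition zone
`[E₀, E₁]`), and the curve parameters evolve with pulse number:

```
A(N)  = a₁ · (1 − (1 + N/b₁)^(−c₁))          # increase factor, saturates at a₁
E₀(N) = a₂/N + b₂·exp(−c₂·N)                 # lower turning point, decays to 0
```

`A(0) = 0` (untreated tissue), and the fully porated plateau is
`σ₀ · (1 + a₁)`. For the reference rabbit-liver parameter set shipped with
the package (σ₀ = 0.137 S/m, a₁ = 2.3919) that plateau is 0.465 S/m. The
temperature coefficient α is 2 %/°C with the additive coupling above; a
multiplicative variant is available.

The package covers the full workflow:

- **Synthetic recordings** — `generate_dataset()` emulates the
  characterisation protocol (90 pulses at 1 Hz, 100 µs width, training
  fields 100–2,800 V/cm, 3 replicates) from a ground-truth model plus a
  lumped electro-thermal plant with configurable current noise, so the
  entire pipeline is testable end to end without experimental data.
  `synthesize_waveform()` emits raw 100 µs traces for the averaging path.
- **Extraction** — `average_last_window()` (end-of-pulse last-4 µs
  averaging that excludes the capacitive transient) and
  `extract_conductivity()` (shape-factor conversion σ = I·L/(U·S) for the
  uniform-field plate geometry).
- **Fitting** — `fit_per_pulse()` fits the smoothed-Heaviside curve across
  magnitudes at every pulse number (bounded Levenberg–Marquardt,
  deterministic starts), `pool_sigma0()` averages the per-pulse baselines,
  and `fit_pulse_number_model()` fits A(N) and E₀(N) with multi-start
  searches, R² and linearised 95 % confidence intervals.
- **Simulation** — `simulate_lumped()` (exact for plate geometry) and
  `simulate_axisymmetric()` (2D finite-volume Laplace/bioheat solver with
  Picard iteration for the field-dependent conductivity and a mid-plane
  current integral) both support the `conventional` mode that clamps N = 1.
- **Validation** — `rmse()`, `relative_errors()`, `compare_models()` and
  `run_pipeline()` score the multi-pulse model against the conventional one
  and write all artifacts (CSV tables, model JSON, markdown report).

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects
support `tidy()`/`glance()` and result tables have `autoplot()` methods.

## Worked example

```r
library(pulsecond)

model <- liver_multipulse_model()   # reference rabbit-liver parameter set
geom  <- sample_geometry()          # Ø 1 cm x 5 mm cylinder, liver constants

# synthetic treatment recordings: 11 training magnitudes x 90 pulses x 3
# replicates, 3 % current noise
recordings <- generate_dataset(model, protocol_config(), geom,
                               noise = 0.03, seed = 42)
obs       <- extract_conductivity(recordings, geom)
fits      <- fit_per_pulse(obs)
model_fit <- fit_pulse_number_model(fits)
model_fit
#> <pulse_model_fit>
#>   pooled sigma0 = 0.1371 S/m, E1 = 7.946e+04 V/m
#>   A(N):  R^2 = 0.6152 | E0(N): R^2 = 0.9010
#> <pulse_number_model>
#>   A(N)  = 2.924 * (1 - (1 + N/3.25e-06)^-0.08948)
#>   E0(N) = 6994 / N + 3.003e+04 * exp(-0.002911 N)  [V/m]
#>   E1 = 7.946e+04 V/m, sigma0 = 0.1371 S/m, alpha = 0.02 /degC, T0 = 24 degC
```

The pooled baseline conductivity (0.1371 S/m) is recovered to 0.1 % of the
ground truth (0.137 S/m) despite 3 % current noise, and every one of the 90
per-pulse curve fits keeps R² above 0.98:

```r
glance(model_fit)
#> # A tibble: 1 x 7
#>   sigma0_pooled E1_const r.squared.A r.squared.E0 min.r.squared.per.pulse ...
#> 1         0.137   79461.       0.615        0.901                   0.988
```

Simulating a 90-pulse treatment at 2,500 V/cm (1,250 V across the 5 mm
sample) with the fitted model shows the current rising from 8.0 A toward
saturation as electroporation accumulates and the sample warms:

```r
simulate_lumped(model_fit$model, applied_voltage = 1250, geom,
                protocol_config(n_pulses = 90, field_magnitudes = 2500))
#> # A tibble: 90 x 4
#>    pulse_index   I_A   T_C sigma_S_per_m
#>  1           1  8.02  24           0.408
#>  2           2  8.21  24.7         0.418
#>  3           3  8.33  25.3         0.424
#>  ...
```

`run_pipeline(seed = 1, out_dir = "run")` executes the whole chain —
generate, extract, fit, simulate the four validation magnitudes in both
model modes, compare — and writes the artifacts; on synthetic data the
multi-pulse model beats the conventional one (lower RMSE against the
observed currents) at every validation magnitude.

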