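---
title: "Multi-pulse dynamic conductivity: model, fitting and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-pulse dynamic conductivity: model, fitting and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsecond)
```

## The model

Trains of ~100 µs pulsed electric fields porate cell membranes and raise
bulk tissue conductivity. `pulsecond` models the end-of-pulse conductivity
of a plate-electrode tissue sample as a function of field magnitude `E`,
pulse number `N` and temperature `T`:

σ(E, N, T) = σ₀ · (1 + A(N) · flc2hs(E − E_del(N), E_range(N)) + α·(T − T₀))

The three terms are the intrinsic tissue conductivity (σ₀), the
electroporation contribution (σ₀·A·flc2hs), and the thermal contribution
(σ₀·α·(T − T₀)). The electroporation term ramps from 0 to σ₀·A across a
transition zone bounded by the turning points E₀ (conductivity starts to
rise) and E₁ (the rise saturates); internally the step is centred at
E_del = (E₀+E₁)/2 with half-width E_range = (E₁−E₀)/2, but the package
parameterises fits by (E₀, E₁) because those are the quantities with a
physical reading and the ones modelled against pulse number.

Pulse-number dependence enters through two fitted functions:

- `A(N) = a₁(1 − (1 + N/b₁)^(−c₁))`, a₁,b₁,c₁ > 0 — a symmetric sigmoid in
  log N with A(0) = 0 and asymptote a₁. This algebraic form is the unique
  reading of the printed expression consistent with both limits (zero
  before treatment, saturation at a₁); the reference liver coefficients
  give a₁ = 2.3919 and a saturated conductivity σ₀(1+a₁) = 0.465 S/m.
- `E₀(N) = a₂/N + b₂·e^(−c₂N)`, a₂,b₂,c₂ ≥ 0 — decreasing for N ≥ 1 with
  limit 0: accumulated poration lets ever-lower fields re-porate the
  tissue. The reciprocal term diverges at N = 0, which the package reports
  as a documented `Inf` (no pulse applied, no finite onset field) rather
  than an overflow.

The upper turning point E₁ is treated as constant across pulse number: its
per-pulse estimates vary by less than ~5 %, so the default fitting mode
("pool") first frees E₁ per pulse and then refits all pulses with E₁ fixed
to the mean of the converged first-pass estimates. **E₁ has no published
reference value**; the shipped default of 8.0×10⁴ V/m (800 V/cm) for the
synthetic ground truth is this package's assumption, chosen to sit inside
the characterised field range, and is flagged as such wherever it appears.

Setting N = 1 recovers the *conventional* model σ(E, T) used by existing
planning workflows (`clamp_conventional()`); all conductivity growth over
the train is then attributed to Joule heating.

### The smoothed step

`flc2hs(x, r)` is the Heaviside step smoothed over `[−r, r]` with a
continuous second derivative. The interior is the odd quintic
`0.5 + 0.9375t − 0.625t³ + 0.1875t⁵` in `t = x/r`: the six conditions
(value, first and second derivative matching the clamped constants at both
endpoints) determine a quintic uniquely, and oddness about the midpoint
reduces them to a 3×3 linear system whose solution is the coefficient set
above (re-derived independently in the test suite). This is the standard
definition of this function in finite-element software. C² continuity
matters because the fitted curve's second derivative participates in the
Jacobians of the nonlinear solver.

### Temperature coupling

Two variants are implemented. The default *additive* form references the
thermal term to the baseline conductivity σ₀; the *multiplicative* form
(`σ₀(1 + A·flc2hs)(1 + α(T−T₀))`) references it to the electroporated
conductivity. They coincide when α = 0 or T = T₀ (a property test). The
additive form underestimates the thermal contribution at high A and
therefore folds part of it into A; the multiplicative form does the
opposite. The additive form is the default because it keeps A's trend
interpretable as a cumulative electroporation effect. α defaults to
0.02 /°C (soft-tissue literature value, reported range 1–3 %/°C) and
T₀ = 24 °C; both are fixed inputs to the fits, not free parameters —
with only one temperature trajectory per magnitude, α and A are not
separately identifiable.

## The synthetic-data generator

`generate_dataset()` emulates the characterisation experiment so the whole
pipeline can be exercised and validated by parameter recovery:

- **Protocol** — 90 pulses, 100 µs width, 1 s period; training magnitudes
  {100, 200, 400, 600, 800, 1,200, 1,400, 1,600, 1,800, 2,000, 2,800} V/cm
  and validation magnitudes {500, 1,000, 1,500, 2,500} V/cm; 3 replicates
  per magnitude.
- **Plant** — the plate geometry makes the field uniform (E = U/L, Ø 1 cm ×
  5 mm sample), so recordings follow from the truth model and a lumped
  thermal state: each pulse draws I = σ(E, N, T)·E·S, and the temperature
  advances by `thermal_step()` — duty-scaled adiabatic Joule heating
  σE²(d/τ)/(ρc_p) minus a Newton-type loss toward ambient. Liver constants
  ρ = 1,079 kg/m³, c_p = 3,540 J/kg/K, k = 0.52 W/m/K.
- **Noise** — multiplicative Gaussian noise on the current channel only
  (the voltage is a set-point), default relative s.d. 3 %. There is no
  published noise characterisation for such recordings; 3 % is this
  package's convention, set once as a plausible oscilloscope/current-probe
  figure for this signal range.
- **Heat loss** — the lumped loss rate defaults to 0.06 /s, set once so
  that 90 pulses at the top validation magnitude (2,500 V/cm) give a
  terminal rise of order 10 °C (steady state ≈ 0.76 °C per pulse / 0.06 ≈
  12.7 °C): qualitatively the regime the fits must cope with, where the
  thermal term is material but does not dominate. This constant belongs to
  the synthetic plant only; it is not a tissue property.

What the generator deliberately does **not** emulate: capacitive
transients and electrode polarisation (excluded from the analysis by
design — `synthesize_waveform()` can add a decaying onset spike precisely
to show the last-4 µs averaging ignores it), contact-impedance drift,
waveform droop, spatial temperature gradients within the sample, membrane
resealing between pulses, and tissue-to-tissue variability. Passing
recovery tests therefore demonstrates that the estimation machinery is
correct and well-conditioned under the stated noise model — not that the
model family captures every feature of real recordings.

## Fitting

Per pulse number, `fit_heaviside_curve()` minimises Σ(σ_obs − σ_model)²
over (σ₀, A, E₀, E₁) with bounds σ₀ > 0, A ≥ 0, 0 ≤ E₀ < E₁, using bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`) on the internal parameterisation
(σ₀, A, E₀, ΔE = E₁−E₀), which turns the ordering constraint into a simple
box. Initial guesses are deterministic: σ₀ from the mean conductivity at
the two lowest magnitudes, A from the dynamic range, E₀ from the field
interval of steepest observed rise, E₁ = 2E₀; a small set of fallback
starts shifting the guessed transition zone runs only if the first fit
fails to converge or leaves > 15 % of the variance unexplained. Least
squares is unweighted. Fits are *flagged* (not dropped) when R² < 0.85 and
excluded downstream only on non-convergence.

The pulse-number fits need more care because their loss surfaces have
shallow, curved valleys:

- `fit_A_vs_N()` runs a deterministic 24-point multi-start grid over
  (a₁, b₁, c₁) — b₁ spans decades because only b₁^c₁-type combinations are
  well determined at N ≥ 1 — and keeps the lowest-deviance solution.
- `fit_E0_vs_N()` exploits that the model is linear in (a₂, b₂) given c₂:
  the projected SSE is scanned over a log-spaced c₂ grid (it is
  multimodal, so a bare golden-section search can land in the wrong
  basin), refined locally, and polished by bounded LM. A c₂ estimate at
  the zero boundary is flagged — the exponential term has degenerated to a
  constant, which happens legitimately when the pulse train is too short
  to see the slow decay.

95 % confidence intervals come from the linearised covariance
s²(JᵀJ)⁻¹ at the optimum with t-quantiles — the standard curve-fitting
workflow. Only well-determined coefficients (the asymptote a₁ in
particular) should be interpreted through these intervals; b₁'s interval is
typically wide because of the valley geometry. Constant inputs (zero
variance in A) are flagged degenerate rather than fitted.

The baseline conductivity entering the final model is the arithmetic mean
of the converged per-pulse σ₀ estimates (`pool_sigma0()`), since the
baseline should not depend on pulse number.

## Simulation

`simulate_lumped()` is exact for the plate geometry (uniform field) and is
the reference implementation: per pulse, σₙ = σ(E, n, Tₙ), Iₙ = σₙES, then
one thermal step. With zero heat loss the temperature rise equals the
cumulative Σσₙ E² d/(ρc_p) exactly (energy-bookkeeping test).

`simulate_axisymmetric()` solves the same physics as a 2D axisymmetric
finite-volume problem — tissue cylinder plus insulating mold annulus
between equipotential plate electrodes — for geometries where the field is
not uniform. Numerical choices:

- Nonlinearity by Picard (fixed-point) iteration: σ per cell is evaluated
  at the previous iterate's |∇φ| and the start-of-pulse temperature;
  convergence when the maximum relative field change drops below 10⁻⁴,
  with a 50-iteration cap that raises an error rather than returning an
  unconverged field. When σ does not depend on E the loop converges in one
  iteration (a test).
- Harmonic-mean face conductivities; the mold's conductivity (10⁻¹⁶ S/m)
  is floored at 10⁻⁹ of the maximum cell conductivity inside the matrix
  assembly — the implied leakage current is ~10⁻⁹ of the tissue current,
  far below discretisation error, and the sparse LU stays well
  conditioned.
- Delivered current is the normal current density integrated over the
  tissue mid-plane; the currents through *all* axial planes are retained so
  charge conservation is testable (they agree to ~10⁻¹⁴ relative).
- Default grid: 24 radial cells across the tissue radius (minimum 20
  enforced), 20 axial cells; for the plate geometry a refinement step
  changes the current by far less than 0.5 %.
- Thermal update per 1 s period, with the duty-scaled source: either the
  same scalar `thermal_step()` as the lumped model (`thermal = "lumped"`),
  or one implicit conduction step on the grid with electrode planes and
  mold exterior held at 24 °C (`thermal = "conduction"`). The
  lumped-vs-grid agreement test runs the grid solver with the lumped
  thermal update **on purpose**: the plate field is uniform, so the lumped
  model is an exact oracle for the electrical discretisation, and sharing
  the thermal path isolates exactly that. The conduction mode, whose
  boundary cooling makes it genuinely different physics, is tested
  separately (heating, boundedness, charge conservation).
- Within-pulse dynamics are not resolved: the model is quasi-static per
  pulse and describes only end-of-pulse currents.

## Validation

`compare_models()` scores simulated against observed per-pulse currents by
RMSE and per-pulse relative error `|fᵢ − ȳᵢ|/ȳᵢ` (observations averaged
over replicates pulse-wise before the metrics). On synthetic data whose
truth *is* a multi-pulse model, the multi-pulse simulation must beat the
conventional one at every validation magnitude; the package asserts this
ordering as a property, since the corresponding experimental RMSE table
derives from undeposited recordings and is not reproducible. The
experiment-free analogue is `run_pipeline()`, which chains
generate → extract → fit → simulate → compare deterministically from one
seed and writes all artifacts.

## Problem sizes and test budget

The test suite generates everything it needs in code. Full-scale runs (11
magnitudes × 90 pulses × 3 replicates, noiseless and at 3 % noise) anchor
the recovery and R²-floor checks and each complete in a few seconds;
solver property tests use shortened trains (2–15 pulses) and the default
grid, with one 40×20 refinement case. The whole suite runs in well under a
minute on one core.

## Known limitations

- The parameter functions are calibrated for 1 Hz, 100 µs monopolar
  trains; pulse-frequency and pulse-width dependence are out of scope.
- α and A cannot be fully decoupled by this experimental design; the
  additive/multiplicative choice shifts the split between them.
- Membrane resealing/recovery between pulses is not modelled, so the model
  should not be extrapolated to long inter-pulse delays.
- The reference parameter set is ex vivo rabbit liver; other tissues need
  their own fits.
- The grid solver is 2D axisymmetric by construction; needle-electrode
  (fully 3D) geometries are out of scope.
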