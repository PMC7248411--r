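Package: pulsecond
Title: Multi-Pulse Dynamic Conductivity Modelling for Pulsed-Electric-Field
    Treated Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the dynamic electrical conductivity of
    tissue treated with trains of 100-microsecond pulsed electric fields, as
    used in irreversible electroporation (IRE) treatment planning. Implements
    a smoothed-Heaviside conductivity model sigma(E, N, T) in which the
    electroporation increase factor and the lower turning point of the
    field-conductivity curve evolve with pulse number; per-pulse nonlinear
    least-squares fitting of treatment recordings with pooled baseline
    conductivity and pulse-number parameter models; a synthetic pulse-train
    generator with a lumped electro-thermal plant for end-to-end parameter
    recovery studies; lumped and 2D axisymmetric coupled Laplace-bioheat
    pulse-train simulators; and RMSE-based comparison of the multi-pulse
    model against the conventional single-pulse conductivity model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
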