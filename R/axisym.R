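# 2D axisymmetric finite-volume solver for the coupled Laplace-bioheat
# pulse-train problem: tissue cylinder inside an insulating mold annulus
# between equipotential plate electrodes. Cell-centred uniform grid in
# (r, z); harmonic-mean face coefficients; the radial axis (r = 0) and the
# outer radius are zero-flux, the electrode planes are Dirichlet.

axisym_grid <- function(geom, nr_tissue = 24L, nz = 20L) {
  R_t <- geom$diameter / 2
  R_m <- geom$mold_diameter / 2
  dr <- R_t / nr_tissue
  nr_mold <- as.integer(round((R_m - R_t) / dr))
  nr <- nr_tissue + nr_mold
  dz <- geom$L / nz
  r_c <- (seq_len(nr) - 0.5) * dr
  list(
    nr = nr, nz = nz, nr_tissue = as.integer(nr_tissue), dr = dr, dz = dz,
    r_c = r_c, r_face = seq_len(nr) * dr,   # outer face radius of cell i
    tissue = seq_len(nr) <= nr_tissue,      # radial tissue mask
    L = geom$L, R_t = R_t, R_m = R_m
  )
}

cell_index <- function(i, j, nr) (j - 1L) * nr + i

# Assemble the conservation system sum_f c_f (phi_nb - phi_c) = 0 with
# Dirichlet values phi = bc0 at z = 0 and phi = bc1 at z = L.
# `coef` is the per-cell transport coefficient (sigma or k), as an nr x nz
# matrix. Returns list(A, b).
axisym_system <- function(g, coef, bc0, bc1) {
  nr <- g$nr; nz <- g$nz
  ii <- jj <- xx <- numeric(0)
  b <- numeric(nr * nz)
  diag_acc <- numeric(nr * nz)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  # radial faces between (i, j) and (i + 1, j)
  for (i in seq_len(nr - 1L)) {
    A_f <- 2 * pi * g$r_face[i] * g$dz
    for (j in seq_len(nz)) {
      cf <- 2 * coef[i, j] * coef[i + 1L, j] / (coef[i, j] + coef[i + 1L, j])
      w <- cf * A_f / g$dr
      p <- cell_index(i, j, nr); q <- cell_index(i + 1L, j, nr)
      add(p, q, -w); add(q, p, -w)
      diag_acc[p] <- diag_acc[p] + w
      diag_acc[q] <- diag_acc[q] + w
    }
  }
  # axial faces between (i, j) and (i, j + 1)
  for (i in seq_len(nr)) {
    A_f <- 2 * pi * g$r_c[i] * g$dr
    for (j in seq_len(nz - 1L)) {
      cf <- 2 * coef[i, j] * coef[i, j + 1L] / (coef[i, j] + coef[i, j + 1L])
      w <- cf * A_f / g$dz
      p <- cell_index(i, j, nr); q <- cell_index(i, j + 1L, nr)
      add(p, q, -w); add(q, p, -w)
      diag_acc[p] <- diag_acc[p] + w
      diag_acc[q] <- diag_acc[q] + w
    }
    # Dirichlet boundary faces at z = 0 and z = L (half-cell distance)
    w0 <- coef[i, 1L] * A_f / (g$dz / 2)
    p <- cell_index(i, 1L, nr)
    diag_acc[p] <- diag_acc[p] + w0
    b[p] <- b[p] + w0 * bc0
    w1 <- coef[i, nz] * A_f / (g$dz / 2)
    p <- cell_index(i, nz, nr)
    diag_acc[p] <- diag_acc[p] + w1
    b[p] <- b[p] + w1 * bc1
  }
  n <- nr * nz
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n)), j = c(jj, seq_len(n)),
                            x = c(xx, diag_acc), dims = c(n, n))
  list(A = A, b = b)
}

# |grad phi| per cell from face gradients (Dirichlet 0 / U at z faces).
axisym_field <- function(g, phi, U) {
  nr <- g$nr; nz <- g$nz
  ph <- matrix(phi, nr, nz)
  gz_face <- matrix(0, nr, nz + 1L)            # axial face gradients
  gz_face[, 1L] <- (ph[, 1L] - 0) / (g$dz / 2)
  gz_face[, nz + 1L] <- (U - ph[, nz]) / (g$dz / 2)
  if (nz > 1L) {
    gz_face[, 2:nz] <- (ph[, 2:nz] - ph[, 1:(nz - 1L)]) / g$dz
  }
  Ez <- (gz_face[, 1:nz, drop = FALSE] + gz_face[, 2:(nz + 1L), drop = FALSE]) / 2
  gr_face <- matrix(0, nr + 1L, nz)            # radial face gradients
  if (nr > 1L) {
    gr_face[2:nr, ] <- (ph[2:nr, , drop = FALSE] - ph[1:(nr - 1L), , drop = FALSE]) / g$dr
  }
  Er <- (gr_face[1:nr, , drop = FALSE] + gr_face[2:(nr + 1L), , drop = FALSE]) / 2
  sqrt(Er^2 + Ez^2)
}

# Total axial current through each of the nz + 1 axial face planes.
axisym_plane_currents <- function(g, phi, sigma, U) {
  nr <- g$nr; nz <- g$nz
  ph <- matrix(phi, nr, nz)
  A_f <- 2 * pi * g$r_c * g$dr
  I <- numeric(nz + 1L)
  I[1L] <- sum(sigma[, 1L] * A_f * (ph[, 1L] - 0) / (g$dz / 2))
  I[nz + 1L] <- sum(sigma[, nz] * A_f * (U - ph[, nz]) / (g$dz / 2))
  if (nz > 1L) {
    for (j in seq_len(nz - 1L)) {
      sf <- 2 * sigma[, j] * sigma[, j + 1L] / (sigma[, j] + sigma[, j + 1L])
      I[j + 1L] <- sum(sf * A_f * (ph[, j + 1L] - ph[, j]) / g$dz)
    }
  }
  I
}

#' Simulate a pulse train with the 2D axisymmetric grid solver
#'
#' Solves, per pulse, the nonlinear axisymmetric Laplace problem
#' `div(sigma(E, N, T) grad phi) = 0` for the tissue cylinder inside its
#' insulating mold between equipotential plate electrodes, by fixed-point
#' (Picard) iteration: the conductivity of each tissue cell is evaluated at
#' the previous iterate's field magnitude and the start-of-pulse
#' temperature, and the iteration stops when the maximum relative field
#' change falls below `tol`. The delivered current is the normal current
#' density integrated over the tissue mid-plane; currents through every
#' other axial plane are retained (attribute `plane_currents`) so charge
#' conservation can be checked.
#'
#' Between pulses the temperature advances over one period with the
#' duty-scaled Joule source. Two thermal treatments are available:
#' `thermal = "lumped"` applies the same scalar [thermal_step()] as
#' [simulate_lumped()] (uniform tissue temperature; use this when comparing
#' the two solvers, so the comparison isolates the electrical
#' discretisation), while `thermal = "conduction"` takes one implicit
#' conduction step of the bioheat equation on the same grid with the
#' electrode planes and mold exterior held at `T_amb`.
#'
#' @param model A [pulse_number_model()].
#' @param applied_voltage Plateau voltage `U` (V).
#' @param geom A [sample_geometry()] (supplies cylinder and mold dimensions
#'   and material constants).
#' @param protocol A [protocol_config()].
#' @param mode `"multi_pulse"` or `"conventional"` (pulse number clamped to 1).
#' @param nr_tissue Radial cells across the tissue radius (`>= 20`).
#' @param nz Axial cells across the gap (even, so a face lies on the
#'   mid-plane).
#' @param thermal `"lumped"` or `"conduction"`, see Details.
#' @param heat_loss Loss rate for the lumped thermal mode (1/s).
#' @param T_amb Ambient / boundary temperature (degC).
#' @param variant Temperature coupling, see [conductivity()].
#' @param tol Picard convergence tolerance on the relative field change.
#' @param max_iter Maximum Picard iterations per pulse.
#' @return A tibble of class `pef_simulation` (`pulse_index`, `I_A`, `T_C`,
#'   `sigma_S_per_m` where `sigma` is the apparent conductivity
#'   `I L / (U S)`), with attributes `plane_currents` (pulses x planes
#'   matrix), `picard_iters`, `grid`, `mode`, `solver = "axisymmetric"`.
#' @export
simulate_axisymmetric <- function(model, applied_voltage,
                                  geom = sample_geometry(),
                                  protocol = protocol_config(),
                                  mode = c("multi_pulse", "conventional"),
                                  nr_tissue = 24L, nz = 20L,
                                  thermal = c("lumped", "conduction"),
                                  heat_loss = 0.06, T_amb = model$T0,
                                  variant = "additive",
                                  tol = 1e-4, max_iter = 50L) {
  stopifnot(inherits(model, "pulse_number_model"),
            inherits(geom, "sample_geometry"),
            inherits(protocol, "protocol_config"),
            applied_voltage > 0)
  mode <- match.arg(mode)
  thermal <- match.arg(thermal)
  if (nr_tissue < 20L) {
    stop("`nr_tissue` must be >= 20 to resolve the tissue radius.",
         call. = FALSE)
  }
  if (nz %% 2L != 0L) stop("`nz` must be even (mid-plane face).", call. = FALSE)
  g <- axisym_grid(geom, nr_tissue, nz)
  U <- applied_voltage
  n_pulses <- protocol$n_pulses
  duty <- protocol$pulse_width / protocol$period
  tis <- g$tissue

  # thermal state: scalar (lumped) or nr x nz field (conduction)
  T_scalar <- model$T0
  T_field <- matrix(T_amb, g$nr, g$nz)
  if (thermal == "conduction") {
    k_cell <- matrix(geom$mold$k, g$nr, g$nz); k_cell[tis, ] <- geom$k
    rc_cell <- matrix(geom$mold$rho * geom$mold$c_p, g$nr, g$nz)
    rc_cell[tis, ] <- geom$rho * geom$c_p
    Ksys <- axisym_system(g, k_cell, T_amb, T_amb)
    Vol <- outer(2 * pi * g$r_c * g$dr * g$dz, rep(1, g$nz))
    Mdiag <- as.numeric(rc_cell * Vol / protocol$period)
    H <- Ksys$A + Matrix::Diagonal(x = Mdiag)
    Hfac <- Matrix::Cholesky(Matrix::forceSymmetric(H))
  }

  I_out <- T_out <- sig_out <- numeric(n_pulses)
  iters <- integer(n_pulses)
  planes <- matrix(NA_real_, n_pulses, g$nz + 1L)

  E_cell <- matrix(U / geom$L, g$nr, g$nz)   # initial field iterate
  for (p in seq_len(n_pulses)) {
    Neff <- if (mode == "conventional") 1 else p
    T_cell <- if (thermal == "lumped") matrix(T_scalar, g$nr, g$nz) else T_field
    T_out[p] <- if (thermal == "lumped") T_scalar else mean(T_field[tis, ])
    phi <- NULL; sigma_cell <- NULL
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sigma_cell <- matrix(geom$mold$sigma, g$nr, g$nz)
      sigma_cell[tis, ] <- conductivity_multi_pulse(
        E = as.numeric(E_cell[tis, ]), N = Neff,
        T = as.numeric(T_cell[tis, ]), model = model, variant = variant
      )
      # floor keeps the sparse LU well conditioned; the implied mold leakage
      # current (~1e-9 of the tissue current) is far below discretisation error
      sigma_cell <- pmax(sigma_cell, 1e-9 * max(sigma_cell))
      sys <- axisym_system(g, sigma_cell, 0, U)
      phi <- as.numeric(Matrix::solve(sys$A, sys$b))
      E_new <- axisym_field(g, phi, U)
      rel <- max(abs(E_new[tis, ] - E_cell[tis, ])) /
        max(max(abs(E_cell[tis, ])), 1e-12)
      E_cell <- E_new
      if (rel < tol) { converged <- TRUE; iters[p] <- it; break }
    }
    if (!converged) {
      stop(sprintf(
        "Picard iteration did not converge within %d iterations at pulse %d (last rel change %.3g).",
        max_iter, p, rel), call. = FALSE)
    }
    pc <- axisym_plane_currents(g, phi, sigma_cell, U)
    planes[p, ] <- pc
    I_out[p] <- pc[g$nz / 2L + 1L]            # face at z = L/2
    sig_out[p] <- I_out[p] * geom$L / (U * geom$S)

    # advance temperature over one period
    if (thermal == "lumped") {
      T_scalar <- thermal_step(T_scalar, sig_out[p], U / geom$L, geom,
                               protocol, heat_loss, T_amb = T_amb)
    } else {
      q <- sigma_cell * E_cell^2 * duty
      q[!tis, ] <- 0
      Vol_q <- outer(2 * pi * g$r_c * g$dr * g$dz, rep(1, g$nz))
      rhs <- Mdiag * as.numeric(T_field) + as.numeric(q * Vol_q) + Ksys$b
      T_field <- matrix(as.numeric(Matrix::solve(Hfac, rhs)), g$nr, g$nz)
    }
  }
  out <- tibble::tibble(pulse_index = seq_len(n_pulses), I_A = I_out,
                        T_C = T_out, sigma_S_per_m = sig_out)
  structure(out,
            class = c("pef_simulation", class(out)),
            mode = mode, applied_voltage = U, solver = "axisymmetric",
            thermal = thermal, plane_currents = planes,
            picard_iters = iters, grid = g)
}
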