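# Independent oracles used across tests. These deliberately avoid the
# package's own evaluation paths.

# brute-force grid search for a monoexponential decay time constant with the
# amplitude profiled out by linear least squares
grid_search_decay <- function(t, y, T_grid = seq(1, 200, by = 0.01)) {
  sse <- vapply(T_grid, function(Tc) {
    e <- exp(-t / Tc)
    A <- sum(y * e) / sum(e * e)
    sum((y - A * e)^2)
  }, numeric(1))
  T_grid[which.min(sse)]
}

# bisection root finder for phi solving a*exp(b*phi) + c = tx
bisect_invert <- function(a, b, cc, tx, lo, hi, tol = 1e-12) {
  f <- function(phi) a * exp(b * phi) + cc - tx
  if (f(lo) * f(hi) > 0) stop("oracle: root not bracketed")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# term-by-term scalar re-implementation of the solid-matrix energy,
# structured differently from the package path
oracle_energy <- function(C_bar, phi_f, phi_co, k1, k2, k3, a0, w, theta_deg,
                          n_fam = 8) {
  phi_pg <- 1 - phi_f - phi_co
  th <- theta_deg * pi / 180
  az <- 2 * pi * (0:(n_fam - 1)) / n_fam
  total <- phi_pg * a0 * (sum(diag(C_bar)) - 3)
  if (phi_co > 1e-8) {
    k2t <- phi_co * k2; k3t <- phi_co * k3
    cof <- det(C_bar) * t(solve(C_bar))
    for (i in seq_len(n_fam)) {
      m <- c(cos(th) * cos(az[i]), cos(th) * sin(az[i]), sin(th))
      Lt <- (w / 3) * diag(3) + (1 - w) * (m %o% m)
      I4 <- sum(diag(C_bar %*% Lt))
      K <- sum(diag(cof %*% Lt))
      total <- total + phi_co * k1 *
        (exp(k2t * (I4 - 1)) / k2t + (K^k3t - 1) / k3t)
    }
  }
  total
}

# independent Cauchy stress: central difference of the total energy with
# respect to the deformation gradient, sigma = J^-1 (dPsi/dF) F^T
oracle_sigma_fd <- function(F, comp, arch, params, h = 1e-6) {
  psi_of <- function(Fm) {
    st <- make_kinematics(Fm)
    free_energy(st, comp, arch, params) + osmotic_energy(st$J, comp, params)
  }
  P <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    Fp <- F; Fm <- F
    Fp[a, b] <- Fp[a, b] + h
    Fm[a, b] <- Fm[a, b] - h
    P[a, b] <- (psi_of(Fp) - psi_of(Fm)) / (2 * h)
  }
  (P %*% t(F)) / det(F)
}

# nested-bisection equilibrium of a layered column: outer bisection on the
# shared stress, inner bisection on each layer's stretch
oracle_equilibrium <- function(mesh, strain, tol = 1e-12) {
  n <- mesh$n_layers
  lam_of <- function(i, s) {
    lo <- mesh$phi_s[i] + 1e-7; hi <- 1
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (layer_axial_stress(mesh, mid, i) - s <= 0) lo <- mid else hi <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  mean_strain <- function(s) {
    lam <- vapply(seq_len(n), lam_of, numeric(1), s = s)
    sum(mesh$t_frac * (1 - lam))
  }
  s_hi <- 0; s_lo <- -1e-3
  while (mean_strain(s_lo) < strain) s_lo <- s_lo * 2
  for (k in 1:200) {
    mid <- (s_lo + s_hi) / 2
    if (mean_strain(mid) >= strain) s_lo <- mid else s_hi <- mid
    if (s_hi - s_lo < tol * max(1, abs(s_lo))) break
  }
  s <- (s_lo + s_hi) / 2
  list(stress = s, lambda = vapply(seq_len(n), lam_of, numeric(1), s = s))
}

# piecewise two-level composition field (for two-layer columns)
two_level_field <- function(phi_f = c(0.78, 0.72), phi_co = c(0.12, 0.2)) {
  z <- seq(0, 1, length.out = 401)
  composition_field(z, ifelse(z < 0.5, phi_f[1], phi_f[2]),
                    ifelse(z < 0.5, phi_co[1], phi_co[2]))
}

random_admissible_composition <- function() {
  phi_f <- runif(1, 0.6, 0.85)
  phi_co <- runif(1, 0.05, min(0.3, 0.95 - phi_f))
  local_composition(phi_f, phi_co)
}
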