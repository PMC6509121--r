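#' Global constitutive material parameters
#'
#' The six-parameter set of the fiber-reinforced cartilage model: `k1` (MPa)
#' scales the collagen fibril energy, `k2` and `k3` (dimensionless) control
#' the fibril nonlinearity in tension (J-shaped exponential) and compression
#' (tube contraction), `a0` (MPa) is the stiffness of the non-collagenous
#' matrix and of the osmotic term, `a1` (dimensionless) the compressibility
#' exponent of the osmotic term, and `w` in \[0, 1\] the fiber dispersion
#' weight (0 = ideal alignment, 1 = isotropic fiber distribution). Defaults
#' are the identified global set: k1 = 0.6 MPa, k2 = 50, k3 = 25,
#' a0 = 0.35 MPa, a1 = 5, w = 0.3.
#'
#' @param k1,k2,k3,a0,a1,w See description.
#' @return An object of class `material_parameters`.
#' @export
material_parameters <- function(k1 = 0.6, k2 = 50, k3 = 25,
                                a0 = 0.35, a1 = 5, w = 0.3) {
  p <- list(k1 = k1, k2 = k2, k3 = k3, a0 = a0, a1 = a1, w = w)
  if (any(!vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), TRUE)))
    stop("all material parameters must be single finite numbers")
  if (k1 <= 0 || a0 <= 0) stop("k1 and a0 must be positive (MPa)")
  if (k2 <= 0 || k3 <= 0 || a1 <= 0) stop("k2, k3 and a1 must be positive")
  if (w < 0 || w > 1) stop("the dispersion weight w must lie in [0, 1]")
  structure(p, class = "material_parameters")
}

#' @export
print.material_parameters <- function(x, ...) {
  cat(sprintf("<material_parameters> k1 = %g MPa, k2 = %g, k3 = %g, a0 = %g MPa, a1 = %g, w = %g\n",
              x$k1, x$k2, x$k3, x$a0, x$a1, x$w))
  invisible(x)
}

#' Local tissue composition at a material point
#'
#' @param phi_f,phi_co Fluid and collagen volume fractions.
#' @param phi_pg Proteoglycan fraction; defaults to the saturation remainder
#'   `1 - phi_f - phi_co`.
#' @return An object of class `local_composition` with the solid fraction
#'   `phi_s = 1 - phi_f`.
#' @export
local_composition <- function(phi_f, phi_co, phi_pg = 1 - phi_f - phi_co) {
  if (abs(phi_f + phi_co + phi_pg - 1) > 1e-10)
    stop("volume fractions must sum to 1 (tol 1e-10)")
  if (any(c(phi_f, phi_co, phi_pg) < 0) || any(c(phi_f, phi_co, phi_pg) > 1))
    stop("volume fractions must lie in [0, 1]")
  structure(list(phi_f = phi_f, phi_co = phi_co, phi_pg = phi_pg,
                 phi_s = 1 - phi_f),
            class = "local_composition")
}

#' Kinematic quantities of a deformation state
#'
#' Computes the relative volume change `J = det(F)`, the right Cauchy-Green
#' tensor `C = t(F) %*% F` and its distortional (isochoric) part
#' `C_bar = J^(-2/3) C` with `det(C_bar) = 1`.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @return An object of class `deformation_state` with fields `F`, `J`, `C`,
#'   `C_bar`.
#' @export
make_kinematics <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("inverted element: det(F) must be positive")
  C <- crossprod(F)
  structure(list(F = F, J = J, C = C, C_bar = J^(-2 / 3) * C),
            class = "deformation_state")
}

#' Benninghoff arcade fiber architecture
#'
#' Idealized depth-dependent collagen fibril architecture: `n_families`
#' equiangular fiber families (default 8, azimuths 45 degrees apart), each
#' inclined by `theta_fib(z)` out of the surface plane. The default linear
#' inclination profile runs from 0 degrees at the articular surface (z = 0,
#' fibers parallel to the surface) to 90 degrees at the osteochondral
#' interface (z = 1, fibers perpendicular to the bone).
#'
#' @param z Normalized depth in \[0, 1\].
#' @param n_families Number of fiber families (default 8).
#' @param w Dispersion weight used for the weighted structural tensors.
#' @param angle_profile Optional function mapping z to the inclination in
#'   degrees; default `function(z) 90 * z`.
#' @return An object of class `fiber_architecture` with the unit direction
#'   matrix `directions` (n x 3), the plain structural tensors `L`
#'   (list of `m %o% m`) and the weighted tensors `L_tilde`.
#' @export
arcade_directions <- function(z, n_families = 8L, w = 0.3, angle_profile = NULL) {
  if (!is.finite(z) || z < 0 || z > 1)
    stop("normalized depth z must lie in [0, 1]")
  if (is.null(angle_profile)) angle_profile <- function(z) 90 * z
  theta <- angle_profile(z) * pi / 180
  az <- 2 * pi * (seq_len(n_families) - 1) / n_families
  m <- cbind(cos(theta) * cos(az), cos(theta) * sin(az),
             rep(sin(theta), n_families))
  L <- lapply(seq_len(n_families), function(i) tcrossprod(m[i, ]))
  Lt <- lapply(L, function(Li) (w / 3) * diag(3) + (1 - w) * Li)
  structure(list(z = z, n_families = n_families, w = w, theta_deg = theta * 180 / pi,
                 directions = m, L = L, L_tilde = Lt),
            class = "fiber_architecture")
}

#' Weighted structural tensor of a fiber family
#'
#' `L_tilde = (w/3) I + (1 - w) m %o% m`: a rank-one fiber tensor blended
#' with the identity by the dispersion weight w. Its trace is 1 for any w.
#'
#' @param m Unit fiber direction (length-3).
#' @param w Dispersion weight in \[0, 1\].
#' @return 3x3 symmetric positive semidefinite matrix with unit trace.
#' @export
structural_tensor <- function(m, w) {
  m <- as.numeric(m)
  if (abs(sum(m^2) - 1) > 1e-8)
    stop("fiber direction must be a unit vector")
  if (w < 0 || w > 1) stop("dispersion weight w must lie in [0, 1]")
  (w / 3) * diag(3) + (1 - w) * tcrossprod(m)
}

#' Isochoric strain invariants of the fiber-reinforced model
#'
#' Returns the first isochoric invariant `I1_bar = tr(C_bar)`, the fiber
#' stretch invariants and the cofactor (areal) invariants
#' `K_bar_i = tr(cof(C_bar) L_tilde_i)`. Two variants of the fiber stretch
#' invariant are returned: `I4_bar` computed with the plain structural
#' tensors `L_i = m_i %o% m_i` and `I4_bar_weighted` computed with the
#' weighted tensors `L_tilde_i` (the form consistent with a stress-free
#' reference state; see the package vignette).
#'
#' @param state A [make_kinematics()] result.
#' @param arch An [arcade_directions()] result.
#' @return List with `I1_bar`, `I4_bar`, `I4_bar_weighted`, `K_bar`.
#' @export
cm_invariants <- function(state, arch) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(arch, "fiber_architecture"))
  Cb <- state$C_bar
  cofCb <- det(Cb) * solve(Cb)   # cof(C) = det(C) C^{-1} for symmetric C
  list(
    I1_bar = sum(diag(Cb)),
    I4_bar = vapply(arch$L, function(L) sum(Cb * L), numeric(1)),
    I4_bar_weighted = vapply(arch$L_tilde, function(L) sum(Cb * L), numeric(1)),
    K_bar = vapply(arch$L_tilde, function(L) sum(cofCb * L), numeric(1))
  )
}

# Collagen fibril contribution is switched off below this fraction: the
# 1/k_tilde prefactors diverge as phi_co -> 0 while the stress vanishes.
.PHI_CO_MIN <- 1e-8

# Isochoric free energy as a function of C_bar (used by both the public
# surface and the finite-difference stress path).
.psi_bar <- function(C_bar, comp, arch, params,
                     fiber_invariant = c("weighted", "plain")) {
  fiber_invariant <- match.arg(fiber_invariant)
  I1 <- sum(diag(C_bar))
  psi <- comp$phi_pg * params$a0 * (I1 - 3)
  if (comp$phi_co > .PHI_CO_MIN) {
    k2t <- comp$phi_co * params$k2
    k3t <- comp$phi_co * params$k3
    if (k2t == 0 || k3t == 0) stop("effective fibril exponents must be positive")
    cofCb <- det(C_bar) * solve(C_bar)
    G <- if (fiber_invariant == "weighted") arch$L_tilde else arch$L
    fib <- 0
    for (i in seq_len(arch$n_families)) {
      I4 <- sum(C_bar * G[[i]])
      K <- sum(cofCb * arch$L_tilde[[i]])
      fib <- fib + (1 / k2t) * exp(k2t * (I4 - 1)) + (1 / k3t) * (K^k3t - 1)
    }
    psi <- psi + comp$phi_co * params$k1 * fib
  }
  psi
}

#' Isochoric free energy density
#'
#' The solid-matrix free energy
#' `Psi_bar = Phi_co * Psi_co + Phi_pg * Psi_pg` (MPa): a polyconvex fibril
#' energy summed over the fiber families,
#' `sum_i k1 [ exp(k2t (I4_i - 1))/k2t + (K_i^k3t - 1)/k3t ]` with
#' composition-scaled exponents `k2t = Phi_co k2`, `k3t = Phi_co k3`, plus a
#' Neo-Hookean proteoglycan matrix `a0 (I1_bar - 3)`. The fibril term is set
#' to zero below `Phi_co = 1e-8` (its stress vanishes there while the energy
#' constant diverges).
#'
#' @param state A [make_kinematics()] result.
#' @param comp A [local_composition()].
#' @param arch An [arcade_directions()] result.
#' @param params A [material_parameters()] set.
#' @param fiber_invariant `"weighted"` (default; fiber stretch measured with
#'   the dispersion-weighted structural tensor, giving an exactly stress-free
#'   reference state) or `"plain"` (unweighted `L_i`).
#' @return Scalar energy density in MPa (per unit reference volume).
#' @export
free_energy <- function(state, comp, arch, params,
                        fiber_invariant = c("weighted", "plain")) {
  stopifnot(inherits(state, "deformation_state"),
            inherits(comp, "local_composition"),
            inherits(arch, "fiber_architecture"),
            inherits(params, "material_parameters"))
  .psi_bar(state$C_bar, comp, arch, params, fiber_invariant)
}

#' Osmotic multiplier
#'
#' Empirical swelling-pressure law
#' `pi(J) = a0 ((1 - Phi_s)/(J - Phi_s))^(2 a1t) + pi0` with the
#' composition-scaled exponent `a1t = Phi_f a1` and the offset `pi0 = -a0`
#' chosen so that `pi(1) = 0` (stress-free reference). The multiplier
#' diverges as J approaches the compaction point `J -> Phi_s` at which all
#' fluid is expelled.
#'
#' @param J Relative volume change, must exceed `Phi_s` by more than 1e-9.
#' @param comp A [local_composition()].
#' @param params A [material_parameters()] set.
#' @return Osmotic multiplier in MPa.
#' @export
osmotic_pressure <- function(J, comp, params) {
  if (any(J <= comp$phi_s + 1e-9))
    stop(sprintf("compaction error: J = %.6g at or below the compaction point Phi_s = %.6g",
                 min(J), comp$phi_s))
  a1t <- comp$phi_f * params$a1
  params$a0 * ((1 - comp$phi_s) / (J - comp$phi_s))^(2 * a1t) - params$a0
}

#' Osmotic energy density
#'
#' The volumetric energy `Psi_pi(J)` whose negative J-derivative is the
#' osmotic multiplier, normalized so `Psi_pi(1) = 0`. Closed form:
#' `-a0 (1 - Phi_s)^(2a1t) [ (J - Phi_s)^(1 - 2a1t) - (1 - Phi_s)^(1 - 2a1t) ] / (1 - 2a1t) + a0 (J - 1)`
#' (logarithmic branch at `2 a1t = 1`).
#'
#' @inheritParams osmotic_pressure
#' @return Energy density in MPa.
#' @export
osmotic_energy <- function(J, comp, params) {
  if (any(J <= comp$phi_s + 1e-9))
    stop("compaction error: J at or below the compaction point")
  a1t <- comp$phi_f * params$a1
  fs <- comp$phi_s
  e <- 2 * a1t
  base <- if (abs(e - 1) < 1e-12) {
    (1 - fs) * (log(J - fs) - log(1 - fs))
  } else {
    (1 - fs)^e * ((J - fs)^(1 - e) - (1 - fs)^(1 - e)) / (1 - e)
  }
  -params$a0 * base + params$a0 * (J - 1)
}

# analytic dPsi_bar/dC_bar (the isochoric second Piola-Kirchhoff tensor S_bar)
.s_bar_analytic <- function(C_bar, comp, arch, params, fiber_invariant) {
  I3 <- diag(3)
  S <- comp$phi_pg * params$a0 * I3
  if (comp$phi_co > .PHI_CO_MIN) {
    k2t <- comp$phi_co * params$k2
    k3t <- comp$phi_co * params$k3
    Cinv <- solve(C_bar)
    dC <- det(C_bar)
    G <- if (fiber_invariant == "weighted") arch$L_tilde else arch$L
    fib <- matrix(0, 3, 3)
    for (i in seq_len(arch$n_families)) {
      Lt <- arch$L_tilde[[i]]
      I4 <- sum(C_bar * G[[i]])
      K <- sum(dC * Cinv * Lt)
      # d K / d C_bar = det(C)[ tr(C^-1 Lt) C^-1 - C^-1 Lt C^-1 ]
      dK <- dC * (sum(Cinv * Lt) * Cinv - Cinv %*% Lt %*% Cinv)
      fib <- fib + exp(k2t * (I4 - 1)) * G[[i]] + K^(k3t - 1) * dK
    }
    S <- S + comp$phi_co * params$k1 * fib
  }
  S
}

# legacy closed-form fibril stress: S_bar = Phi_co sum k1[(f' - g') L_tilde + g' K I]
# + Phi_pg a0 I; not the derivative of the implemented energy (see docs)
.s_bar_legacy <- function(C_bar, comp, arch, params) {
  S <- comp$phi_pg * params$a0 * diag(3)
  if (comp$phi_co > .PHI_CO_MIN) {
    k2t <- comp$phi_co * params$k2
    k3t <- comp$phi_co * params$k3
    Cinv <- solve(C_bar)
    dC <- det(C_bar)
    fib <- matrix(0, 3, 3)
    for (i in seq_len(arch$n_families)) {
      Lt <- arch$L_tilde[[i]]
      I4 <- sum(C_bar * Lt)
      K <- sum(dC * Cinv * Lt)
      fp <- exp(k2t * (I4 - 1))
      gp <- K^(k3t - 1)
      fib <- fib + (fp - gp) * Lt + gp * K * diag(3)
    }
    S <- S + comp$phi_co * params$k1 * fib
  }
  S
}

#' Cauchy stress of the cartilage model
#'
#' Assembles the Cauchy stress
#' `sigma = 2 J^-1 F (dPsi_bar/dC + dPsi_pi/dC) t(F)` with the deviatoric
#' projection `dPsi_bar/dC = J^(-2/3) [S_bar - (1/3)(S_bar : C) C^-1]` and
#' the energy-consistent osmotic term `dPsi_pi/dC = -(pi J / 2) C^-1`
#' (so the volumetric Cauchy contribution is `-pi I`).
#'
#' Three evaluation paths for `S_bar` are provided: `"analytic"` (default;
#' the closed-form derivative of the implemented [free_energy()]),
#' `"numeric"` (central differences of the total energy with respect to C;
#' slower, used as an independent check) and `"legacy"` (a commonly quoted
#' closed form of the fibril stress that attaches the fiber-stretch
#' derivative to the weighted structural tensor but omits the C-dependent
#' terms of the cofactor-invariant derivative; it is NOT the derivative of
#' the implemented energy and is retained only for comparison - see the
#' vignette).
#'
#' @inheritParams free_energy
#' @param method Stress evaluation path, see Details.
#' @param fd_step Relative finite-difference step for `method = "numeric"`.
#' @return An object of class `stress_state` with fields `sigma` (3x3 MPa,
#'   symmetric), `S_bar`, `pi` and `pi0`.
#' @export
cauchy_stress <- function(state, comp, arch, params,
                          method = c("analytic", "numeric", "legacy"),
                          fiber_invariant = c("weighted", "plain"),
                          fd_step = 1e-6) {
  method <- match.arg(method)
  fiber_invariant <- match.arg(fiber_invariant)
  stopifnot(inherits(state, "deformation_state"))
  J <- state$J; C <- state$C; F <- state$F
  pi_val <- osmotic_pressure(J, comp, params)

  if (method == "numeric") {
    # S = 2 dPsi_tot/dC by central differences on the 9 components of C
    # (the energy extends symmetrically, so the unconstrained gradient is
    # the correct symmetric-variation derivative)
    total <- function(Cm) {
      Jm <- sqrt(det(Cm))
      .psi_bar(det(Cm)^(-1 / 3) * Cm, comp, arch, params, fiber_invariant) +
        osmotic_energy(Jm, comp, params)
    }
    G <- matrix(0, 3, 3)
    h <- fd_step * max(abs(C))
    for (a in 1:3) for (b in 1:3) {
      Cp <- C; Cm <- C
      Cp[a, b] <- Cp[a, b] + h
      Cm[a, b] <- Cm[a, b] - h
      G[a, b] <- (total(Cp) - total(Cm)) / (2 * h)
    }
    S_tot <- 2 * (G + t(G)) / 2
    sigma <- (1 / J) * F %*% S_tot %*% t(F)
    S_bar <- NULL
  } else {
    C_bar <- state$C_bar
    S_bar <- if (method == "analytic")
      .s_bar_analytic(C_bar, comp, arch, params, fiber_invariant)
    else
      .s_bar_legacy(C_bar, comp, arch, params)
    Cinv <- solve(C)
    dpsibar_dC <- J^(-2 / 3) * (S_bar - (1 / 3) * sum(S_bar * C_bar * J^(2 / 3)) * Cinv)
    dpsipi_dC <- -(pi_val * J / 2) * Cinv
    sigma <- (2 / J) * F %*% (dpsibar_dC + dpsipi_dC) %*% t(F)
  }
  sigma <- (sigma + t(sigma)) / 2
  structure(list(sigma = sigma, S_bar = S_bar, pi = pi_val, pi0 = -params$a0,
                 method = method),
            class = "stress_state")
}

#' @export
print.stress_state <- function(x, ...) {
  cat(sprintf("<stress_state> method %s, pi = %.4g MPa, sigma_zz = %.4g MPa\n",
              x$method, x$pi, x$sigma[3, 3]))
  invisible(x)
}
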