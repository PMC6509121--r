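#' Loading protocol for equilibrium confined compression
#'
#' The default emulates a staircase of 20 ramped compressions of 1%/min up
#' to a total strain of 20%, each followed by relaxation to equilibrium.
#' Only the relaxed states are modelled; the strain rate is metadata.
#'
#' @param strains Increasing applied compressive strains (fractions, e.g.
#'   0.01..0.20).
#' @param rate_pct_per_min Ramp rate in percent per minute (metadata).
#' @return An object of class `loading_protocol`.
#' @export
loading_protocol <- function(strains = seq(0.01, 0.20, by = 0.01),
                             rate_pct_per_min = 1) {
  strains <- as.numeric(strains)
  if (any(!is.finite(strains)) || any(strains <= 0) || any(strains >= 1))
    stop("strains must lie in (0, 1)")
  if (any(diff(strains) <= 0)) stop("strains must be strictly increasing")
  structure(list(strains = strains, rate_pct_per_min = rate_pct_per_min),
            class = "loading_protocol")
}

#' Build a layered sample column
#'
#' Discretizes a depth-resolved composition field into `n_layers` equal-
#' thickness layers (ordered surface to bone), each carrying its
#' layer-averaged composition (trapezoidal average of the linearly
#' interpolated field) and the arcade fiber inclination at its midpoint.
#'
#' @param comp A [composition_field()] on z in \[0, 1\].
#' @param params A [material_parameters()] set.
#' @param thickness Sample thickness in mm.
#' @param n_layers Number of layers (default 20).
#' @param n_families Fiber families per layer (default 8).
#' @param angle_profile Optional inclination profile in degrees (default
#'   `90 * z`), see [arcade_directions()].
#' @return An object of class `column_mesh`.
#' @export
build_column <- function(comp, params, thickness = 4.2, n_layers = 20L,
                         n_families = 8L, angle_profile = NULL) {
  stopifnot(inherits(comp, "composition_field"),
            inherits(params, "material_parameters"))
  if (n_layers < 1L) stop("need at least one layer")
  if (is.null(angle_profile)) angle_profile <- function(z) 90 * z
  edges <- seq(0, 1, length.out = n_layers + 1L)
  f_f <- stats::approxfun(comp$z, comp$phi_f, rule = 2)
  f_co <- stats::approxfun(comp$z, comp$phi_co, rule = 2)
  # exact trapezoidal mean of the piecewise-linear interpolant: integrate
  # over the union of the layer edges and the field's grid knots
  layer_mean <- function(fn, lo, hi) {
    zz <- sort(unique(c(lo, hi, comp$z[comp$z > lo & comp$z < hi])))
    pracma::trapz(zz, fn(zz)) / (hi - lo)
  }
  phi_f <- phi_co <- numeric(n_layers)
  for (i in seq_len(n_layers)) {
    phi_f[i] <- layer_mean(f_f, edges[i], edges[i + 1L])
    phi_co[i] <- layer_mean(f_co, edges[i], edges[i + 1L])
  }
  phi_pg <- 1 - phi_f - phi_co
  if (any(phi_pg < comp$delta_tol))
    stop(sprintf("saturation error: layer %d has proteoglycan fraction %.3g below tolerance",
                 which(phi_pg < comp$delta_tol)[1], min(phi_pg)))
  z_mid <- (edges[-1L] + edges[-(n_layers + 1L)]) / 2
  mesh <- structure(
    list(n_layers = n_layers, z_mid = z_mid,
         t_frac = rep(1 / n_layers, n_layers), thickness = thickness,
         phi_f = phi_f, phi_co = phi_co, phi_pg = phi_pg, phi_s = 1 - phi_f,
         theta_deg = angle_profile(z_mid), n_families = n_families,
         params = params),
    class = "column_mesh")
  mesh$terms <- .axial_terms(mesh)   # cached closed-form stress constants
  mesh
}

#' @export
print.column_mesh <- function(x, ...) {
  cat(sprintf("<column_mesh> %d layers, thickness %.3g mm, phi_co %.3f..%.3f, compaction at J = %.3f\n",
              x$n_layers, x$thickness, min(x$phi_co), max(x$phi_co), max(x$phi_s)))
  invisible(x)
}

# Precompute the per-layer constants of the closed-form confined-compression
# stress: under F = diag(1, 1, lambda) the eight equiangular families at a
# common inclination theta share identical invariants, so the axial nominal
# stress reduces to a scalar derivative of the energy in lambda.
.axial_terms <- function(mesh) {
  p <- mesh$params
  th <- mesh$theta_deg * pi / 180
  w <- p$w
  list(
    Ap = 2 * w / 3 + (1 - w) * cos(th)^2,  # planar weight of L_tilde
    Az = w / 3 + (1 - w) * sin(th)^2,      # axial weight of L_tilde
    k2t = mesh$phi_co * p$k2, k3t = mesh$phi_co * p$k3,
    a1t = mesh$phi_f * p$a1,
    n = mesh$n_families, k1 = p$k1, a0 = p$a0,
    phi_f = mesh$phi_f, phi_co = mesh$phi_co, phi_pg = mesh$phi_pg,
    phi_s = mesh$phi_s,
    fib_on = as.numeric(mesh$phi_co > .PHI_CO_MIN))
}

# axial nominal stress P(lambda) per layer (vectorized over layers);
# P = dPsi_tot/dlambda, and since J = lambda with fixed lateral stretches the
# axial Cauchy and nominal components coincide.
.axial_P <- function(tm, lam) {
  u <- lam^(-2 / 3); v <- lam^(4 / 3)
  du <- -(2 / 3) * lam^(-5 / 3); dv <- (4 / 3) * lam^(1 / 3)
  I4 <- u * tm$Ap + v * tm$Az
  K <- (1 / u) * tm$Ap + (1 / v) * tm$Az
  dI4 <- du * tm$Ap + dv * tm$Az
  dK <- (2 / 3) * lam^(-1 / 3) * tm$Ap - (4 / 3) * lam^(-7 / 3) * tm$Az
  fib <- tm$fib_on * tm$phi_co * tm$n * tm$k1 *
    (exp(tm$k2t * (I4 - 1)) * dI4 + K^(tm$k3t - 1) * dK)
  pg <- tm$phi_pg * tm$a0 * (2 * du + dv)
  osm <- tm$a0 * ((1 - tm$phi_s) / (lam - tm$phi_s))^(2 * tm$a1t) - tm$a0
  fib + pg - osm
}

# dP/dlambda per layer (vectorized)
.axial_dP <- function(tm, lam) {
  u <- lam^(-2 / 3); v <- lam^(4 / 3)
  du <- -(2 / 3) * lam^(-5 / 3); dv <- (4 / 3) * lam^(1 / 3)
  d2u <- (10 / 9) * lam^(-8 / 3); d2v <- (4 / 9) * lam^(-2 / 3)
  I4 <- u * tm$Ap + v * tm$Az
  K <- (1 / u) * tm$Ap + (1 / v) * tm$Az
  dI4 <- du * tm$Ap + dv * tm$Az
  dK <- (2 / 3) * lam^(-1 / 3) * tm$Ap - (4 / 3) * lam^(-7 / 3) * tm$Az
  d2I4 <- d2u * tm$Ap + d2v * tm$Az
  d2K <- -(2 / 9) * lam^(-4 / 3) * tm$Ap + (28 / 9) * lam^(-10 / 3) * tm$Az
  fib <- tm$fib_on * tm$phi_co * tm$n * tm$k1 *
    (exp(tm$k2t * (I4 - 1)) * (tm$k2t * dI4^2 + d2I4) +
       (tm$k3t - 1) * K^(tm$k3t - 2) * dK^2 + K^(tm$k3t - 1) * d2K)
  pg <- tm$phi_pg * tm$a0 * (2 * d2u + d2v)
  dosm <- tm$a0 * 2 * tm$a1t * ((1 - tm$phi_s) / (lam - tm$phi_s))^(2 * tm$a1t - 1) *
    (-(1 - tm$phi_s) / (lam - tm$phi_s)^2)
  fib + pg - dosm
}

#' Axial nominal stress of one layer under confined compression
#'
#' Evaluates the equilibrium axial nominal stress of a single layer at axial
#' stretch `lambda` under lateral confinement (`F = diag(1, 1, lambda)`).
#' Under this deformation the nominal and Cauchy axial components coincide
#' (`J = lambda`). The value is the closed-form lambda-derivative of the
#' implemented energy (isochoric plus osmotic) and is negative in
#' compression; it diverges as `lambda` approaches the layer's compaction
#' point `Phi_s`.
#'
#' @param mesh A [build_column()] mesh.
#' @param lambda Axial stretch in `(Phi_s, 1]`.
#' @param layer Layer index (default 1).
#' @return Nominal axial stress in MPa.
#' @export
layer_axial_stress <- function(mesh, lambda, layer = 1L) {
  stopifnot(inherits(mesh, "column_mesh"))
  tm <- if (is.null(mesh$terms)) .axial_terms(mesh) else mesh$terms
  tm <- lapply(tm, function(x) if (length(x) == mesh$n_layers) x[layer] else x)
  if (any(lambda <= tm$phi_s + 1e-9))
    stop(sprintf("compaction error: lambda = %.6g at or below Phi_s = %.6g",
                 min(lambda), tm$phi_s))
  .axial_P(tm, lambda)
}

# inner solve: per-layer stretches at shared axial stress s (vectorized,
# safeguarded Newton); lam0 is the warm start
.lambda_of_stress <- function(tm, s, lam0, lo) {
  lam <- pmin(pmax(lam0, lo + 1e-7), 1)
  for (it in 1:100) {
    r <- .axial_P(tm, lam) - s
    if (max(abs(r)) < 1e-13 * max(1, abs(s))) break
    step <- r / .axial_dP(tm, lam)
    lam_new <- lam - step
    # bisect toward the admissible interval when Newton overshoots
    bad <- lam_new <= lo + 1e-10 | lam_new > 1
    lam_new[bad] <- (lam[bad] + ifelse(step[bad] > 0, lo[bad] + 1e-10, 1)) / 2
    lam <- lam_new
  }
  lam
}

#' Solve the layered equilibrium at one applied strain
#'
#' Series equilibrium of the confined column: finds per-layer axial
#' stretches such that every layer carries the same axial nominal stress and
#' the thickness-weighted compressive strains sum to the applied strain.
#' Newton iteration on the shared stress with a vectorized per-layer
#' monotone inversion; converges the strain residual below 1e-12.
#'
#' @param mesh A [build_column()] mesh.
#' @param strain Applied compressive strain in `[0, 1 - max(Phi_s))`.
#' @param lambda0 Optional warm-start stretches.
#' @return List with `stress` (shared axial nominal stress, MPa), `lambda`
#'   (per-layer stretches), `strain` and `residual`.
#' @export
solve_equilibrium <- function(mesh, strain, lambda0 = NULL) {
  stopifnot(inherits(mesh, "column_mesh"))
  tm <- if (is.null(mesh$terms)) .axial_terms(mesh) else mesh$terms
  lo <- tm$phi_s + 1e-8
  if (strain >= 1 - max(tm$phi_s))
    stop(sprintf("applied strain %.3g exceeds the compaction bound %.3g",
                 strain, 1 - max(tm$phi_s)))
  if (strain == 0)
    return(list(stress = 0, lambda = rep(1, mesh$n_layers), strain = 0,
                residual = 0))
  t_frac <- mesh$t_frac
  lam <- if (is.null(lambda0)) rep(1 - strain, mesh$n_layers) else lambda0
  g_of <- function(s, lam_start) {
    lam <- .lambda_of_stress(tm, s, lam_start, lo)
    list(g = sum(t_frac * (1 - lam)) - strain, lam = lam)
  }
  # bracket the shared stress: g(0) = -strain < 0, g increases as s decreases
  s_hi <- 0
  s <- min(.axial_P(tm, rep(1 - strain, mesh$n_layers)))
  res <- g_of(s, lam)
  while (res$g < 0) {
    s_hi <- s
    s <- s * 2 - 1e-3
    res <- g_of(s, res$lam)
  }
  s_lo <- s   # g(s_lo) >= 0
  lam <- res$lam
  for (it in 1:200) {
    if (abs(res$g) < 1e-13) break
    dg <- -sum(t_frac / .axial_dP(tm, lam))
    s_new <- s - res$g / dg
    if (!is.finite(s_new) || s_new <= s_lo || s_new >= s_hi)
      s_new <- (s_lo + s_hi) / 2
    s <- s_new
    res <- g_of(s, lam)
    lam <- res$lam
    if (res$g >= 0) s_lo <- s else s_hi <- s
  }
  if (abs(res$g) > 1e-10)
    stop(sprintf("equilibrium solver did not converge: strain residual %.3g", res$g))
  list(stress = s, lambda = lam, strain = strain, residual = res$g)
}

#' Simulate a confined-compression loading protocol
#'
#' Solves the relaxed (equilibrium) state at every strain level of the
#' protocol, warm-starting each level from the previous one.
#'
#' @param mesh A [build_column()] mesh.
#' @param protocol A [loading_protocol()].
#' @return An object of class `equilibrium_solution`: a list with `curve`
#'   (data.frame `strain`, `stress` in MPa), `lambda` (levels x layers
#'   matrix) and the mesh.
#' @export
simulate_protocol <- function(mesh, protocol = loading_protocol()) {
  stopifnot(inherits(protocol, "loading_protocol"))
  ns <- length(protocol$strains)
  stress <- numeric(ns)
  lambda <- matrix(NA_real_, ns, mesh$n_layers)
  lam <- NULL
  for (i in seq_len(ns)) {
    sol <- solve_equilibrium(mesh, protocol$strains[i], lambda0 = lam)
    stress[i] <- sol$stress
    lambda[i, ] <- lam <- sol$lambda
  }
  structure(list(curve = data.frame(strain = protocol$strains, stress = stress),
                 lambda = lambda, mesh = mesh, protocol = protocol),
            class = "equilibrium_solution")
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat(sprintf("<equilibrium_solution> %d levels to %.0f%%, stress %.4g..%.4g MPa\n",
              nrow(x$curve), 100 * max(x$curve$strain),
              x$curve$stress[1], x$curve$stress[nrow(x$curve)]))
  invisible(x)
}

#' Equilibrium stiffness at a target strain
#'
#' Tangent modulus `d|stress|/d strain` at `eps0` by central difference of
#' the two curve points adjacent to `eps0` (default), or the secant modulus
#' `|stress(eps0)|/eps0` (linear interpolation onto `eps0`).
#'
#' @param solution An [simulate_protocol()] result, or a data.frame with
#'   columns `strain` and `stress`.
#' @param eps0 Target strain (default 0.15).
#' @param method `"tangent"` (default) or `"secant"`.
#' @return Stiffness in MPa.
#' @export
stiffness_at <- function(solution, eps0 = 0.15, method = c("tangent", "secant")) {
  method <- match.arg(method)
  curve <- if (inherits(solution, "equilibrium_solution")) solution$curve else solution
  e <- curve$strain; s <- abs(curve$stress)
  if (eps0 < min(e) || eps0 > max(e))
    stop(sprintf("eps0 = %g outside the simulated strain range [%g, %g]",
                 eps0, min(e), max(e)))
  if (method == "secant")
    return(stats::approx(e, s, xout = eps0)$y / eps0)
  node <- which(abs(e - eps0) < 1e-12)
  if (length(node) == 1L && node > 1L && node < length(e)) {
    i_lo <- node - 1L; i_hi <- node + 1L
  } else {
    i_lo <- max(which(e <= eps0)); i_hi <- min(which(e >= eps0))
    if (i_lo == i_hi) {  # eps0 at an endpoint node
      stop("eps0 lies on the curve boundary; no adjacent points for a central difference")
    }
  }
  (s[i_hi] - s[i_lo]) / (e[i_hi] - e[i_lo])
}
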