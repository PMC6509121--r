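#' Idealized depth-dependent cartilage composition
#'
#' Reference profiles of the fluid, collagen and proteoglycan volume
#' fractions over the normalized tissue depth z (0 = articular surface,
#' 1 = osteochondral interface). The defaults are smooth quadratic profiles
#' reproducing the classical depth trends qualitatively: fluid decreasing
#' from 0.85 at the surface to 0.70 at the bone, collagen increasing from
#' 0.10 to 0.25, proteoglycan as the saturation remainder (peaking at
#' mid-depth). They are implementation defaults, overridable through
#' `coefficients`.
#'
#' @param z Numeric vector of normalized depths in \[0, 1\].
#' @param coefficients Optional list with numeric vectors `fluid` and
#'   `collagen`, each polynomial coefficients `c(c0, c1, c2, ...)` in z
#'   (intercept first). Proteoglycan is always the remainder
#'   `1 - fluid - collagen`.
#' @return A data.frame with columns `z`, `phi_f`, `phi_co`, `phi_pg`
#'   summing to 1 at every depth.
#' @export
wilson_reference_profile <- function(z, coefficients = NULL) {
  if (any(!is.finite(z)) || any(z < 0 | z > 1))
    stop("normalized depth z must lie in [0, 1]")
  if (is.null(coefficients))
    coefficients <- list(fluid = c(0.85, -0.20, 0.05),
                         collagen = c(0.10, 0.05, 0.10))
  polyval <- function(cf, z) {
    out <- 0
    for (k in seq_along(cf)) out <- out + cf[k] * z^(k - 1)
    out
  }
  phi_f <- polyval(coefficients$fluid, z)
  phi_co <- polyval(coefficients$collagen, z)
  phi_pg <- 1 - phi_f - phi_co
  if (any(phi_f < 0 | phi_f > 1 | phi_co < 0 | phi_co > 1 | phi_pg < 0))
    stop("reference profile coefficients produce fractions outside [0, 1]")
  data.frame(z = z, phi_f = phi_f, phi_co = phi_co, phi_pg = phi_pg)
}

#' Calibrate the exponential relaxation-time/composition relation
#'
#' Least-squares fit of `Tx(phi) = a * exp(b * phi) + c` relating a
#' constituent's volume fraction to a relaxation time. The calibration stores
#' its domain of definition (the Tx range spanned by the training pairs) and
#' the clamp constants `l` and `u` (the phi values at the lower and upper Tx
#' bound) used to extend the inverse continuously outside the domain.
#'
#' The fit profiles the nonlinearity: for each candidate rate `b` on a signed
#' grid, `(a, c)` solve a linear least-squares problem; the best triple is
#' polished by Levenberg-Marquardt.
#'
#' @param phi Volume fractions (training inputs), at least 4 values spanning
#'   a nondegenerate interval.
#' @param tx Relaxation times in ms, same length as `phi`.
#' @param constituent `"f"` (fluid) or `"co"` (collagen); metadata.
#' @param modality Modality label; metadata.
#' @return An object of class `exponential_calibration` with fields `a`, `b`,
#'   `c`, `tx_lo`, `tx_up`, `l`, `u`.
#' @export
calibrate_exponential <- function(phi, tx, constituent = "f", modality = "T2") {
  phi <- as.numeric(phi); tx <- as.numeric(tx)
  if (length(phi) != length(tx)) stop("'phi' and 'tx' must have equal length")
  if (length(phi) < 4L) stop("need at least 4 calibration pairs")
  if (diff(range(phi)) < 1e-6) stop("calibration error: phi values are degenerate")
  if (stats::sd(tx) < 1e-10 * (abs(mean(tx)) + 1))
    stop("calibration error: relaxation times do not vary (b unidentifiable)")

  # profile b: (a, c) linear given b
  sse_for <- function(b) {
    X <- cbind(exp(b * phi), 1)
    fit <- stats::lm.fit(X, tx)
    list(sse = sum(fit$residuals^2), a = fit$coefficients[1], c = fit$coefficients[2])
  }
  grid <- c(-exp(seq(log(0.1), log(30), length.out = 40)),
            exp(seq(log(0.1), log(30), length.out = 40)))
  sses <- vapply(grid, function(b) sse_for(b)$sse, numeric(1))
  b0 <- grid[which.min(sses)]
  p0 <- with(sse_for(b0), c(a, b0, c))
  res <- minpack.lm::nls.lm(
    par = unname(p0), fn = function(p) p[1] * exp(p[2] * phi) + p[3] - tx,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  p <- unname(res$par)
  if (abs(p[1]) < 1e-12 || abs(p[2]) < 1e-8)
    stop("calibration error: degenerate exponential (a or b ~ 0)")
  fwd <- function(phi) p[1] * exp(p[2] * phi) + p[3]
  phi_lo <- min(phi); phi_up <- max(phi)
  tx_ends <- sort(c(fwd(phi_lo), fwd(phi_up)))
  increasing <- fwd(phi_up) > fwd(phi_lo)
  structure(
    list(a = p[1], b = p[2], c = p[3],
         constituent = constituent, modality = modality,
         tx_lo = tx_ends[1], tx_up = tx_ends[2],
         # clamp constants: phi at the lower / upper Tx bound of definition
         l = if (increasing) phi_lo else phi_up,
         u = if (increasing) phi_up else phi_lo),
    class = "exponential_calibration"
  )
}

#' @export
print.exponential_calibration <- function(x, ...) {
  cat(sprintf("<exponential_calibration> %s(%s): Tx = %.4g exp(%.4g phi) + %.4g on [%.4g, %.4g] ms\n",
              x$modality, x$constituent, x$a, x$b, x$c, x$tx_lo, x$tx_up))
  invisible(x)
}

#' Invert an exponential calibration
#'
#' Maps a relaxation time to a volume fraction by inverting
#' `Tx(phi) = a exp(b phi) + c`:
#' `phi = log((Tx - c)/a) / b` inside the calibration domain, continuously
#' extended by the constants `l` (at or below the lower bound of definition)
#' and `u` (at or above the upper bound), making the inverse a total,
#' continuous and monotone function of Tx.
#'
#' @param cal An [calibrate_exponential()] result.
#' @param tx Relaxation time(s) in ms.
#' @return Volume fraction(s).
#' @export
invert_calibration <- function(cal, tx) {
  stopifnot(inherits(cal, "exponential_calibration"))
  if (any(is.na(tx))) stop("NaN/NA relaxation time")
  tx <- pmin(pmax(tx, cal$tx_lo), cal$tx_up)
  arg <- (tx - cal$c) / cal$a
  phi <- ifelse(arg > 0, log(pmax(arg, .Machine$double.xmin)) / cal$b, NA_real_)
  # clamp exactly at/beyond the bounds of definition (l, u are the phi
  # values at the lower/upper Tx bound, stored by the calibration)
  phi[tx <= cal$tx_lo] <- cal$l
  phi[tx >= cal$tx_up] <- cal$u
  unname(phi)
}

#' Fit a rational depth profile
#'
#' Phenomenological one-dimensional representation of a volume fraction over
#' the normalized depth z: a cubic-over-linear rational function
#' `phi(z) = (alpha z^3 + beta z^2 + gamma z + delta) / (eps z + kappa)`.
#' Numerator and denominator share a common scale, so the gauge `kappa = 1`
#' is fixed to make the coefficients identifiable. The denominator is kept
#' strictly positive on \[0, 1\] by bounding `eps > -1`.
#'
#' @param z Normalized depths (at least 7 points spanning \[0, 1\]).
#' @param phi Volume fractions at `z`.
#' @return An object of class `rational_depth_fit` with coefficients
#'   `alpha`, `beta`, `gamma`, `delta`, `eps` (`kappa` fixed at 1); evaluate
#'   with [predict()].
#' @export
fit_depth_profile <- function(z, phi) {
  z <- as.numeric(z); phi <- as.numeric(phi)
  if (length(z) != length(phi)) stop("'z' and 'phi' must have equal length")
  if (length(z) < 7L) stop("need at least 7 depth samples")
  if (min(z) > 0.15 || max(z) < 0.85)
    stop("depth samples must span the normalized depth interval [0, 1]")
  # start from the cubic polynomial fit (eps = 0)
  X <- cbind(z^3, z^2, z, 1)
  p0 <- c(stats::lm.fit(X, phi)$coefficients, 0)
  res <- minpack.lm::nls.lm(
    par = unname(p0),
    fn = function(p) (p[1] * z^3 + p[2] * z^2 + p[3] * z + p[4]) / (p[5] * z + 1) - phi,
    lower = c(-Inf, -Inf, -Inf, -Inf, -0.95),
    upper = c(Inf, Inf, Inf, Inf, 50),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  p <- unname(res$par)
  fit <- structure(
    list(alpha = p[1], beta = p[2], gamma = p[3], delta = p[4],
         eps = p[5], kappa = 1),
    class = "rational_depth_fit")
  chk <- predict(fit, seq(0, 1, length.out = 101))
  if (any(chk < -1e-6 | chk > 1 + 1e-6))
    warning("fitted depth profile leaves [0, 1] on the unit interval")
  fit
}

#' @export
predict.rational_depth_fit <- function(object, newdata = seq(0, 1, length.out = 50), ...) {
  z <- as.numeric(newdata)
  with(object, (alpha * z^3 + beta * z^2 + gamma * z + delta) / (eps * z + kappa))
}

#' @export
print.rational_depth_fit <- function(x, ...) {
  cat(sprintf("<rational_depth_fit> (%.4g z^3 + %.4g z^2 + %.4g z + %.4g) / (%.4g z + 1)\n",
              x$alpha, x$beta, x$gamma, x$delta, x$eps))
  invisible(x)
}

#' Modality weights for the composition combination
#'
#' One weight per modality (T1, T1rho, T2, T2*) and constituent, subject to
#' the normalization condition that each constituent's weights sum to 1.
#' Defaults are the identified global set: fluid (0.41, 0.42, 0.16, 0.01),
#' collagen (0.31, 0.12, 0.11, 0.46).
#'
#' @param fluid,collagen Numeric vectors of 4 non-negative weights, in the
#'   order T1, T1rho, T2, T2*; each must sum to 1 within 1e-8.
#' @return An object of class `weight_set`: a 2 x 4 numeric matrix with rows
#'   `f`, `co` and columns `T1`, `T1rho`, `T2`, `T2star`.
#' @export
weight_set <- function(fluid = c(0.41, 0.42, 0.16, 0.01),
                       collagen = c(0.31, 0.12, 0.11, 0.46)) {
  w <- rbind(f = as.numeric(fluid), co = as.numeric(collagen))
  colnames(w) <- c("T1", "T1rho", "T2", "T2star")
  if (any(w < 0) || any(w > 1))
    stop("weights must lie in [0, 1]")
  if (any(abs(rowSums(w) - 1) > 1e-8))
    stop("normalization error: each constituent's weights must sum to 1 (tol 1e-8)")
  structure(w, class = c("weight_set", "matrix"))
}

#' Depth-resolved composition field
#'
#' Validated container for the fluid, collagen and proteoglycan volume
#' fractions on a normalized depth grid, enforcing the saturation condition
#' `phi_pg + phi_f + phi_co = 1` and a minimally positive proteoglycan
#' fraction (`phi_pg >= delta_tol`).
#'
#' @param z Depth grid in \[0, 1\], increasing.
#' @param phi_f,phi_co Fluid and collagen volume fractions on `z`.
#' @param delta_tol Positivity tolerance for the proteoglycan remainder
#'   (default 1e-6).
#' @return An object of class `composition_field`.
#' @export
composition_field <- function(z, phi_f, phi_co, delta_tol = 1e-6) {
  z <- as.numeric(z)
  stopifnot(length(z) == length(phi_f), length(z) == length(phi_co))
  if (any(z < 0 | z > 1) || any(diff(z) <= 0))
    stop("'z' must be increasing within [0, 1]")
  phi_pg <- 1 - phi_f - phi_co
  bad <- which(phi_pg < delta_tol)
  if (length(bad))
    stop(sprintf(paste0("saturation error: proteoglycan fraction below %.1g at ",
                        "z = %.4g (phi_f + phi_co = %.6g)"),
                 delta_tol, z[bad[1]], phi_f[bad[1]] + phi_co[bad[1]]))
  if (any(phi_f < 0 | phi_f > 1 | phi_co < 0 | phi_co > 1))
    stop("volume fractions must lie in [0, 1]")
  structure(
    list(z = z, phi_f = phi_f, phi_co = phi_co, phi_pg = phi_pg,
         delta_tol = delta_tol),
    class = "composition_field")
}

#' @export
print.composition_field <- function(x, ...) {
  cat(sprintf("<composition_field> %d depths; phi_f %.3f..%.3f, phi_co %.3f..%.3f, phi_pg %.3f..%.3f\n",
              length(x$z), min(x$phi_f), max(x$phi_f), min(x$phi_co),
              max(x$phi_co), min(x$phi_pg), max(x$phi_pg)))
  invisible(x)
}

#' Combine per-modality depth profiles into a composition field
#'
#' Weighted combination of the four modality-specific volume-fraction
#' profiles per constituent,
#' `Phi_xi(z) = sum_x w_x^xi * phi_xi^x(z)`, with the proteoglycan fraction
#' obtained as the saturation remainder `1 - Phi_f - Phi_co`. Raises a
#' saturation error (naming the offending depth) if the remainder falls below
#' the positivity tolerance anywhere on the grid.
#'
#' @param fits Named list with elements `f` and `co`, each a named list of
#'   four [fit_depth_profile()] objects (or plain functions of z) keyed
#'   `T1`, `T1rho`, `T2`, `T2star`.
#' @param weights A [weight_set()].
#' @param z_grid Depth grid (default 101 uniform points).
#' @param delta_tol Positivity tolerance for the proteoglycan remainder.
#' @return A [composition_field()].
#' @export
combine_fractions <- function(fits, weights = weight_set(),
                              z_grid = seq(0, 1, length.out = 101),
                              delta_tol = 1e-6) {
  if (!inherits(weights, "weight_set")) weights <- do.call(weight_set, weights)
  modalities <- colnames(weights)
  eval_profile <- function(obj, z) {
    if (inherits(obj, "rational_depth_fit")) predict(obj, z)
    else if (is.function(obj)) obj(z)
    else stop("profile must be a rational_depth_fit or a function of z")
  }
  total <- function(constituent) {
    acc <- numeric(length(z_grid))
    for (m in modalities)
      acc <- acc + weights[constituent, m] * eval_profile(fits[[constituent]][[m]], z_grid)
    acc
  }
  composition_field(z_grid, total("f"), total("co"), delta_tol = delta_tol)
}
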