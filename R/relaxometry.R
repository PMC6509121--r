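#' Acquisition protocol for a quantitative MRI sequence
#'
#' Describes the timing grid of one relaxometry sequence: inversion times
#' (T1), spin-lock durations (T1rho) or echo times (T2, T2*), together with
#' the repetition time and the echo-time cutoff applied to multi-echo decays.
#'
#' @param modality One of `"T1"`, `"T1rho"`, `"T2"`, `"T2star"`.
#' @param timings Numeric vector of timing values in ms (TI for T1, TSL for
#'   T1rho, TE for T2/T2*), strictly increasing. All must be positive except
#'   that a spin-lock duration of 0 is allowed for T1rho.
#' @param TR Repetition time in ms. Required for T1 (it enters the
#'   inversion-recovery signal model) and must exceed the largest inversion
#'   time; otherwise metadata.
#' @param TE_cutoff Echo-time cutoff in ms; echoes beyond this value are
#'   excluded from T2 and T2* fitting. Default 60.
#' @return An object of class `acquisition_protocol`.
#' @seealso [default_protocol()] for the acquisition grids used throughout,
#'   [model_signal()], [fit_signal_model()].
#' @export
acquisition_protocol <- function(modality, timings, TR = NULL, TE_cutoff = 60) {
  modality <- match.arg(modality, c("T1", "T1rho", "T2", "T2star"))
  timings <- as.numeric(timings)
  if (length(timings) < 2L || any(!is.finite(timings)))
    stop("'timings' must be a finite numeric vector of length >= 2")
  if (any(diff(timings) <= 0))
    stop("'timings' must be strictly increasing")
  min_allowed <- if (modality == "T1rho") 0 else .Machine$double.eps
  if (any(timings < min_allowed))
    stop("timing values must be positive (a spin-lock time of 0 is allowed for T1rho)")
  if (modality == "T1") {
    if (is.null(TR))
      stop("T1 inversion recovery requires the repetition time 'TR'")
    if (TR <= max(timings))
      stop("'TR' must exceed the largest inversion time")
  }
  structure(
    list(modality = modality, timings = timings, TR = TR,
         TE_cutoff = TE_cutoff),
    class = "acquisition_protocol"
  )
}

#' Default acquisition protocols
#'
#' Timing grids of the clinical 3.0 T protocol driving all defaults:
#' inversion recovery with TI = 150, 300, 500, 800, 1000, 1500 ms and
#' TR = 3000 ms for T1; spin-lock durations 0, 10, 20, 30, 40 ms for T1rho;
#' multi-spin-echo TE = n * 8.38 ms (n = 1..12) for T2; multi-gradient-echo
#' TE = 3.9 + n * 9.6 ms (n = 1..14) for T2*.
#'
#' @param modality One of `"T1"`, `"T1rho"`, `"T2"`, `"T2star"`.
#' @return An [acquisition_protocol()] object.
#' @export
default_protocol <- function(modality = c("T1", "T1rho", "T2", "T2star")) {
  modality <- match.arg(modality)
  switch(modality,
    T1     = acquisition_protocol("T1", c(150, 300, 500, 800, 1000, 1500), TR = 3000),
    T1rho  = acquisition_protocol("T1rho", c(0, 10, 20, 30, 40), TR = 30),
    T2     = acquisition_protocol("T2", 8.38 * (1:12), TR = 1500),
    T2star = acquisition_protocol("T2star", 3.9 + 9.6 * (1:14), TR = 700)
  )
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf("<acquisition_protocol> %s: %d timings [%g..%g ms]",
              x$modality, length(x$timings), min(x$timings), max(x$timings)))
  if (!is.null(x$TR)) cat(sprintf(", TR = %g ms", x$TR))
  cat(sprintf(", TE cutoff = %g ms\n", x$TE_cutoff))
  invisible(x)
}

# Signed (pre-magnitude) inversion-recovery signal.
.ir_signed <- function(A, T1, TI, TR) {
  A * (1 - 2 * exp(-TI / T1) + exp(-TR / T1))
}

#' Model-predicted signal magnitudes
#'
#' Evaluates the relaxometry signal model of the protocol's modality at the
#' protocol timings: magnitude inversion recovery
#' `|A (1 - 2 exp(-TI/T1) + exp(-TR/T1))|` for T1, the monoexponential
#' spin-lock decay `A exp(-TSL/T1rho)` for T1rho, the offset exponential
#' `A exp(-TE/T2) + B` for T2, and `A exp(-TE/T2*)` for T2*.
#'
#' @param fit A list or `signal_model_fit` with elements `relaxation_time`
#'   (ms), `amplitude` and, for T2, `offset` (defaults to 0).
#' @param protocol An [acquisition_protocol()].
#' @return Numeric vector of predicted magnitudes at `protocol$timings`.
#' @export
model_signal <- function(fit, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  Trel <- fit$relaxation_time
  if (!is.numeric(Trel) || length(Trel) != 1L || !is.finite(Trel) || Trel <= 0)
    stop("relaxation time must be a single positive number")
  A <- fit$amplitude
  B <- if (is.null(fit$offset)) 0 else fit$offset
  t <- protocol$timings
  switch(protocol$modality,
    T1     = abs(.ir_signed(A, Trel, t, protocol$TR)),
    T1rho  = A * exp(-t / Trel),
    T2     = A * exp(-t / Trel) + B,
    T2star = A * exp(-t / Trel)
  )
}

# adjusted R^2 = 1 - (1 - R^2)(n - 1)/(n - p - 1)
.adjusted_r2 <- function(y, yhat, n_par) {
  n <- length(y)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(-Inf)
  r2 <- 1 - ss_res / ss_tot
  if (n - n_par - 1 <= 0) return(-Inf)
  1 - (1 - r2) * (n - 1) / (n - n_par - 1)
}

.new_fit <- function(modality, Trel, A, B, adj_r2, converged = TRUE) {
  structure(
    list(modality = modality, relaxation_time = unname(Trel),
         amplitude = unname(A), offset = unname(B),
         adjusted_r2 = unname(adj_r2), converged = converged),
    class = "signal_model_fit"
  )
}

#' @export
print.signal_model_fit <- function(x, ...) {
  cat(sprintf("<signal_model_fit> %s = %.4g ms, A = %.4g, B = %.4g, adj. R2 = %.6g%s\n",
              x$modality, x$relaxation_time, x$amplitude, x$offset, x$adjusted_r2,
              if (isTRUE(x$converged)) "" else " (NOT CONVERGED)"))
  invisible(x)
}

# Monoexponential decay fit A exp(-t/T) [+ B], Levenberg-Marquardt with a
# log-linearized start. Returns NULL on non-convergence.
.fit_exp_decay <- function(t, y, with_offset) {
  # start values: subtract a provisional offset, regress log magnitude on t
  B0 <- if (with_offset) max(0, min(y) - 0.05 * diff(range(y))) else 0
  pos <- (y - B0) > 0
  if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(y[pos] - B0) ~ t[pos]))
    T0 <- if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else diff(range(t))
    A0 <- exp(cf[1])
  } else {
    T0 <- diff(range(t))
    A0 <- max(y)
  }
  T0 <- min(max(T0, 1e-2), 1e4)
  resid_fn <- if (with_offset) {
    function(p) p[2] * exp(-t / p[1]) + p[3] - y
  } else {
    function(p) p[2] * exp(-t / p[1]) - y
  }
  p0 <- if (with_offset) c(T0, A0, B0) else c(T0, A0)
  lower <- if (with_offset) c(1e-3, 0, -Inf) else c(1e-3, 0)
  res <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                       control = minpack.lm::nls.lm.control(maxiter = 200,
                                                            ftol = 1e-14,
                                                            ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(res) || res$info %in% c(0, 9)) return(NULL)
  res$par
}

# Magnitude inversion-recovery fit with polarity restoration: the sign of the
# pre-magnitude signal is unknown per inversion time, so every contiguous
# negative-prefix polarity split is tried and the split with least squared
# error wins.
.fit_ir <- function(TI, y, TR) {
  best <- NULL
  n <- length(TI)
  for (k in 0:n) {
    sgn <- rep(1, n); if (k > 0) sgn[seq_len(k)] <- -1
    ys <- sgn * y
    # null point between TI_k and TI_{k+1} gives the T1 start
    TInull <- if (k == 0) TI[1] / 2 else if (k == n) 1.5 * TI[n] else (TI[k] + TI[k + 1]) / 2
    T10 <- max(TInull / log(2), 1)
    resid_fn <- function(p) .ir_signed(p[2], p[1], TI, TR) - ys
    res <- tryCatch(
      minpack.lm::nls.lm(par = c(T10, max(abs(y))), fn = resid_fn,
                         lower = c(1e-2, 0),
                         control = minpack.lm::nls.lm.control(maxiter = 200,
                                                              ftol = 1e-14,
                                                              ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res) || res$info %in% c(0, 9)) next
    sse <- sum((abs(.ir_signed(res$par[2], res$par[1], TI, TR)) - y)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = res$par, sse = sse)
  }
  if (is.null(best)) NULL else best$par
}

#' Fit a relaxometry signal model to one pixel's signal series
#'
#' Nonlinear least-squares estimation of the relaxation time (and signal
#' amplitude; plus the constant offset for T2) from magnitudes measured on a
#' timing grid. For T2 and T2* only echoes with TE at or below the protocol's
#' `TE_cutoff` (default 60 ms) enter the fit, to avoid mis-fitting from late
#' low-SNR echoes. Fit quality is reported as R-squared adjusted to the
#' degrees of freedom; noise-free data yield an adjusted R-squared of 1.
#'
#' The T1 inversion-recovery model is fitted on magnitude data by polarity
#' restoration (all contiguous sign splits are tried, least squared error
#' wins). T2/T2*/T1rho decays are started from a log-linearized regression and
#' refined by Levenberg-Marquardt.
#'
#' @param series Numeric vector of non-negative signal magnitudes, one per
#'   protocol timing (or a list with elements `timings` and `magnitudes`).
#' @param protocol An [acquisition_protocol()].
#' @return A `signal_model_fit` with elements `relaxation_time` (ms),
#'   `amplitude`, `offset` (0 except for T2), `adjusted_r2` and `converged`.
#'   A non-convergent fit is returned flagged with `adjusted_r2 = -Inf`
#'   rather than raising an error; degenerate input (constant magnitudes)
#'   raises an unidentifiable-fit error.
#' @export
fit_signal_model <- function(series, protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (is.list(series)) {
    if (!isTRUE(all.equal(as.numeric(series$timings), protocol$timings)))
      stop("series timings do not match the protocol")
    series <- series$magnitudes
  }
  y <- as.numeric(series)
  t <- protocol$timings
  if (length(y) != length(t))
    stop("series length does not match the protocol timing grid")
  if (any(y < 0) || any(!is.finite(y)))
    stop("magnitudes must be finite and non-negative")

  # echo-time filter for the multi-echo decays
  if (protocol$modality %in% c("T2", "T2star")) {
    keep <- t <= protocol$TE_cutoff
    t <- t[keep]; y <- y[keep]
  }
  n_par <- switch(protocol$modality, T1 = 2L, T1rho = 2L, T2 = 3L, T2star = 2L)
  if (length(t) < n_par + 1L)
    stop(sprintf("need at least %d timing points after the echo-time filter", n_par + 1L))
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1))
    stop("unidentifiable fit: signal magnitudes are constant")

  par <- switch(protocol$modality,
    T1     = .fit_ir(t, y, protocol$TR),
    T1rho  = .fit_exp_decay(t, y, with_offset = FALSE),
    T2     = .fit_exp_decay(t, y, with_offset = TRUE),
    T2star = .fit_exp_decay(t, y, with_offset = FALSE)
  )
  if (is.null(par))
    return(.new_fit(protocol$modality, NA_real_, NA_real_, 0, -Inf, converged = FALSE))
  Trel <- par[1]; A <- par[2]
  B <- if (protocol$modality == "T2") par[3] else 0
  if (abs(A) < 1e-12)
    stop("unidentifiable fit: estimated amplitude is zero")
  sub <- acquisition_protocol(protocol$modality, t, TR = protocol$TR,
                              TE_cutoff = protocol$TE_cutoff)
  yhat <- model_signal(list(relaxation_time = Trel, amplitude = A, offset = B), sub)
  .new_fit(protocol$modality, Trel, A, B, .adjusted_r2(y, yhat, n_par))
}

# 4-connected binary erosion with configurable radius (diamond structuring
# element); radius 0 is a no-op.
.erode_mask <- function(mask, radius = 1L) {
  if (radius <= 0) return(mask)
  r <- as.integer(radius)
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "diamond")
  # pad with background so pixels at the image border count as boundary
  padded <- matrix(0, nrow(mask) + 2L * r, ncol(mask) + 2L * r)
  padded[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- as.numeric(mask)
  out <- EBImage::erode(padded, kern)
  matrix(out[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] > 0.5,
         nrow(mask), ncol(mask))
}

#' Construct a quantitative parameter map
#'
#' @param values Numeric matrix of relaxation times (ms); `NA` where no valid
#'   fit exists.
#' @param quality Numeric matrix of adjusted R-squared values (`-Inf` flags a
#'   failed fit).
#' @param mask Logical matrix of fitted pixels.
#' @param modality Modality label.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, quality, mask, modality = "T2") {
  stopifnot(is.matrix(values), is.matrix(quality), is.matrix(mask),
            all(dim(values) == dim(mask)), all(dim(quality) == dim(mask)))
  ok <- mask & is.finite(quality)
  if (any(ok & (!is.finite(values) | values <= 0)))
    stop("parameter map values must be finite and positive wherever fitted")
  structure(list(values = values, quality = quality, mask = mask,
                 modality = modality),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  ok <- x$mask & is.finite(x$quality)
  cat(sprintf("<parameter_map> %s %dx%d, %d fitted pixels, median %.4g ms, median adj. R2 %.4g\n",
              x$modality, nrow(x$values), ncol(x$values), sum(ok),
              stats::median(x$values[ok]), stats::median(x$quality[ok])))
  invisible(x)
}

#' Fit a parameter map from a co-registered image stack
#'
#' Runs [fit_signal_model()] for every pixel of a tissue mask after excluding
#' boundary pixels (one-pixel 4-connected erosion by default) to avoid
#' partial-volume effects. Pixels whose fit does not converge are flagged with
#' an adjusted R-squared of `-Inf` and an `NA` value; an optional quality
#' threshold additionally masks poorly fitted pixels.
#'
#' @param stack 3-D numeric array (rows x cols x timings) of signal
#'   magnitudes, co-registered across timings.
#' @param protocol An [acquisition_protocol()]; `dim(stack)[3]` must equal the
#'   number of protocol timings.
#' @param mask Logical matrix (rows x cols) of tissue pixels.
#' @param erode_radius Boundary-exclusion radius in pixels (default 1). If
#'   erosion would empty the mask, it is skipped with a warning and the
#'   original pixels are retained.
#' @param quality_threshold Optional minimum adjusted R-squared; pixels below
#'   it are removed from the returned mask (none by default).
#' @return A [parameter_map()].
#' @export
build_parameter_map <- function(stack, protocol, mask, erode_radius = 1L,
                                quality_threshold = NULL) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  d <- dim(stack)
  if (length(d) != 3L || d[3] != length(protocol$timings))
    stop("'stack' must be rows x cols x timings matching the protocol")
  mask <- matrix(as.logical(mask), d[1], d[2])
  if (!any(mask)) stop("'mask' is empty")
  eroded <- .erode_mask(mask, erode_radius)
  if (!any(eroded)) {
    warning("boundary erosion would remove every masked pixel; erosion skipped")
    eroded <- mask
  }
  values <- matrix(NA_real_, d[1], d[2])
  quality <- matrix(NA_real_, d[1], d[2])
  idx <- which(eroded, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    fit <- tryCatch(fit_signal_model(stack[r, c, ], protocol),
                    error = function(e) NULL)
    if (is.null(fit)) {
      quality[r, c] <- -Inf
    } else {
      values[r, c] <- fit$relaxation_time
      quality[r, c] <- fit$adjusted_r2
    }
  }
  if (!is.null(quality_threshold)) {
    bad <- eroded & (!is.finite(quality) | quality < quality_threshold)
    eroded[bad] <- FALSE
  }
  parameter_map(values, quality, eroded, modality = protocol$modality)
}
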