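#' Squared Pearson correlation between measured and modelled values
#'
#' Goodness of fit as the square of Pearson's correlation coefficient.
#' Note this measure is invariant to scale and offset of the modelled
#' values; the complementary relative error [relative_error_omega()]
#' captures magnitude mismatch.
#'
#' @param y Measured values (length >= 3, nonconstant).
#' @param f Modelled values, same length.
#' @return R-squared in \[0, 1\].
#' @export
r_squared <- function(y, f) {
  y <- as.numeric(y); f <- as.numeric(f)
  if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
  if (length(y) < 3L) stop("need at least 3 points")
  if (stats::sd(y) == 0) stop("undefined correlation: 'y' is constant")
  if (stats::sd(f) == 0) stop("undefined correlation: 'f' is constant")
  stats::cor(y, f)^2
}

#' Relative approximated error (percent)
#'
#' `Omega = 100 * ||y - f|| / ||y||` (Euclidean norms): the scale-aware
#' complement to [r_squared()].
#'
#' @inheritParams r_squared
#' @return Omega in percent (>= 0).
#' @export
relative_error_omega <- function(y, f) {
  y <- as.numeric(y); f <- as.numeric(f)
  if (length(y) != length(f)) stop("'y' and 'f' must have equal length")
  ny <- sqrt(sum(y^2))
  if (ny == 0) stop("||y|| must be positive")
  100 * sqrt(sum((y - f)^2)) / ny
}

#' A sample for global parameter identification
#'
#' Bundles one specimen's modality-specific depth profiles (fluid and
#' collagen, per T1/T1rho/T2/T2*), thickness, loading protocol and measured
#' relaxed stress-strain curve. The profiles are combined into a composition
#' field by the candidate weights during optimization.
#'
#' @param profiles Named list with elements `f` and `co`, each a named list
#'   of four depth profiles ([fit_depth_profile()] objects or functions of
#'   z), keyed `T1`, `T1rho`, `T2`, `T2star`.
#' @param thickness Sample thickness in mm.
#' @param protocol A [loading_protocol()].
#' @param measured Numeric vector of measured relaxed nominal stresses (MPa)
#'   at the protocol strains.
#' @param id Optional sample label.
#' @return An object of class `cartilage_sample`.
#' @export
cartilage_sample <- function(profiles, thickness, protocol, measured,
                             id = NULL) {
  stopifnot(inherits(protocol, "loading_protocol"))
  if (length(measured) != length(protocol$strains))
    stop("'measured' must match the protocol strain levels")
  structure(list(profiles = profiles, thickness = thickness,
                 protocol = protocol, measured = as.numeric(measured),
                 id = id),
            class = "cartilage_sample")
}

#' Global parameter set (material constants + modality weights)
#'
#' @param params A [material_parameters()] set.
#' @param weights A [weight_set()].
#' @return An object of class `global_parameter_set`.
#' @export
global_parameter_set <- function(params = material_parameters(),
                                 weights = weight_set()) {
  stopifnot(inherits(params, "material_parameters"),
            inherits(weights, "weight_set"))
  structure(list(params = params, weights = weights),
            class = "global_parameter_set")
}

#' @export
print.global_parameter_set <- function(x, ...) {
  print(x$params)
  cat("  fluid weights:    ", paste(sprintf("%.3f", x$weights["f", ]), collapse = " "), "\n")
  cat("  collagen weights: ", paste(sprintf("%.3f", x$weights["co", ]), collapse = " "), "\n")
  invisible(x)
}

# forward-model one sample under a candidate global set
.simulate_sample <- function(sample, theta, n_layers = 20L,
                             z_grid = seq(0, 1, length.out = 101)) {
  comp <- combine_fractions(sample$profiles, theta$weights, z_grid = z_grid)
  mesh <- build_column(comp, theta$params, thickness = sample$thickness,
                       n_layers = n_layers)
  simulate_protocol(mesh, sample$protocol)$curve$stress
}

#' Objective function of the global inverse fit
#'
#' Sum over samples of per-sample-normalized squared residuals between
#' simulated and measured relaxed stresses at the protocol strains:
#' `sum_s ||y_s - f_s||^2 / ||y_s||^2`. Normalization by each sample's
#' measured norm prevents stiff samples from dominating. A simulation
#' failure under the candidate parameters (e.g. compaction) contributes a
#' large penalty instead of raising.
#'
#' @param samples List of [cartilage_sample()] objects.
#' @param theta A [global_parameter_set()].
#' @param n_layers Layers of the forward column (default 20).
#' @param penalty Value contributed by a failed forward solve (default 1e6).
#' @return Scalar objective (0 iff every modelled curve equals its
#'   measurement).
#' @export
objective <- function(samples, theta, n_layers = 20L, penalty = 1e6) {
  stopifnot(inherits(theta, "global_parameter_set"))
  total <- 0
  for (s in samples) {
    f <- tryCatch(.simulate_sample(s, theta, n_layers = n_layers),
                  error = function(e) NULL)
    if (is.null(f)) {
      total <- total + penalty
    } else {
      total <- total + sum((s$measured - f)^2) / sum(s$measured^2)
    }
  }
  total
}

# pack/unpack the optimization vector:
# (k1, k2, k3, a0, a1, w, wf[1..4], wc[1..4]) with weight rows normalized
# to sum 1 inside the objective and on output.
.theta_pack <- function(theta) {
  p <- theta$params
  c(p$k1, p$k2, p$k3, p$a0, p$a1, p$w,
    as.numeric(theta$weights["f", ]), as.numeric(theta$weights["co", ]))
}

.theta_unpack <- function(x) {
  wf <- x[7:10] / sum(x[7:10])
  wc <- x[11:14] / sum(x[11:14])
  global_parameter_set(
    material_parameters(k1 = x[1], k2 = x[2], k3 = x[3],
                        a0 = x[4], a1 = x[5], w = x[6]),
    weight_set(fluid = wf, collagen = wc))
}

#' Default box bounds of the global fit
#'
#' @return List with numeric vectors `lower` and `upper` over the packed
#'   parameter vector (k1, k2, k3, a0, a1, w, 4 fluid weights, 4 collagen
#'   weights).
#' @export
default_bounds <- function() {
  list(lower = c(0.05, 5, 2, 0.05, 1, 0.05, rep(1e-3, 8)),
       upper = c(5, 200, 100, 2, 12, 0.95, rep(1, 8)))
}

#' Global constrained identification of material parameters and weights
#'
#' Bound-constrained minimization of [objective()] over the six material
#' constants and the eight modality weights, updating the parameters for all
#' samples simultaneously (a single global set). The per-constituent weight
#' normalization (sum = 1) is enforced by projection inside the objective
#' and on the returned set, so the output always satisfies it. Multi-start:
#' the supplied start plus `n_starts - 1` seeded random feasible starts;
#' best local minimum wins.
#'
#' @param samples List of [cartilage_sample()] objects.
#' @param theta0 Feasible starting [global_parameter_set()].
#' @param bounds List with `lower`/`upper` over the packed vector, see
#'   [default_bounds()].
#' @param n_starts Number of optimizer starts (default 5).
#' @param seed Seed for the random restarts (default 1).
#' @param n_layers Forward-model layers (default 20).
#' @param control Passed to [stats::optim()] (method `"L-BFGS-B"`).
#' @return List with `theta` (the identified [global_parameter_set()]),
#'   `report` (a `fit_report`: per-sample R-squared and Omega, objective,
#'   convergence) and `starts` (objective value per start).
#' @export
optimize_global <- function(samples, theta0 = global_parameter_set(),
                            bounds = default_bounds(), n_starts = 5L,
                            seed = 1L, n_layers = 20L,
                            control = list(maxit = 200, factr = 1e9)) {
  stopifnot(inherits(theta0, "global_parameter_set"))
  x0 <- .theta_pack(theta0)
  if (any(x0 < bounds$lower) || any(x0 > bounds$upper))
    stop("infeasible start: theta0 violates the bounds")
  # optimize in scaled coordinates so the finite-difference gradient sees
  # comparable relative steps across parameters of very different magnitude
  scale <- pmax(abs(.theta_pack(global_parameter_set())), 0.05)
  fn <- function(y) objective(samples, .theta_unpack(y * scale),
                              n_layers = n_layers)
  if (fn(x0 / scale) >= 1e6)
    stop("infeasible start: forward model fails for every sample at theta0")

  starts <- list(x0)
  if (n_starts > 1L) {
    rng <- .seeded_rng(seed)
    for (k in seq_len(n_starts - 1L)) {
      span <- bounds$upper - bounds$lower
      starts[[k + 1L]] <- pmin(pmax(
        x0 * stats::runif(length(x0), 0.6, 1.6),
        bounds$lower + 0.02 * span), bounds$upper - 0.02 * span)
    }
    rng$restore()
  }
  best <- NULL
  start_values <- numeric(length(starts))
  for (k in seq_along(starts)) {
    res <- tryCatch(
      stats::optim(starts[[k]] / scale, fn, method = "L-BFGS-B",
                   lower = bounds$lower / scale, upper = bounds$upper / scale,
                   control = control),
      error = function(e) NULL)
    if (is.null(res)) { start_values[k] <- NA_real_; next }
    start_values[k] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- .theta_unpack(best$par * scale)
  report <- fit_report(samples, theta, n_layers = n_layers,
                       objective_value = best$value,
                       convergence = best$convergence)
  list(theta = theta, report = report, starts = start_values)
}

#' Per-sample goodness-of-fit report
#'
#' @param samples List of [cartilage_sample()] objects.
#' @param theta A [global_parameter_set()].
#' @param n_layers Forward-model layers.
#' @param objective_value,convergence Optional diagnostics stored verbatim.
#' @return An object of class `fit_report`: data.frame `per_sample` with
#'   columns `id`, `r_squared`, `omega_pct`, plus `objective` and
#'   `convergence`.
#' @export
fit_report <- function(samples, theta, n_layers = 20L,
                       objective_value = NULL, convergence = NULL) {
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    f <- .simulate_sample(s, theta, n_layers = n_layers)
    data.frame(id = if (is.null(s$id)) paste0("sample", i) else s$id,
               r_squared = r_squared(s$measured, f),
               omega_pct = relative_error_omega(s$measured, f))
  })
  structure(list(per_sample = do.call(rbind, rows),
                 objective = if (is.null(objective_value))
                   objective(samples, theta, n_layers = n_layers)
                 else objective_value,
                 convergence = convergence),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report> objective =", format(x$objective, digits = 6), "\n")
  print(x$per_sample, row.names = FALSE)
  invisible(x)
}

#' One-dimensional objective sweep (identifiability diagnostic)
#'
#' Profiles the objective along a single packed parameter while all others
#' are held at `theta`: a cheap profile-likelihood-style check of how well
#' the data constrain each constant (the fibril constants and the collagen
#' weighting are partially confounded).
#'
#' @param samples List of [cartilage_sample()] objects.
#' @param theta Reference [global_parameter_set()].
#' @param param One of `"k1"`, `"k2"`, `"k3"`, `"a0"`, `"a1"`, `"w"`.
#' @param values Parameter values to evaluate.
#' @param n_layers Forward-model layers.
#' @return data.frame with columns `value` and `objective`.
#' @export
parameter_sweep <- function(samples, theta, param, values, n_layers = 20L) {
  idx <- match(param, c("k1", "k2", "k3", "a0", "a1", "w"))
  if (is.na(idx)) stop("unknown parameter: ", param)
  x <- .theta_pack(theta)
  obj <- vapply(values, function(v) {
    xi <- x; xi[idx] <- v
    objective(samples, .theta_unpack(xi), n_layers = n_layers)
  }, numeric(1))
  data.frame(value = values, objective = obj)
}
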