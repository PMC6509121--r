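params_default <- material_parameters()

uniform_field <- function(phi_f = 0.75, phi_co = 0.18) {
  z <- seq(0, 1, length.out = 51)
  composition_field(z, rep(phi_f, 51), rep(phi_co, 51))
}

wilson_field <- function() {
  ref <- wilson_reference_profile(seq(0, 1, length.out = 101))
  composition_field(ref$z, ref$phi_f, ref$phi_co)
}

test_that("column construction averages layers against a trapezoid oracle", {
  mesh_u <- build_column(uniform_field(), params_default, n_layers = 5)
  expect_equal(mesh_u$phi_f, rep(0.75, 5), tolerance = 1e-12)
  expect_equal(mesh_u$phi_co, rep(0.18, 5), tolerance = 1e-12)
  expect_equal(sum(mesh_u$t_frac), 1, tolerance = 1e-12)

  expect_equal(build_column(uniform_field(), params_default, n_layers = 1)$n_layers, 1)

  field <- wilson_field()
  mesh <- build_column(field, params_default, n_layers = 20)
  # trapezoid oracle over the linear interpolant of the field grid,
  # evaluated on a dense grid containing the knots
  ref_fun <- stats::approxfun(field$z, field$phi_f, rule = 2)
  edges <- seq(0, 1, length.out = 21)
  for (i in c(1, 7, 20)) {
    zz <- sort(unique(c(seq(edges[i], edges[i + 1], length.out = 201),
                        field$z[field$z >= edges[i] & field$z <= edges[i + 1]])))
    oracle <- pracma::trapz(zz, ref_fun(zz)) / (edges[i + 1] - edges[i])
    expect_equal(mesh$phi_f[i], oracle, tolerance = 1e-8)
  }

  # saturation guard on layer averages (corrupted field)
  tight <- wilson_field()
  tight$phi_co <- tight$phi_co + 0.3
  expect_error(build_column(tight, params_default), "saturation")
})

test_that("layer stress is zero at rest, compressive under load, divergent at compaction", {
  mesh <- build_column(uniform_field(), params_default, n_layers = 3)
  expect_equal(layer_axial_stress(mesh, 1, 1), 0, tolerance = 1e-12)
  s85 <- layer_axial_stress(mesh, 0.85, 2)
  expect_lt(s85, 0)
  # cross-module consistency with the tensor constitutive path
  st <- make_kinematics(diag(c(1, 1, 0.85)))
  comp <- local_composition(0.75, 0.18)
  arch <- arcade_directions(mesh$z_mid[2], w = params_default$w)
  expect_equal(s85, cauchy_stress(st, comp, arch, params_default)$sigma[3, 3],
               tolerance = 1e-10)
  # divergence toward the compaction point
  expect_lt(layer_axial_stress(mesh, 0.25 + 1e-6, 2), -1e4)
  expect_error(layer_axial_stress(mesh, 0.2, 2), "compaction")
})

test_that("homogeneous columns compress uniformly", {
  # uniform composition AND a constant fiber angle: all layers identical
  mesh <- build_column(uniform_field(), params_default, n_layers = 12,
                       angle_profile = function(z) 0 * z + 45)
  sol <- solve_equilibrium(mesh, 0.1)
  expect_equal(sol$lambda, rep(0.9, 12), tolerance = 1e-9)
  expect_equal(sol$stress, layer_axial_stress(mesh, 0.9, 1), tolerance = 1e-8)

  sol0 <- solve_equilibrium(mesh, 0)
  expect_equal(sol0$stress, 0)
  expect_equal(sol0$lambda, rep(1, 12))

  expect_error(solve_equilibrium(mesh, 0.8), "compaction")
})

test_that("equilibrium satisfies stress uniformity and the strain constraint", {
  mesh <- build_column(wilson_field(), params_default, n_layers = 20)
  for (eps in c(0.05, 0.15)) {
    sol <- solve_equilibrium(mesh, eps)
    stresses <- vapply(1:20, function(i)
      layer_axial_stress(mesh, sol$lambda[i], i), numeric(1))
    expect_lt(max(stresses) - min(stresses), 1e-8)
    expect_equal(sum(mesh$t_frac * (1 - sol$lambda)), eps, tolerance = 1e-10)
  }
})

test_that("two-layer equilibria match the nested-bisection oracle", {
  set.seed(9)
  for (i in 1:8) {
    phi_f <- runif(2, 0.65, 0.8)
    phi_co <- runif(2, 0.08, 0.15)
    mesh <- build_column(two_level_field(phi_f, phi_co), params_default,
                         n_layers = 2)
    eps <- runif(1, 0.03, 0.15)
    sol <- solve_equilibrium(mesh, eps)
    oracle <- oracle_equilibrium(mesh, eps)
    expect_equal(sol$stress, oracle$stress, tolerance = 1e-8)
    expect_equal(sol$lambda, oracle$lambda, tolerance = 1e-6)
  }
})

test_that("softer layers localize the compressive strain", {
  mesh <- build_column(two_level_field(c(0.75, 0.75), c(0.08, 0.22)),
                       params_default, n_layers = 2)
  sol <- solve_equilibrium(mesh, 0.1)
  # the collagen-poor layer (1) carries the larger compressive strain
  expect_lt(sol$lambda[1], sol$lambda[2])
})

test_that("solution is invariant to layer-order reversal", {
  mesh <- build_column(wilson_field(), params_default, n_layers = 10)
  rev_mesh <- mesh
  for (f in c("phi_f", "phi_co", "phi_pg", "phi_s", "theta_deg"))
    rev_mesh[[f]] <- rev(mesh[[f]])
  rev_mesh$terms <- NULL
  rev_mesh$terms <- qmrcart:::.axial_terms(rev_mesh)
  s1 <- solve_equilibrium(mesh, 0.12)
  s2 <- solve_equilibrium(rev_mesh, 0.12)
  expect_equal(s1$stress, s2$stress, tolerance = 1e-9)
  expect_equal(s1$lambda, rev(s2$lambda), tolerance = 1e-7)
})

test_that("protocol simulation is monotone and ordered by stiffness", {
  mesh <- build_column(uniform_field(), params_default, n_layers = 8)
  sol <- simulate_protocol(mesh)
  expect_equal(nrow(sol$curve), 20)
  expect_true(all(diff(abs(sol$curve$stress)) > 0))

  one <- simulate_protocol(mesh, loading_protocol(0.07))
  expect_equal(one$curve$stress, solve_equilibrium(mesh, 0.07)$stress,
               tolerance = 1e-10)

  stiffer <- build_column(uniform_field(phi_co = 0.24), params_default,
                          n_layers = 8)
  sol2 <- simulate_protocol(stiffer)
  expect_true(all(abs(sol2$curve$stress) > abs(sol$curve$stress)))
})

test_that("stiffness definitions behave as documented", {
  lin <- data.frame(strain = seq(0.01, 0.2, by = 0.01),
                    stress = -2 * seq(0.01, 0.2, by = 0.01))
  expect_equal(stiffness_at(lin, 0.15), 2, tolerance = 1e-12)
  expect_equal(stiffness_at(lin, 0.15, method = "secant"), 2, tolerance = 1e-12)

  mesh <- build_column(wilson_field(), params_default, n_layers = 10)
  sol <- simulate_protocol(mesh)
  # the model curve is convex in |stress|: tangent exceeds secant
  expect_gt(stiffness_at(sol, 0.15), stiffness_at(sol, 0.15, method = "secant"))

  short <- data.frame(strain = seq(0.01, 0.1, by = 0.01),
                      stress = -seq(0.01, 0.1, by = 0.01))
  expect_error(stiffness_at(short, 0.15), "outside")
})
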