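test_that("signal models reproduce closed-form values", {
  # inversion recovery null point: TI = T1 log 2 with TR >> T1 nulls the signal
  pr <- acquisition_protocol("T1", c(100, 750 * log(2), 2000), TR = 1e6)
  s <- model_signal(list(relaxation_time = 750, amplitude = 1), pr)
  expect_lt(s[2], 1e-6)

  # T2 with zero amplitude is the constant offset
  pr2 <- default_protocol("T2")
  s2 <- model_signal(list(relaxation_time = 50, amplitude = 0, offset = 0.3), pr2)
  expect_equal(s2, rep(0.3, length(pr2$timings)))

  # spin-lock decay at TSL = T1rho is exp(-1)
  pr3 <- acquisition_protocol("T1rho", c(0, 40))
  s3 <- model_signal(list(relaxation_time = 40, amplitude = 1), pr3)
  expect_equal(s3[2], exp(-1), tolerance = 1e-12)

  expect_error(model_signal(list(relaxation_time = -5, amplitude = 1), pr3),
               "positive")
})

test_that("protocol validation rejects malformed timing grids", {
  expect_error(acquisition_protocol("T2", c(10, 10, 20)), "increasing")
  expect_error(acquisition_protocol("T2", c(-5, 10)), "positive")
  expect_error(acquisition_protocol("T1", c(150, 300), TR = 200), "exceed")
  expect_silent(acquisition_protocol("T1rho", c(0, 10, 20)))
})

test_that("noise-free fits recover generating parameters on the default grids", {
  cases <- list(
    list(mod = "T1", T = 750, A = 1.3, B = 0),
    list(mod = "T1rho", T = 40, A = 0.9, B = 0),
    list(mod = "T2", T = 50, A = 1, B = 0.07),
    list(mod = "T2star", T = 30, A = 1.1, B = 0))
  for (cs in cases) {
    pr <- default_protocol(cs$mod)
    y <- model_signal(list(relaxation_time = cs$T, amplitude = cs$A,
                           offset = cs$B), pr)
    fit <- fit_signal_model(y, pr)
    expect_equal(fit$relaxation_time, cs$T, tolerance = 1e-6,
                 label = paste(cs$mod, "relaxation time"))
    expect_equal(fit$amplitude, cs$A, tolerance = 1e-5)
    expect_equal(fit$adjusted_r2, 1, tolerance = 1e-9)
  }
})

test_that("round-trip property holds over random parameter draws", {
  set.seed(42)
  for (i in 1:8) {
    mod <- sample(c("T1", "T1rho", "T2", "T2star"), 1)
    Tt <- switch(mod, T1 = runif(1, 400, 1200), T1rho = runif(1, 20, 70),
                 T2 = runif(1, 25, 90), T2star = runif(1, 12, 50))
    A <- runif(1, 0.5, 2)
    B <- if (mod == "T2") runif(1, 0, 0.15) else 0
    pr <- default_protocol(mod)
    y <- model_signal(list(relaxation_time = Tt, amplitude = A, offset = B), pr)
    fit <- fit_signal_model(y, pr)
    expect_equal(fit$relaxation_time, Tt, tolerance = 1e-5,
                 label = sprintf("%s draw %d", mod, i))
  }
})

test_that("decay magnitude is strictly decreasing in timing when A > 0, B = 0", {
  pr <- default_protocol("T1rho")
  s <- model_signal(list(relaxation_time = 35, amplitude = 0.8), pr)
  expect_true(all(diff(s) < 0))
  pr2 <- default_protocol("T2star")
  s2 <- model_signal(list(relaxation_time = 28, amplitude = 1.5), pr2)
  expect_true(all(diff(s2) < 0))
})

test_that("noisy T2* fit matches a brute-force grid-search oracle", {
  pr <- default_protocol("T2star")
  y0 <- model_signal(list(relaxation_time = 30, amplitude = 1), pr)
  set.seed(7)
  y <- pmax(y0 + rnorm(length(y0), sd = 0.01), 0)
  fit <- fit_signal_model(y, pr)
  keep <- pr$timings <= pr$TE_cutoff
  oracle <- grid_search_decay(pr$timings[keep], y[keep])
  expect_lt(abs(fit$relaxation_time - oracle), 0.05)
})

test_that("echo-time filter is equivalent to fitting the truncated grid", {
  pr_full <- default_protocol("T2")
  keep <- pr_full$timings <= 60
  pr_trunc <- acquisition_protocol("T2", pr_full$timings[keep], TR = 1500)
  set.seed(11)
  y0 <- model_signal(list(relaxation_time = 48, amplitude = 1, offset = 0.05),
                     pr_full)
  y <- pmax(y0 + rnorm(length(y0), sd = 0.02), 0)
  f_full <- fit_signal_model(y, pr_full)
  f_trunc <- fit_signal_model(y[keep], pr_trunc)
  expect_identical(f_full$relaxation_time, f_trunc$relaxation_time)
  expect_identical(f_full$adjusted_r2, f_trunc$adjusted_r2)
})

test_that("degenerate series raise unidentifiable-fit errors", {
  pr <- default_protocol("T2")
  expect_error(fit_signal_model(rep(0.5, 12), pr), "unidentifiable")
  expect_error(fit_signal_model(rep(0, 12), pr), "unidentifiable")
})

test_that("parameter maps honour boundary exclusion and mask degeneracies", {
  pr <- default_protocol("T2")
  sig <- model_signal(list(relaxation_time = 50, amplitude = 1, offset = 0), pr)
  nr <- 8; nc <- 6
  stack <- array(rep(sig, each = nr * nc), dim = c(nr, nc, length(sig)))
  mask <- matrix(TRUE, nr, nc)

  map <- build_parameter_map(stack, pr, mask)
  # one-pixel erosion removes the border
  expect_false(any(map$mask[1, ]))
  expect_false(any(map$mask[, 1]))
  expect_equal(sum(map$mask), (nr - 2) * (nc - 2))
  expect_equal(unname(map$values[map$mask]), rep(50, sum(map$mask)),
               tolerance = 1e-6)

  # a single interior pixel would be erased by erosion: retained with warning
  mask1 <- matrix(FALSE, nr, nc); mask1[4, 3] <- TRUE
  expect_warning(map1 <- build_parameter_map(stack, pr, mask1), "erosion")
  expect_equal(sum(map1$mask), 1)
  expect_equal(map1$values[4, 3], 50, tolerance = 1e-6)

  expect_error(build_parameter_map(stack, pr, matrix(FALSE, nr, nc)), "empty")
})

test_that("depth-graded stack reproduces the per-row truth gradient", {
  pr <- default_protocol("T2")
  nr <- 12; nc <- 5
  truth <- seq(80, 45, length.out = nr)
  stack <- array(0, dim = c(nr, nc, length(pr$timings)))
  for (r in 1:nr) {
    sig <- model_signal(list(relaxation_time = truth[r], amplitude = 1,
                             offset = 0), pr)
    for (ci in 1:nc) stack[r, ci, ] <- sig
  }
  map <- build_parameter_map(stack, pr, matrix(TRUE, nr, nc))
  for (r in 2:(nr - 1))
    expect_equal(unname(map$values[r, 2]), truth[r], tolerance = 1e-6)
})
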