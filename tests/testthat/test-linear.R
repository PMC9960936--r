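test_that("linearization matches the complex-step Jacobian at the equilibrium", {
  p <- bench_params()
  set.seed(7)
  for (U in c(0.6, random_admissible_U(10, p))) {
    op <- equilibrium_from_input(U, p)
    lin <- linearize(p, U)
    J <- complex_step_jacobian(c(op$X1, op$X2), U, p)
    b <- complex_step_b(c(op$X1, op$X2), U, p)
    expect_equal(lin$A, J, tolerance = 1e-10)
    expect_equal(lin$b, b, tolerance = 1e-10)
    expect_identical(lin$c, c(1, 0))
  }
})

test_that("benchmark linearization values at U = 0.6", {
  lin <- linearize(bench_params(), 0.6)
  expect_equal(lin$A, matrix(c(-0.845455, 0.0371901, -3.96, 0), 2, 2),
               tolerance = 1e-5)
  expect_equal(lin$b, c(4.05, -0.613636), tolerance = 1e-6)
  expect_equal(sort(eigen(lin$A)$values), sort(c(-0.6, -0.2454545)),
               tolerance = 1e-6)
})

test_that("I/O coefficients agree with the transfer function of the state-space form", {
  p <- bench_params()
  expect_equal(unlist(io_coefficients(p, 0.6)[c("hD", "hN")]),
               c(hD = 0.2454545, hN = 4.05), tolerance = 1e-6)
  set.seed(11)
  for (U in random_admissible_U(20, p)) {
    lin <- linearize(p, U)
    io <- io_coefficients(p, U)
    # resolvent oracle c (sI - A)^{-1} b at probe frequencies vs hN/(s+hD)
    for (s in c(0.1i, 1i, 2 + 0.5i)) {
      H <- (lin$c %*% solve(s * diag(2) - lin$A, lin$b))[1]
      expect_equal(H, io$hN / (s + io$hD), tolerance = 1e-10)
    }
    # both approximant poles strictly negative (local stability)
    expect_true(all(Re(eigen(lin$A)$values) < 0))
    expect_equal(sort(eigen(lin$A)$values), sort(c(-U, -io$hD)),
                 tolerance = 1e-9)
  }
  # numerator coefficient vanishes at the admissibility boundary
  Umax <- admissible_input_bounds(p)["Umax"]
  expect_lt(io_coefficients(p, Umax * (1 - 1e-5))$hN, 1e-3)
})

test_that("physical parameters are reconstructable from I/O data (and round trip)", {
  p <- bench_params()
  io <- io_coefficients(p, 0.6)
  pr <- reconstruct_parameters(io, 0.6, 4.95, 1 / 6.6)
  expect_equal(unclass(pr)[c("mu_m", "s_in", "K")],
               list(mu_m = 1.2, s_in = 9, K = 4.95), tolerance = 1e-9)
  set.seed(13)
  for (U in random_admissible_U(100, p)) {
    op <- equilibrium_from_input(U, p)
    io <- io_coefficients(p, U)
    pr <- reconstruct_parameters(io, U, op$Y, p$delta)
    expect_equal(unclass(pr), unclass(p), tolerance = 1e-10)
    io2 <- io_coefficients(pr, U)
    expect_equal(io2$hD, io$hD, tolerance = 1e-10)
    expect_equal(io2$hN, io$hN, tolerance = 1e-10)
  }
  # outside the admissible set H the inversion must refuse
  expect_error(reconstruct_parameters(switchsense:::new_io_model(1, 1),
                                      U = 0.1, Y = 1, delta = 1 / 6.6),
               class = "switchsense_reconstructability_error")
})

test_that("state-space form built from I/O coefficients equals the direct linearization", {
  p <- bench_params()
  set.seed(17)
  for (U in random_admissible_U(20, p)) {
    op <- equilibrium_from_input(U, p)
    io <- io_coefficients(p, U)
    li <- statespace_from_io(io, U, op$Y, p$delta)
    ld <- linearize(p, U)
    expect_equal(li$A, ld$A, tolerance = 1e-12)
    expect_equal(li$b, ld$b, tolerance = 1e-12)
    expect_equal(li$op$X2, op$X2, tolerance = 1e-12)
  }
  # example values: X2 recovered as delta * hN
  li <- statespace_from_io(io_coefficients(p, 0.6), 0.6, 4.95, 1 / 6.6)
  expect_equal(li$op$X2, 4.05 / 6.6, tolerance = 1e-12)
})

test_that("observability depends on U only", {
  p <- bench_params()
  lin <- linearize(p, 0.6)
  ob <- observability(lin)
  expect_equal(det(ob$matrix), -3.96, tolerance = 1e-9)
  expect_true(ob$observable)
  # observability matrix determinant is -U/delta whatever the coefficients
  set.seed(19)
  for (U in random_admissible_U(10, p)) {
    lin <- linearize(p, U)
    expect_equal(det(observability(lin)$matrix), -U / p$delta,
                 tolerance = 1e-10)
  }
  # U = 0 loses observability
  lin0 <- lin
  lin0$A <- matrix(c(-lin$io$hD, lin$io$hD * p$delta, 0, 0), 2, 2)
  expect_false(observability(lin0)$observable)
})

test_that("io model JSON round-trips", {
  io <- io_coefficients(bench_params(), 0.45)
  f <- tempfile(fileext = ".json")
  write_io_model(io, f)
  io2 <- read_io_model(f)
  expect_equal(io2$hD, io$hD)
  expect_equal(io2$hN, io$hN)
  expect_false(io2$identified)
})
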