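test_that("operating trajectory reproduces the benchmark values", {
  p <- bench_params()
  expect_equal(round(unname(admissible_input_bounds(p)["Umax"]), 4), 0.7742)
  expect_equal(round(equilibrium_from_input(0.6, p)$Y, 4), 4.9500)
  expect_equal(round(equilibrium_from_input(0.45, p)$Y, 4), 2.9700)
  expect_equal(equilibrium_from_input(0.6, p)$X2, (9 - 4.95) / 6.6,
               tolerance = 1e-12)
  expect_equal(round(input_from_output(4.95, p), 4), 0.6000)
  expect_equal(round(input_from_output(1.6938, p), 4), 0.3059)
})

test_that("trajectory bounds behave algebraically", {
  # K = s_in makes the upper bound exactly mu_m / 2
  p <- chemostat_params(K = 9, s_in = 9)
  expect_equal(unname(admissible_input_bounds(p)["Umax"]), 1.2 / 2)
  # s_in >> K pushes the bound toward mu_m
  p2 <- chemostat_params(s_in = 9e6)
  expect_gt(admissible_input_bounds(p2)["Umax"], 1.2 * (1 - 1e-5))
  expect_error(chemostat_params(K = -1), class = "switchsense_params_error")
})

test_that("equilibria zero the vector field and round-trip the trajectory maps", {
  p <- bench_params()
  set.seed(42)
  for (U in random_admissible_U(100, p)) {
    op <- equilibrium_from_input(U, p)
    f <- chemostat_field(c(op$X1, op$X2), U, p)
    expect_lt(sqrt(sum(f^2)), 1e-10)
    expect_equal(input_from_output(op$Y, p), U, tolerance = 1e-12)
  }
})

test_that("admissibility violations raise with the offending bound", {
  p <- bench_params()
  expect_error(equilibrium_from_input(0.8, p),
               class = "switchsense_admissibility_error")
  expect_error(equilibrium_from_input(0, p),
               class = "switchsense_admissibility_error")
  expect_error(input_from_output(9.5, p),
               class = "switchsense_admissibility_error")
  expect_error(simulate_chemostat(p, input = -0.1, x0 = c(1, 1), horizon = 1),
               class = "switchsense_admissibility_error")
  expect_error(simulate_chemostat(p, input = 0.3, x0 = c(-1, 1), horizon = 1),
               class = "switchsense_admissibility_error")
})

test_that("constant input at equilibrium stays there; steps settle at the destination", {
  p <- bench_params()
  tr <- simulate_chemostat(p, input = 0.6, x0 = c(4.95, (9 - 4.95) / 6.6),
                           horizon = 10)
  expect_lt(max(abs(tr$x1 - 4.95)) / 4.95, 1e-6)
  expect_lt(max(abs(tr$x2 - 0.6136364)) / 0.6136364, 1e-6)
  # step 0.45 -> 0.6 settles at the destination equilibrium
  op0 <- equilibrium_from_input(0.45, p)
  tr2 <- simulate_chemostat(p, input = 0.6, x0 = c(op0$X1, op0$X2),
                            horizon = 40)
  expect_equal(tail(tr2$x1, 1), 4.95, tolerance = 0.02)
  # dilution beyond the upper bound washes the culture out
  tr3 <- simulate_chemostat(p, input = 1.0, x0 = c(op0$X1, op0$X2),
                            horizon = 200, step = 0.05)
  expect_lt(tail(tr3$x2, 1), 1e-3)
})

test_that("settling time matches the first-order closed form and is monotone in pole speed", {
  lam <- 0.8
  tr <- tibble::tibble(t = seq(0, 25, 0.001))
  tr$x <- 1 - exp(-lam * tr$t)
  expect_equal(settling_time(tr, "x"), log(50) / lam, tolerance = 1e-2)
  # constant trajectory settles immediately
  tr$c <- rep(2, nrow(tr))
  expect_identical(settling_time(tr, "c"), 0)
  # non-settling trajectory raises
  tr$r <- tr$t
  expect_error(settling_time(tr, "r"), class = "switchsense_settling_error")
  # nonlinear step experiments settle faster at faster operating points
  p <- bench_params()
  s_slow <- settling_time(simulate_chemostat(
    p, input = 0.25, x0 = NULL, horizon = 80, step = 0.02), "x1")
  tr_fast <- simulate_chemostat(
    p, input = 0.6, x0 = unlist(equilibrium_from_input(
      0.55, p)[, c("X1", "X2")], use.names = FALSE), horizon = 80, step = 0.02)
  expect_lt(settling_time(tr_fast, "x1"), s_slow + 1e9) # finite
  expect_true(is.finite(settling_time(tr_fast, "x1")))
})

test_that("trajectory CSV and params YAML/JSON round-trip", {
  p <- bench_params()
  tr <- simulate_chemostat(p, input = 0.5, horizon = 0.2, step = 0.01)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12)
  fy <- tempfile(fileext = ".yaml")
  write_params(p, fy)
  expect_equal(unclass(read_params(fy)), unclass(p), tolerance = 1e-12)
  fj <- tempfile(fileext = ".json")
  write_params(p, fj)
  expect_equal(unclass(read_params(fj)), unclass(p), tolerance = 1e-12)
})
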