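# a small shared bank over the mid-range operating points
mk_bank <- function() {
  p <- bench_params()
  build_bank(bank_points(p, c(0.2134, 0.2826, 0.45, 0.6)), delta = p$delta,
             a = 3.5, zeta_oa = 0.5)
}

test_that("bank construction orders entries and rejects duplicates", {
  p <- bench_params()
  pts <- bank_points(p, c(0.45, 0.2134, 0.6))
  bank <- build_bank(pts, p$delta)
  expect_equal(bank$U, sort(pts$U))
  bank2 <- build_bank(pts[order(pts$U), ], p$delta)
  expect_equal(bank$rho2, bank2$rho2, tolerance = 1e-12)
  expect_error(build_bank(bank_points(p, c(0.3, 0.3)), p$delta),
               class = "switchsense_bank_error")
  single <- build_bank(bank_points(p, 0.45), p$delta)
  expect_equal(nrow(single), 1L)
  expect_equal(glance(single)$n, 1L)
})

test_that("target areas are sound: every scanned destination inside passes", {
  p <- bench_params()
  bank <- mk_bank()
  areas <- target_areas(bank, chi_oa = 0.5, chi_ob = 0.001, n_scan = 120)
  expect_true(all(!areas$empty))
  expect_true(all(areas$lo <= areas$U & areas$U <= areas$hi))
  set.seed(41)
  for (k in seq_len(nrow(areas))) {
    d <- bank$design[[k]]
    pars <- reconstruct_parameters(d$io, d$U, d$Y, d$delta)
    for (UD in runif(25, areas$lo[k], areas$hi[k])) {
      expect_lte(switchsense:::je_o_at(d, UD, pars), 0.001 * (1 + 1e-6))
    }
    expect_lte(d$je_a, 0.5 * (1 + 1e-6))
  }
  # example: the U = 0.6 area contains the 0.65 destination
  a5 <- areas[areas$U == 0.6, ]
  expect_true(a5$lo <= 0.65 && 0.65 <= a5$hi)
})

test_that("relaxing the steady-state threshold can only widen areas; high-U areas saturate", {
  bank <- mk_bank()
  a_tight <- target_area(bank, 4, chi_oa = 0.5, chi_ob = 0.001, n_scan = 120)
  a_loose <- target_area(bank, 4, chi_oa = 0.5, chi_ob = 1e6, n_scan = 120)
  expect_lte(a_loose$lo, a_tight$lo)
  expect_gte(a_loose$hi, a_tight$hi)
  # with the threshold out of the way only admissibility limits the area
  p <- bench_params()
  Umax <- unname(admissible_input_bounds(p)["Umax"])
  expect_equal(a_loose$hi, Umax, tolerance = 1e-9)
  # the high-U entry saturates at Umax under the working threshold:
  # nominally symmetric, asymmetric in effect
  a5 <- target_area(bank, 4, chi_oa = 0.5, chi_ob = 0.001, n_scan = 120)
  expect_equal(a5$hi, Umax, tolerance = 1e-6)
  expect_gt(a5$u_max_lo, a5$u_max_hi)
  # an unmeetable convergence threshold yields an empty area
  a_empty <- target_area(bank, 1, chi_oa = 1e-4, chi_ob = 0.001, n_scan = 50)
  expect_true(a_empty$empty)
})

test_that("dense-web check passes on overlapping intervals and reports gaps", {
  toy <- function(lo, hi, U = (lo + hi) / 2) {
    tibble::tibble(i = seq_along(lo), U = U, lo = lo, hi = hi,
                   u_max_lo = U - lo, u_max_hi = hi - U,
                   symmetric = TRUE, empty = FALSE)
  }
  expect_true(dense_web_check(toy(c(0, 1), c(2, 3)))$pass)
  rep_fail <- dense_web_check(toy(c(0, 2.5), c(2, 3)))
  expect_false(rep_fail$pass)
  expect_equal(rep_fail$gaps$gap_lo, 2)
  expect_equal(rep_fail$gaps$gap_hi, 2.5)
  # sparse low-dilution nominals leave an uncovered interval (narrow areas)
  p <- bench_params()
  sparse <- build_bank(bank_points(p, c(0.07, 0.13)), p$delta)
  web <- dense_web_check(target_areas(sparse, 0.5, 0.001, n_scan = 120))
  expect_false(web$pass)
  expect_equal(nrow(web$gaps), 1L)
  expect_true(web$gaps$gap_lo > 0.07 && web$gaps$gap_hi < 0.13)
})

test_that("transition planning: trivial, greedy farthest-reach, reverse, errors", {
  bank <- mk_bank()
  areas <- target_areas(bank, 0.5, 0.001, n_scan = 120)
  # trivial plan
  p0 <- plan_transition(areas, 0.45, 0.45)
  expect_equal(nrow(p0), 0L)
  # greedy forward: the wide high-U area is reached in one hop when it
  # covers the start, otherwise through overlaps
  pf <- plan_transition(areas, 0.2134, 0.6, bank = bank)
  expect_equal(pf$U_target[nrow(pf)], 0.6)
  expect_true(all(diff(c(0.2134, pf$U_target)) > 0) || nrow(pf) == 1)
  # hand-picked intermediates follow the printed route
  pp <- plan_transition(areas, 0.2134, 0.6,
                        intermediates = c(0.2826, 0.45), bank = bank)
  expect_equal(pp$U_target, c(0.2826, 0.45, 0.6))
  expect_equal(pp$observer, c(2, 3, 4))
  expect_true(all(pp$duration > 0))
  # reverse transition plans downward
  pr <- plan_transition(areas, 0.6, 0.2134, bank = bank)
  expect_equal(pr$U_target[nrow(pr)], 0.2134)
  # uncovered endpoint raises
  expect_error(plan_transition(areas, 0.01, 0.6),
               class = "switchsense_planning_error")
})

test_that("executing a sound plan keeps estimates continuous and errors small", {
  p <- bench_params()
  bank <- mk_bank()
  areas <- target_areas(bank, 0.5, 0.001, n_scan = 120)
  plan <- plan_transition(areas, 0.2134, 0.6,
                          intermediates = c(0.2826, 0.45), bank = bank)
  run <- execute_transition(plan, p, bank)
  # supervisor hands the physical estimate over continuously
  sw <- which(diff(run$stage) != 0)
  for (k in sw) {
    expect_equal(run$xhat1[k + 1], run$xhat1[k], tolerance = 1e-12)
    expect_equal(run$xhat2[k + 1], run$xhat2[k], tolerance = 1e-12)
  }
  # the literal raw-deviation handoff jumps the estimate instead
  run_lit <- execute_transition(plan, p, bank, literal_handoff = TRUE)
  jumps <- vapply(which(diff(run_lit$stage) != 0), function(k) {
    abs(run_lit$xhat1[k + 1] - run_lit$xhat1[k])
  }, numeric(1))
  expect_gt(max(jumps), 1e-3)
  # per-stage steady errors are far below the stage movements
  s <- summarize_run(run, bank)
  expect_true(all(s$steady_rel_err < 0.032))
  expect_true(all(s$substrate_rel_err < 1e-3))
  # matched start: substrate estimate indistinguishable from the plant
  stage1 <- run[run$stage == 1, ]
  expect_lt(max(abs(stage1$e1)) / bank$Y[2], 0.05)
  expect_lt(abs(tail(stage1$e1, 1)) / bank$Y[2], 1e-3)
})

test_that("stage-wise error decay dominates the regional-stability rate on linear replays", {
  d <- ref_design()
  h <- 0.01
  t <- seq(0, 2, h)
  lin <- statespace_from_io(d$io, d$U, d$Y, d$delta)
  ltr <- simulate_linear_approximant(lin, 0, dx0 = c(0.2, 0.1), horizon = 2,
                                     step = h)
  dat <- tibble::tibble(t = t, u = d$U, y = d$Y + ltr$dx1)
  est <- simulate_observer(d, dat, z0 = c(0.2, 0.1) + c(0.1, -0.2))
  e <- sqrt((ltr$dx1 - est$dz1)^2 + (ltr$dx2 - est$dz2)^2)
  # past the initial transient the envelope decays at least at rate a
  i0 <- which.min(abs(t - 0.5)); i1 <- which.min(abs(t - 1.5))
  expect_lt(e[i1] / e[i0], exp(-d$a * (t[i1] - t[i0])) * 10)
})
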