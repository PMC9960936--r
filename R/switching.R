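#' Build a bank of optimized observers
#'
#' One pole-optimized full-order observer per operating point, ordered by
#' increasing dilution rate. Points may carry true or identified I/O
#' coefficients; all entries share the yield constant, the stability
#' margin and the convergence threshold.
#'
#' @param points Tibble with columns `U`, `Y` and either `hD`, `hN` or an
#'   `io` list-column of `io_model`s (see [bank_points()]).
#' @param delta Yield constant.
#' @param a Stability margin (1/day).
#' @param zeta_oa Convergence threshold for the pole optimization.
#' @param bounds Optional pole search bounds passed to [optimize_poles()].
#' @return An `observer_bank`: tibble with one row per entry
#'   (`i, U, Y, X2, hD, hN, rho1, rho2, je_a, je_o_tilde`) and a `design`
#'   list-column; `delta`, `a`, `zeta_oa` kept as attributes.
#' @export
build_bank <- function(points, delta, a = 3.5, zeta_oa = 0.5, bounds = NULL) {
  stopifnot(is.data.frame(points), "U" %in% names(points))
  if (anyDuplicated(points$U)) {
    ss_abort("duplicate operating inputs in the bank point set",
             "switchsense_bank_error")
  }
  points <- points[order(points$U), , drop = FALSE]
  ios <- if ("io" %in% names(points)) points$io else
    purrr::map2(points$hD, points$hN, function(hD, hN) new_io_model(hD, hN))
  designs <- purrr::pmap(list(ios, points$U, points$Y, seq_len(nrow(points))),
    function(io, U, Y, i) {
      tryCatch(design_observer(io, U, Y, delta, a, zeta_oa, bounds),
               switchsense_error = function(e) {
                 ss_abort(sprintf("observer design infeasible at bank entry %d (U = %.4g): %s",
                                  i, U, conditionMessage(e)),
                          "switchsense_bank_error")
               })
    })
  out <- tibble::tibble(
    i = seq_len(nrow(points)), U = points$U, Y = points$Y,
    X2 = purrr::map_dbl(designs, function(d) d$X[2]),
    hD = purrr::map_dbl(ios, "hD"), hN = purrr::map_dbl(ios, "hN"),
    rho1 = purrr::map_dbl(designs, "rho1"),
    rho2 = purrr::map_dbl(designs, "rho2"),
    je_a = purrr::map_dbl(designs, "je_a"),
    je_o_tilde = purrr::map_dbl(designs, "je_o_tilde"),
    design = designs)
  attr(out, "delta") <- delta; attr(out, "a") <- a
  attr(out, "zeta_oa") <- zeta_oa
  class(out) <- c("observer_bank", class(out))
  out
}

#' Bank point set from known physical parameters
#'
#' Helper for design studies: the exact operating outputs and I/O
#' coefficients at a vector of dilution rates.
#'
#' @param params A [chemostat_params()] object.
#' @param U Dilution rates.
#' @return Tibble `U, Y, hD, hN` suitable for [build_bank()].
#' @export
bank_points <- function(params, U) {
  ops <- equilibrium_from_input(U, params)
  ios <- purrr::map(U, function(u) io_coefficients(params, u))
  tibble::tibble(U = U, Y = ops$Y,
                 hD = purrr::map_dbl(ios, "hD"),
                 hN = purrr::map_dbl(ios, "hN"))
}

#' @method tidy observer_bank
#' @export
tidy.observer_bank <- function(x, ...) {
  out <- tibble::as_tibble(x[setdiff(names(x), "design")])
  out
}

#' @method glance observer_bank
#' @export
glance.observer_bank <- function(x, ...) {
  tibble::tibble(n = nrow(x), delta = attr(x, "delta"), a = attr(x, "a"),
                 zeta_oa = attr(x, "zeta_oa"),
                 U_min = min(x$U), U_max = max(x$U))
}

# steady-state ratio metric at destination UD for one bank entry
je_o_at <- function(design, UD, params) {
  uw <- UD - design$U
  if (uw == 0) return(0)
  dest <- equilibrium_on_trajectory(UD, params)
  steady_state_error(design, uw, destination = dest)$je_o
}

#' Target operating area of a bank entry
#'
#' The interval of destination inputs around the entry's nominal \eqn{U_i}
#' on which the entry's observer satisfies both thresholds: the
#' convergence metric \eqn{J_{e,A} \le \chi_{O,A}} (destination
#' independent) and the steady-state ratio \eqn{J_{e,O} \le \chi_{O,B}} at
#' every scanned destination, destination equilibria taken on the
#' nonlinear operating trajectory. Symmetric areas grow one half-width on
#' both sides (saturating at the admissible bounds, which makes high-U
#' areas asymmetric in effect); `symmetric = FALSE` grows each side
#' independently until failure or saturation.
#'
#' @param bank An `observer_bank`.
#' @param index Entry index.
#' @param chi_oa,chi_ob Thresholds \eqn{\chi_{O,A}}, \eqn{\chi_{O,B}}.
#' @param params Optional [chemostat_params()] for the destination
#'   trajectory; default reconstructs them from the entry's (identified)
#'   I/O model — the fully data-driven route.
#' @param n_scan Grid points per side (default 400).
#' @param refine Boundary bisection tolerance (1/day), default 1e-4.
#' @param symmetric Grow a symmetric interval (default) or each side free.
#' @param floor_u Smallest admissible destination (default 1e-4).
#' @return One-row tibble of class `target_area`:
#'   `i, U, lo, hi, u_max_lo, u_max_hi, symmetric, empty`.
#' @export
target_area <- function(bank, index, chi_oa, chi_ob, params = NULL,
                        n_scan = 400, refine = 1e-4, symmetric = TRUE,
                        floor_u = 1e-4) {
  stopifnot(chi_oa > 0, chi_ob > 0)
  entry <- bank$design[[which(bank$i == index)]]
  if (is.null(params)) {
    params <- reconstruct_parameters(entry$io, entry$U, entry$Y, entry$delta)
  }
  Umax <- unname(admissible_input_bounds(params)["Umax"])
  Ui <- entry$U
  if (entry$je_a > chi_oa * (1 + 1e-6)) {
    return(structure(tibble::tibble(i = index, U = Ui, lo = NA_real_,
                                    hi = NA_real_, u_max_lo = 0, u_max_hi = 0,
                                    symmetric = symmetric, empty = TRUE),
                     class = c("target_area", class(tibble::tibble()))))
  }
  ok <- function(UD) {
    UD >= floor_u && UD <= Umax && je_o_at(entry, UD, params) <= chi_ob
  }
  side_max <- function(dir) {
    # largest u with Ui + dir*u admissible-and-passing, by scan + bisection
    u_cap <- if (dir > 0) Umax - Ui else Ui - floor_u
    if (u_cap <= 0) return(0)
    us <- seq(u_cap / n_scan, u_cap, length.out = n_scan)
    pass <- vapply(us, function(u) ok(Ui + dir * u), logical(1))
    if (all(pass)) return(u_cap)              # saturated at the range bound
    first_fail <- which(!pass)[1]
    lo <- if (first_fail == 1) 0 else us[first_fail - 1]
    hi <- us[first_fail]
    while (hi - lo > refine) {
      mid <- (lo + hi) / 2
      if (ok(Ui + dir * mid)) lo <- mid else hi <- mid
    }
    lo
  }
  up <- side_max(1); dn <- side_max(-1)
  if (symmetric) {
    # one half-width, saturated at the bounds: the binding side is the
    # smaller of the unsaturated sides
    u <- min(c(up, dn)[c(up < Umax - Ui - 1e-12, dn < Ui - floor_u - 1e-12)],
             max(up, dn))
    lo <- max(Ui - u, floor_u); hi <- min(Ui + u, Umax)
  } else {
    lo <- Ui - dn; hi <- Ui + up
  }
  structure(tibble::tibble(i = index, U = Ui, lo = lo, hi = hi,
                           u_max_lo = Ui - lo, u_max_hi = hi - Ui,
                           symmetric = symmetric,
                           empty = FALSE),
            class = c("target_area", class(tibble::tibble())))
}

#' Target areas for every bank entry
#'
#' @inheritParams target_area
#' @param ... Passed to [target_area()].
#' @return Tibble of areas ordered by nominal input.
#' @export
target_areas <- function(bank, chi_oa, chi_ob, params = NULL, ...) {
  out <- purrr::map_dfr(bank$i, function(ix)
    target_area(bank, ix, chi_oa, chi_ob, params = params, ...))
  class(out) <- c("target_area", class(tibble::tibble()))
  out
}

#' Dense-web check on a set of target areas
#'
#' The switching scheme requires every pair of consecutive target areas to
#' overlap, so an observer handover point exists along any transition.
#' Reports the uncovered gaps when the principle fails.
#'
#' @param areas Tibble from [target_areas()], ordered by `U`.
#' @return List of class `dense_web_report`: `pass`, `gaps` (tibble
#'   `after_index, gap_lo, gap_hi`), `areas`.
#' @export
dense_web_check <- function(areas) {
  areas <- areas[order(areas$U), , drop = FALSE]
  gaps <- tibble::tibble(after_index = integer(), gap_lo = numeric(),
                         gap_hi = numeric())
  n <- nrow(areas)
  if (n > 1) {
    for (k in seq_len(n - 1)) {
      hi_k <- areas$hi[k]; lo_n <- areas$lo[k + 1]
      if (isTRUE(areas$empty[k]) || isTRUE(areas$empty[k + 1]) ||
          is.na(hi_k) || is.na(lo_n) || lo_n > hi_k) {
        gaps <- dplyr::bind_rows(gaps, tibble::tibble(
          after_index = areas$i[k],
          gap_lo = if (is.na(hi_k)) areas$U[k] else hi_k,
          gap_hi = if (is.na(lo_n)) areas$U[k + 1] else lo_n))
      }
    }
  }
  structure(list(pass = nrow(gaps) == 0, gaps = gaps, areas = areas),
            class = "dense_web_report")
}

#' @export
print.dense_web_report <- function(x, ...) {
  cat("<dense_web_report> ", if (x$pass) "PASS: all consecutive target areas overlap\n"
      else "FAIL: uncovered gaps between target areas\n")
  if (!x$pass) print(x$gaps)
  invisible(x)
}

covering_areas <- function(areas, U) {
  which(!areas$empty & areas$lo <= U & U <= areas$hi)
}

#' Plan a stepwise transition through target areas
#'
#' Splits a transition from `from` to `to` into individual steps, each
#' handled by the observer of the area being entered. The default rule is
#' the greedy farthest-reach recursion: from the current area, jump to the
#' highest-index area whose interval overlaps it, placing the intermediate
#' destination at the overlap midpoint; reverse transitions run the same
#' recursion downwards (the plan is direction dependent). Hand-picked
#' intermediate points may be supplied instead; each is then assigned the
#' covering area with the nearest nominal (with a warning if a point is
#' not covered by its assigned area).
#'
#' @param areas Tibble from [target_areas()].
#' @param from,to Initial and destination operating inputs (1/day); both
#'   must be covered by some area.
#' @param intermediates Optional vector of intermediate destination inputs
#'   (excluding `to`).
#' @param bank Optional `observer_bank`; when given, each stage's duration
#'   is `timing_factor` times the 2%-settling time of the entered
#'   observer's linear approximant for that step.
#' @param timing_factor Multiple of the settling time at which the next
#'   step is triggered (default 1.1, within the one-to-two settling-times
#'   convention).
#' @param step Sampling step for the settling-time evaluation.
#' @return A `transition_plan` tibble: `stage, observer, U_from, U_target,
#'   Y_target, duration`.
#' @export
plan_transition <- function(areas, from, to, intermediates = NULL,
                            bank = NULL, timing_factor = 1.1, step = 0.01) {
  areas <- areas[order(areas$U), , drop = FALSE]
  cov_from <- covering_areas(areas, from)
  cov_to <- covering_areas(areas, to)
  if (length(cov_from) == 0 || length(cov_to) == 0) {
    ss_abort(sprintf("endpoint %.4g not covered by any target area",
                     if (length(cov_from) == 0) from else to),
             "switchsense_planning_error")
  }
  mk_plan <- function(obs_idx, targets, from) {
    tibble::tibble(stage = seq_along(targets),
                   observer = areas$i[obs_idx],
                   U_from = c(from, head(targets, -1)),
                   U_target = targets)
  }
  if (from == to) {
    plan <- mk_plan(integer(), numeric(), from)
  } else if (!is.null(intermediates)) {
    targets <- c(intermediates, to)
    obs_idx <- vapply(targets, function(u) {
      cov <- covering_areas(areas, u)
      if (length(cov) == 0) {
        warn(sprintf("intermediate point %.4g not covered by any target area; using nearest nominal", u))
        return(which.min(abs(areas$U - u)))
      }
      cov[which.min(abs(areas$U[cov] - u))]
    }, integer(1))
    plan <- mk_plan(obs_idx, targets, from)
  } else {
    dir <- if (to > from) 1L else -1L
    cur <- if (dir > 0) cov_from[which.max(areas$hi[cov_from])]
           else cov_from[which.min(areas$lo[cov_from])]
    obs_idx <- integer(); targets <- numeric()
    guard <- 0L
    while (TRUE) {
      guard <- guard + 1L
      if (guard > nrow(areas) + 1L) {
        ss_abort("transition planning did not terminate (broken web?)",
                 "switchsense_planning_error")
      }
      if (areas$lo[cur] <= to && to <= areas$hi[cur]) {
        obs_idx <- c(obs_idx, cur); targets <- c(targets, to)
        break
      }
      nxt_set <- if (dir > 0) {
        which(seq_len(nrow(areas)) > cur & areas$lo <= areas$hi[cur] &
                !areas$empty)
      } else {
        which(seq_len(nrow(areas)) < cur & areas$hi >= areas$lo[cur] &
                !areas$empty)
      }
      if (length(nxt_set) == 0) {
        ss_abort(sprintf(
          "dense web broken beyond area %d ([%.4g, %.4g]): no overlapping area toward %.4g",
          areas$i[cur], areas$lo[cur], areas$hi[cur], to),
          "switchsense_planning_error")
      }
      nxt <- if (dir > 0) max(nxt_set) else min(nxt_set)
      ov <- c(max(areas$lo[cur], areas$lo[nxt]), min(areas$hi[cur], areas$hi[nxt]))
      obs_idx <- c(obs_idx, nxt); targets <- c(targets, mean(ov))
      cur <- nxt
    }
    plan <- mk_plan(obs_idx, targets, from)
  }
  # destination outputs on the operating trajectory of the governing entry
  plan$Y_target <- vapply(seq_len(nrow(plan)), function(k) {
    if (is.null(bank)) return(NA_real_)
    d <- bank$design[[match(plan$observer[k], bank$i)]]
    pars <- reconstruct_parameters(d$io, d$U, d$Y, d$delta)
    equilibrium_on_trajectory(plan$U_target[k], pars)$Y
  }, numeric(1))
  plan$duration <- vapply(seq_len(nrow(plan)), function(k) {
    if (is.null(bank)) return(NA_real_)
    stage_duration(bank, plan$observer[k], plan$U_from[k], plan$U_target[k],
                   timing_factor, step)
  }, numeric(1))
  attr(plan, "from") <- from; attr(plan, "to") <- to
  attr(plan, "timing_factor") <- timing_factor
  class(plan) <- c("transition_plan", class(plan))
  plan
}

# stage duration = timing_factor x settling time of the entered observer's
# linear approximant stepping U_from -> U_target
stage_duration <- function(bank, observer, U_from, U_target, timing_factor,
                           step = 0.01) {
  d <- bank$design[[match(observer, bank$i)]]
  pars <- reconstruct_parameters(d$io, d$U, d$Y, d$delta)
  lin <- statespace_from_io(d$io, d$U, d$Y, d$delta)
  x_from <- equilibrium_on_trajectory(U_from, pars)
  dx0 <- c(x_from$X1 - d$X[1], x_from$X2 - d$X[2])
  pole_min <- min(abs(c(d$U, d$io$hD)))
  horizon <- max(10 / pole_min, 5)
  tr <- simulate_linear_approximant(lin, input_dev = U_target - d$U,
                                    dx0 = dx0, horizon = horizon, step = step)
  ts <- max(settling_time(tr, "dx1"), settling_time(tr, "dx2"))
  if (ts == 0) ts <- 3.912 / pole_min   # degenerate zero-step stage
  timing_factor * ts
}

#' Execute a planned transition with the switching supervisor
#'
#' Simulates the nonlinear plant under the stepwise input commands of the
#' plan while the supervisor runs the entered area's observer during each
#' stage and switches at the planned times. At a switch the physical
#' estimate is continuous by default: the incoming observer's deviation
#' state is set from the outgoing physical estimate re-based to the new
#' nominal point (`literal_handoff = TRUE` instead copies the raw
#' deviation state between observers, which jumps the physical estimate
#' when the nominals differ). The first observer starts with its measured
#' component on the measurement and the unmeasured component at its
#' nominal.
#'
#' @param plan A `transition_plan` (durations present, i.e. planned with a
#'   bank).
#' @param params [chemostat_params()] of the true plant.
#' @param bank The `observer_bank` referenced by the plan.
#' @param step Sampling step (days).
#' @param x0 Initial plant state; default the equilibrium of the plan's
#'   start input.
#' @param literal_handoff Copy raw deviation states at switches.
#' @return A `switched_run` tibble: `t, u, y, x1, x2, xhat1, xhat2, e1,
#'   e2, active_observer, stage` (switch instants appear twice, once per
#'   adjoining stage).
#' @export
execute_transition <- function(plan, params, bank, step = 0.01, x0 = NULL,
                               literal_handoff = FALSE) {
  if (nrow(plan) == 0) {
    ss_abort("empty transition plan (from == to): nothing to execute",
             "switchsense_planning_error")
  }
  if (any(is.na(plan$duration))) {
    ss_abort("plan has no stage durations; re-plan with the bank supplied",
             "switchsense_planning_error")
  }
  if (!all(plan$observer %in% bank$i)) {
    ss_abort("plan references observers missing from the bank",
             "switchsense_bank_error")
  }
  from <- attr(plan, "from")
  if (is.null(x0)) {
    op0 <- equilibrium_from_input(from, params)
    x0 <- c(op0$X1, op0$X2)
  }
  t0 <- 0
  x_cur <- x0
  z_cur <- NULL
  prev_design <- NULL
  rows <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    d <- bank$design[[match(plan$observer[k], bank$i)]]
    dur <- max(plan$duration[k], 2 * step)
    nt <- ceiling(dur / step)
    tr <- simulate_chemostat(params, input = plan$U_target[k], x0 = x_cur,
                             horizon = nt * step, step = step)
    if (is.null(prev_design)) {
      z0 <- c(tr$x1[1] - d$Y, 0)
    } else if (literal_handoff) {
      z0 <- z_cur
    } else {
      xhat_prev <- z_cur + prev_design$X
      z0 <- xhat_prev - d$X
    }
    est <- simulate_observer(d, tibble::tibble(t = tr$t, u = tr$u, y = tr$x1),
                             z0 = z0)
    rows[[k]] <- tibble::tibble(
      t = t0 + tr$t, u = tr$u, y = tr$x1, x1 = tr$x1, x2 = tr$x2,
      xhat1 = est$xhat1, xhat2 = est$xhat2,
      e1 = tr$x1 - est$xhat1, e2 = tr$x2 - est$xhat2,
      active_observer = plan$observer[k], stage = k)
    n <- nrow(tr)
    t0 <- t0 + tr$t[n]
    x_cur <- c(tr$x1[n], tr$x2[n])
    z_cur <- c(est$dz1[n], est$dz2[n])
    prev_design <- d
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "plan") <- plan
  class(out) <- c("switched_run", class(out))
  out
}

#' Per-stage summary of a switched run
#'
#' Steady (end-of-stage) and peak estimation errors per stage, the steady
#' error relative to the stage's state offset, and the substrate steady
#' error relative to the stage's operating output.
#'
#' @param run A `switched_run`.
#' @param bank The `observer_bank` used.
#' @return Tibble with one row per stage.
#' @export
summarize_run <- function(run, bank) {
  plan <- attr(run, "plan")
  purrr::map_dfr(unique(run$stage), function(k) {
    seg <- run[run$stage == k, ]
    n <- nrow(seg)
    d <- bank$design[[match(seg$active_observer[1], bank$i)]]
    pars <- reconstruct_parameters(d$io, d$U, d$Y, d$delta)
    dest <- equilibrium_on_trajectory(plan$U_target[k], pars)
    src <- equilibrium_on_trajectory(plan$U_from[k], pars)
    # stage state movement: the natural scale of the stage's transient
    dX <- c(dest$X1 - src$X1, dest$X2 - src$X2)
    e_end <- c(seg$e1[n], seg$e2[n])
    tibble::tibble(
      stage = k, observer = seg$active_observer[1],
      U_target = plan$U_target[k],
      t_start = seg$t[1], t_end = seg$t[n],
      je_a = d$je_a,
      steady_err_norm = sqrt(sum(e_end^2)),
      steady_rel_err = sqrt(sum(e_end^2)) / max(sqrt(sum(dX^2)), 1e-12),
      substrate_rel_err = abs(e_end[1]) / dest$Y,
      peak_err_norm = max(sqrt(seg$e1^2 + seg$e2^2)))
  })
}

#' Write target areas / a plan / a switched run to disk
#'
#' Areas and plans as JSON, runs as CSV with the column layout
#' `t,u,y,x1,x2,xhat1,xhat2,e1,e2,active_observer`.
#' @param x The object.
#' @param path File path.
#' @export
write_areas <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_areas
#' @export
write_plan <- function(x, path) {
  jsonlite::write_json(as.data.frame(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_areas
#' @export
write_run <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("t", "u", "y", "x1", "x2", "xhat1",
                                        "xhat2", "e1", "e2",
                                        "active_observer")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
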