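#' Chemostat model parameters
#'
#' Bundles the four physical constants of the Monod-kinetics chemostat
#'
#' \deqn{\dot x_1 = u (s_{in} - x_1) - \mu_m x_1 x_2 / (\delta (x_1 + K)),
#'       \qquad
#'       \dot x_2 = \mu_m x_1 x_2 / (x_1 + K) - u x_2,}
#'
#' where \eqn{x_1} is the substrate concentration (the measured output),
#' \eqn{x_2} the micro-organism concentration, and the dilution rate
#' \eqn{u} the actuated input. Defaults are the benchmark values
#' \eqn{\delta = 1/6.6}, \eqn{\mu_m = 1.2\,\mathrm{day}^{-1}},
#' \eqn{K = 4.95\,\mathrm{kg\,COD/m^3}}, \eqn{s_{in} = 9\,\mathrm{kg/m^3}}.
#'
#' @param delta Yield constant (kg biomass per kg COD consumed).
#' @param mu_m Maximum specific growth rate (1/day).
#' @param K Half-saturation constant of the Monod uptake (kg COD/m^3).
#' @param s_in Feed substrate concentration (kg/m^3).
#'
#' @return An object of class `chemostat_params`.
#' @examples
#' p <- chemostat_params()
#' admissible_input_bounds(p)
#' @export
chemostat_params <- function(delta = 1 / 6.6, mu_m = 1.2, K = 4.95, s_in = 9) {
  vals <- c(delta = delta, mu_m = mu_m, K = K, s_in = s_in)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    ss_abort("all chemostat parameters must be finite and strictly positive",
             "switchsense_params_error")
  }
  structure(list(delta = delta, mu_m = mu_m, K = K, s_in = s_in),
            class = "chemostat_params")
}

#' @export
print.chemostat_params <- function(x, ...) {
  cat("<chemostat_params>\n")
  cat(sprintf("  delta = %.6g  mu_m = %.6g 1/day  K = %.6g kg/m^3  s_in = %.6g kg/m^3\n",
              x$delta, x$mu_m, x$K, x$s_in))
  cat(sprintf("  admissible dilution rate: (0, %.4f) 1/day\n",
              admissible_input_bounds(x)["Umax"]))
  invisible(x)
}

#' Admissible dilution-rate bounds
#'
#' The chemostat sustains a culture only for dilution rates in
#' \eqn{(U_{min}, U_{max})} with \eqn{U_{min} = 0} and
#' \eqn{U_{max} = s_{in}\,\mu_m / (K + s_{in})}; above the upper bound the
#' feed outruns growth and the culture washes out.
#'
#' @param params A [chemostat_params()] object.
#' @param Umin Optional lower bound override (some plants enforce a small
#'   positive minimum flow); default 0.
#' @return Named numeric vector `c(Umin, Umax)` in 1/day.
#' @export
admissible_input_bounds <- function(params, Umin = 0) {
  stopifnot(inherits(params, "chemostat_params"))
  c(Umin = Umin, Umax = params$s_in * params$mu_m / (params$K + params$s_in))
}

# internal: admissibility check with open-interval margin
check_admissible_U <- function(U, params, margin = 1e-6, what = "U") {
  bounds <- admissible_input_bounds(params)
  bad <- U <= bounds["Umin"] + 0 | U >= bounds["Umax"] * (1 - margin)
  if (any(bad)) {
    ss_abort(sprintf(
      "%s = %s outside the admissible open interval (%.6g, %.6g) 1/day",
      what, paste(signif(U[bad], 6), collapse = ", "),
      bounds["Umin"], bounds["Umax"]), "switchsense_admissibility_error")
  }
  invisible(TRUE)
}

#' Equilibrium operating point for a given dilution rate
#'
#' Evaluates the operating trajectory of the chemostat: for an admissible
#' dilution rate `U` the unique nontrivial equilibrium has substrate
#' \eqn{X_1 = K U / (\mu_m - U)} and biomass
#' \eqn{X_2 = \delta (s_{in} - X_1)}; the measured operating value is
#' \eqn{Y = X_1}.
#'
#' @param U Dilution rate(s), 1/day. Vectorized.
#' @param params A [chemostat_params()] object.
#' @return A tibble of class `operating_point` with columns `U, Y, X1, X2`.
#' @examples
#' equilibrium_from_input(0.6, chemostat_params())
#' @export
equilibrium_from_input <- function(U, params = chemostat_params()) {
  check_admissible_U(U, params)
  X1 <- params$K * U / (params$mu_m - U)
  X2 <- params$delta * (params$s_in - X1)
  new_operating_point(U = U, Y = X1, X1 = X1, X2 = X2)
}

new_operating_point <- function(U, Y, X1, X2) {
  out <- tibble::tibble(U = U, Y = Y, X1 = X1, X2 = X2)
  class(out) <- c("operating_point", class(out))
  out
}

#' Dilution rate producing a given substrate operating value
#'
#' Inverts the operating trajectory: \eqn{U = \mu_m Y / (K + Y)}.
#' Round-trips with [equilibrium_from_input()] to machine precision.
#'
#' @param Y Substrate operating value(s), kg/m^3, in \eqn{(0, s_{in})}.
#' @param params A [chemostat_params()] object.
#' @return Dilution rate(s), 1/day.
#' @export
input_from_output <- function(Y, params = chemostat_params()) {
  bad <- Y <= 0 | Y >= params$s_in
  if (any(bad)) {
    ss_abort(sprintf("Y = %s outside the admissible interval (0, s_in = %g)",
                     paste(signif(Y[bad], 6), collapse = ", "), params$s_in),
             "switchsense_admissibility_error")
  }
  params$mu_m * Y / (params$K + Y)
}

# right-hand side of the nonlinear chemostat; `ufun` maps time to dilution rate
chemostat_rhs <- function(t, x, parms) {
  u <- parms$ufun(t)
  f <- parms$mu_m * x[1] / (x[1] + parms$K)
  list(c(u * (parms$s_in - x[1]) - f * x[2] / parms$delta,
         f * x[2] - u * x[2]))
}

#' Simulate the nonlinear chemostat
#'
#' Integrates the two-state Monod chemostat with an adaptive stiff-capable
#' solver (deSolve's `lsoda`, rtol 1e-8 / atol 1e-10 by default). The input
#' may be a constant, a function of time, or a sampled series which is
#' interpolated linearly. States are never clipped inside the integrator: a
#' negative state signals an inadmissible input or solver failure and raises.
#'
#' @param params A [chemostat_params()] object.
#' @param input Constant dilution rate, a function `u(t)`, or a data frame
#'   with columns `t, u` (linearly interpolated, constant-extrapolated).
#' @param x0 Initial state `c(x1, x2)`, componentwise nonnegative. Defaults
#'   to the equilibrium of the initial input value.
#' @param horizon Final time (days).
#' @param step Output sampling step (days), default 0.01.
#' @param rtol,atol Solver tolerances.
#' @return A tibble of class `chemo_trajectory` with columns
#'   `t, u, y, x1, x2` (`y = x1`, the measured substrate).
#' @examples
#' tr <- simulate_chemostat(chemostat_params(), input = 0.6, horizon = 2)
#' tail(tr, 2)
#' @export
simulate_chemostat <- function(params, input, x0 = NULL, horizon,
                               step = 0.01, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "chemostat_params"))
  ufun <- as_input_function(input)
  times <- seq(0, horizon, by = step)
  uu <- ufun(times)
  if (any(uu < 0)) {
    ss_abort("negative dilution-rate input over the horizon",
             "switchsense_admissibility_error")
  }
  if (is.null(x0)) {
    x0 <- unlist(equilibrium_from_input(uu[1], params)[, c("X1", "X2")],
                 use.names = FALSE)
  }
  if (any(x0 < 0)) {
    ss_abort("initial state must be componentwise nonnegative",
             "switchsense_admissibility_error")
  }
  parms <- list(ufun = ufun, mu_m = params$mu_m, K = params$K,
                s_in = params$s_in, delta = params$delta)
  sol <- deSolve::ode(y = c(x1 = x0[1], x2 = x0[2]), times = times,
                      func = chemostat_rhs, parms = parms,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    ss_abort(sprintf("ODE solver failed near t = %.4g days",
                     sol[nrow(sol), "time"]), "switchsense_solver_error")
  }
  if (min(sol[, "x1"], sol[, "x2"]) < -1e-8) {
    ss_abort("integrator produced a negative state: inadmissible input or solver failure",
             "switchsense_solver_error")
  }
  new_trajectory(t = times, u = uu, x1 = sol[, "x1"], x2 = sol[, "x2"])
}

as_input_function <- function(input) {
  if (is.function(input)) return(input)
  if (is.numeric(input) && length(input) == 1) {
    force(input)
    return(function(t) rep(input, length(t)))
  }
  if (is.data.frame(input)) {
    stopifnot(all(c("t", "u") %in% names(input)))
    return(approxfun(input$t, input$u, rule = 2))
  }
  ss_abort("input must be a constant, a function of time, or a data frame with columns t, u",
           "switchsense_input_error")
}

new_trajectory <- function(t, u, x1, x2) {
  out <- tibble::tibble(t = as.numeric(t), u = as.numeric(u),
                        y = as.numeric(x1), x1 = as.numeric(x1),
                        x2 = as.numeric(x2))
  class(out) <- c("chemo_trajectory", class(out))
  out
}

#' Settling time of a trajectory component
#'
#' Smallest time after which the component stays within `band` times the
#' total excursion \eqn{|x(\infty) - x(0)|} of its final value, for all later
#' samples. The final value is the average of the trailing 5% of samples.
#' For excursion-free trajectories (start equals steady state, e.g. a pure
#' transient that returns to its origin) the band refers to the
#' steady-state value instead. The default 2% band is the usual
#' process-control convention.
#'
#' @param traj A data frame with a time column `t` and the component column.
#' @param component Column name, e.g. `"x1"`.
#' @param band Settling band as a fraction of the excursion (default 0.02).
#' @return Settling time (days); 0 for an already-settled trajectory.
#' @export
settling_time <- function(traj, component = "x1", band = 0.02) {
  x <- traj[[component]]
  t <- traj$t
  n <- length(x)
  ntail <- max(2L, ceiling(0.05 * n))
  xinf <- mean(x[(n - ntail + 1L):n])
  excursion <- abs(xinf - x[1])
  peak <- max(abs(x - xinf))
  scale <- max(abs(xinf), peak, 1e-300)
  if (peak <= 1e-9 * scale) return(0)
  # pure return-to-start transients have no net excursion; band then
  # refers to the steady-state value
  ref <- if (excursion >= 0.01 * peak) excursion else max(abs(xinf), peak)
  tol <- band * ref
  if (abs(x[n] - xinf) > tol) {
    ss_abort("no settling within horizon: trajectory end outside the band",
             "switchsense_settling_error")
  }
  dev <- abs(x - xinf)
  outside <- which(dev > tol)
  if (length(outside) == 0) return(0)
  k <- max(outside)
  if (k == n) {
    ss_abort("no settling within horizon", "switchsense_settling_error")
  }
  t[k + 1L]
}

#' Read / write a trajectory CSV
#'
#' Plain CSV with header `t,u,y,x1,x2`, '.' decimal, one row per sample.
#' @param traj A `chemo_trajectory` (or compatible data frame).
#' @param path File path.
#' @return `read_trajectory()` returns a `chemo_trajectory` tibble.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "u", "y", "x1", "x2")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  new_trajectory(t = d$t, u = d$u, x1 = d$x1, x2 = d$x2)
}

#' Read / write chemostat parameters (YAML or JSON)
#'
#' Keys `delta, mu_m, K, s_in`. Format chosen by file extension.
#' @param params A [chemostat_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path)
  chemostat_params(delta = as.numeric(x$delta), mu_m = as.numeric(x$mu_m),
                   K = as.numeric(x$K), s_in = as.numeric(x$s_in))
}
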