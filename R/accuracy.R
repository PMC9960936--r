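#' Simulate the linear approximant in deviation variables
#'
#' Integrates \eqn{\dot{\Delta x} = A \Delta x + b \Delta u} exactly on a
#' uniform grid (first-order-hold on the input deviation).
#'
#' @param lin A `linear_approximant`.
#' @param input_dev Constant input deviation, or a data frame `t, du`.
#' @param dx0 Initial state deviation `c(dx1, dx2)`, default zero.
#' @param horizon Final time (days).
#' @param step Sampling step (days).
#' @return Tibble with `t, du, dx1, dx2, dy` (`dy = dx1`).
#' @export
simulate_linear_approximant <- function(lin, input_dev, dx0 = c(0, 0),
                                        horizon, step = 0.01) {
  times <- seq(0, horizon, by = step)
  du <- if (is.data.frame(input_dev)) {
    approxfun(input_dev$t, input_dev$du, rule = 2)(times)
  } else rep(input_dev, length(times))
  X <- lti_sim(lin$A, lin$b, matrix(du, ncol = 1), step, x0 = dx0)
  tibble::tibble(t = times, du = du, dx1 = X[, 1], dx2 = X[, 2], dy = X[, 1])
}

#' Accuracy configuration for approximant-validity scans
#'
#' Collects the thresholds and perturbation ranges used to map the region
#' of inputs and initial conditions over which the linear approximant is an
#' acceptable stand-in for the nonlinear model. Inputs are perturbed as
#' \eqn{u = U (1 + p_u)} and initial states as \eqn{x_j(0) = (1 + p_j) X_j}.
#' Default ranges span the admissible limits
#' (\eqn{p_u \in (-1, U_{max}/U - 1]}, \eqn{p_j \in (-1, X_{j,max}/X_j - 1]});
#' default thresholds are 5% on all three discrepancy metrics.
#'
#' @param eps1,eps2,eps_inf Thresholds (%) on the steady-state, integral
#'   and sup-norm metrics.
#' @param pu_range,p1_range,p2_range Perturbation intervals (each within
#'   \eqn{(-1, \cdot)}); `NULL` means the admissible default.
#' @param n_pu,n_p1,n_p2 Grid sizes.
#' @param band Settling band used to truncate the time horizon (default 2%).
#' @return An `accuracy_config` list.
#' @export
accuracy_config <- function(eps1 = 5, eps2 = 5, eps_inf = 5,
                            pu_range = NULL, p1_range = NULL, p2_range = NULL,
                            n_pu = 21, n_p1 = 21, n_p2 = 21, band = 0.02) {
  stopifnot(eps1 > 0, eps2 > 0, eps_inf > 0)
  for (r in list(pu_range, p1_range, p2_range)) {
    if (!is.null(r) && !(r[1] > -1 && r[1] < r[2])) {
      ss_abort("perturbation ranges must satisfy -1 < min < max",
               "switchsense_config_error")
    }
  }
  structure(list(eps1 = eps1, eps2 = eps2, eps_inf = eps_inf,
                 pu_range = pu_range, p1_range = p1_range, p2_range = p2_range,
                 n_pu = n_pu, n_p1 = n_p1, n_p2 = n_p2, band = band),
            class = "accuracy_config")
}

trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

tail_limit <- function(x) {
  n <- length(x)
  mean(x[max(1L, n - ceiling(0.05 * n) + 1L):n])
}

#' Discrepancy metrics between nonlinear model and linear approximant
#'
#' Quantifies how far the linear approximant's response is from the
#' nonlinear response, as percentages of the size of the linear deviation
#' itself, with discrepancy \eqn{d_j(t) = x_j(t) - \Delta x_{L,j}(t) - X_j}:
#' \itemize{
#' \item `j_inf`: \eqn{100 \max_j \sup_t |d_j| / \max_j \sup_t |\Delta x_{L,j}|}
#'   (the per-component normalization is read as a ratio of sup-norms over
#'   components and time);
#' \item `j1`: \eqn{100 \sqrt{\sum_j d_j(\infty)^2 / \sum_j \Delta x_{L,j}(\infty)^2}},
#'   limits taken as the mean of the trailing 5% of samples;
#' \item `j2`: same ratio with \eqn{L_2} integrals truncated at each
#'   component's 2%-settling time.
#' }
#'
#' @param nl A `chemo_trajectory` of the nonlinear model.
#' @param lin Output of [simulate_linear_approximant()] on the same grid.
#' @param op The shared [equilibrium_from_input()] operating point.
#' @param Tmax Optional per-component truncation times; defaults to each
#'   nonlinear component's settling time.
#' @param band Settling band for the default `Tmax` rule.
#' @return One-row tibble `j_inf, j1, j2` (percent).
#' @export
accuracy_metrics <- function(nl, lin, op, Tmax = NULL, band = 0.02) {
  stopifnot(nrow(nl) == nrow(lin))
  d1 <- nl$x1 - lin$dx1 - op$X1
  d2 <- nl$x2 - lin$dx2 - op$X2
  xscale <- max(abs(op$X1), abs(op$X2))
  if (max(abs(lin$dx1), abs(lin$dx2)) < 1e-9 * xscale) {
    if (max(abs(d1), abs(d2)) < 1e-6 * xscale) {
      # both systems at rest: no deviation, no discrepancy
      return(tibble::tibble(j_inf = 0, j1 = 0, j2 = 0))
    }
    ss_abort("linear deviation identically zero: accuracy ratios undefined",
             "switchsense_degenerate_error")
  }
  if (is.null(Tmax)) {
    Tmax <- c(settling_time(nl, "x1", band), settling_time(nl, "x2", band))
    Tmax[Tmax == 0] <- max(nl$t)
  }
  i1 <- nl$t <= Tmax[1]; i2 <- nl$t <= Tmax[2]
  j_inf <- 100 * max(max(abs(d1[i1])), max(abs(d2[i2]))) /
    max(max(abs(lin$dx1[i1])), max(abs(lin$dx2[i2])))
  num1 <- tail_limit(d1)^2 + tail_limit(d2)^2
  den1 <- tail_limit(lin$dx1)^2 + tail_limit(lin$dx2)^2
  # decaying (zero-steady-deviation) experiments: both limits vanish
  j1 <- if (den1 < (1e-7 * xscale)^2) {
    if (num1 < (1e-5 * xscale)^2) 0 else ss_abort(
      "zero steady linear deviation with nonzero discrepancy",
      "switchsense_degenerate_error")
  } else 100 * sqrt(num1 / den1)
  num2 <- trapz(nl$t[i1], d1[i1]^2) + trapz(nl$t[i2], d2[i2]^2)
  den2 <- trapz(nl$t[i1], lin$dx1[i1]^2) + trapz(nl$t[i2], lin$dx2[i2]^2)
  j2 <- 100 * sqrt(num2 / den2)
  tibble::tibble(j_inf = j_inf, j1 = j1, j2 = j2)
}

#' One accuracy experiment: step input + perturbed initial conditions
#'
#' Runs the nonlinear model and the linear approximant side by side for the
#' step input \eqn{u = U (1 + p_u)} applied at \eqn{t = 0} from initial
#' conditions \eqn{x_j(0) = (1 + p_j) X_j}, and evaluates
#' [accuracy_metrics()].
#'
#' @param params A [chemostat_params()] object.
#' @param U Operating dilution rate.
#' @param pu,p1,p2 Relative perturbations of input and initial states.
#' @param horizon Simulation horizon (days); default long enough for the
#'   slow pole to settle well inside the 2% band.
#' @param step Sampling step.
#' @param band Settling band.
#' @return List with `nl`, `lin`, `metrics`.
#' @export
accuracy_experiment <- function(params, U, pu = 0, p1 = 0, p2 = 0,
                                horizon = NULL, step = 0.01, band = 0.02) {
  op <- equilibrium_from_input(U, params)
  lin <- linearize(params, U)
  Unew <- U * (1 + pu)
  check_admissible_U(Unew, params, what = "(1+pu)*U")
  if (is.null(horizon)) {
    pmin <- min(abs(c(lin$poles, -Unew, -io_coefficients(params, Unew)$hD)))
    horizon <- max(20, 12 / pmin)
  }
  x0 <- c((1 + p1) * op$X1, (1 + p2) * op$X2)
  nl <- simulate_chemostat(params, input = Unew, x0 = x0,
                           horizon = horizon, step = step)
  ltr <- simulate_linear_approximant(lin, input_dev = pu * U,
                                     dx0 = c(p1 * op$X1, p2 * op$X2),
                                     horizon = horizon, step = step)
  list(nl = nl, lin = ltr, op = op,
       metrics = accuracy_metrics(nl, ltr, op, band = band))
}

#' Closed-form steady-state discrepancy for a step input
#'
#' For the step \eqn{u = U(1 + p_u)} the steady-state metric does not
#' depend on initial conditions and reduces to
#' \deqn{J_1 = 100 \left| \frac{p_u U}{(1 + p_u) U - \mu_m} \right| \%.}
#'
#' @param pu Relative step size.
#' @param U Operating dilution rate (1/day).
#' @param mu_m Maximum growth rate (1/day).
#' @return Percentage.
#' @export
j1_closed_form <- function(pu, U, mu_m) {
  d <- (1 + pu) * U - mu_m
  if (any(abs(d) < 1e-12)) {
    ss_abort("(1+pu)*U equals mu_m: steady-state metric singular",
             "switchsense_degenerate_error")
  }
  100 * abs(pu * U / d)
}

#' Largest accuracy-acceptable input deviation
#'
#' Numerically inverts the closed-form steady-state metric: the largest
#' positive `pu` with \eqn{J_1(p_u) \le \varepsilon_1}, returned as the
#' absolute input deviation \eqn{p_u U} (1/day). This bound is what scales
#' the identification excitation amplitude.
#'
#' @param params A [chemostat_params()] object.
#' @param U Operating dilution rate.
#' @param eps1 Threshold (%), default 5.
#' @return Input deviation (1/day).
#' @export
max_input_deviation <- function(params, U, eps1 = 5) {
  check_admissible_U(U, params)
  Umax <- admissible_input_bounds(params)["Umax"]
  pu_hi <- Umax / U - 1 - 1e-9
  f <- function(pu) j1_closed_form(pu, U, params$mu_m) - eps1
  if (f(pu_hi) <= 0) return(pu_hi * U)
  uniroot(f, c(1e-12, pu_hi), tol = 1e-12)$root * U
}

#' Map the accuracy region over input and initial-condition perturbations
#'
#' Evaluates the three discrepancy metrics over a grid of
#' \eqn{(p_u, p_1, p_2)} perturbations and flags the cells where all three
#' fall below their thresholds. The admissible default ranges span the
#' washout limits of input and states.
#'
#' @param params A [chemostat_params()] object.
#' @param U Operating dilution rate.
#' @param config An [accuracy_config()].
#' @param step Sampling step for the paired simulations.
#' @return Tibble with `pu, p1, p2, j_inf, j1, j2, pass`.
#' @export
accuracy_region <- function(params, U, config = accuracy_config(),
                            step = 0.02) {
  op <- equilibrium_from_input(U, params)
  Umax <- admissible_input_bounds(params)["Umax"]
  rng <- function(r, hi) if (is.null(r)) c(-0.999, hi) else r
  pu_r <- rng(config$pu_range, Umax / U - 1 - 1e-6)
  p1_r <- rng(config$p1_range, params$s_in / op$X1 - 1)
  p2_r <- rng(config$p2_range, params$s_in * params$delta / op$X2 - 1)
  grid <- expand.grid(pu = seq(pu_r[1], pu_r[2], length.out = config$n_pu),
                      p1 = seq(p1_r[1], p1_r[2], length.out = config$n_p1),
                      p2 = seq(p2_r[1], p2_r[2], length.out = config$n_p2))
  res <- purrr::pmap_dfr(grid, function(pu, p1, p2) {
    m <- tryCatch(
      accuracy_experiment(params, U, pu, p1, p2, step = step,
                          band = config$band)$metrics,
      switchsense_error = function(e) {
        ss_abort(sprintf("accuracy scan failed at cell (pu=%.4g, p1=%.4g, p2=%.4g): %s",
                         pu, p1, p2, conditionMessage(e)),
                 "switchsense_region_error")
      })
    tibble::tibble(pu = pu, p1 = p1, p2 = p2, j_inf = m$j_inf,
                   j1 = m$j1, j2 = m$j2)
  })
  res$pass <- res$j1 < config$eps1 & res$j2 < config$eps2 &
    res$j_inf < config$eps_inf
  res
}

#' Export an accuracy region scan as CSV
#'
#' @param region Output of [accuracy_region()].
#' @param path File path.
#' @export
write_accuracy_region <- function(region, path) {
  utils::write.csv(as.data.frame(region), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
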