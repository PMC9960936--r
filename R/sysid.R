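# band-limit a series by zeroing Fourier components above a cutoff
fft_lowpass <- function(x, step, cutoff) {
  n <- length(x)
  X <- fft(x)
  freq <- 2 * pi * (0:(n - 1)) / (n * step)
  freq <- pmin(freq, 2 * pi / step - freq)     # two-sided
  X[freq > cutoff] <- 0
  Re(fft(X, inverse = TRUE)) / n
}

#' Smooth pseudo-random excitation signal
#'
#' Generates the identification input \eqn{u(t) = U + \lambda f_w(t)}:
#' `fw` starts from uniform pseudo-random values in \eqn{[-1, 1]} at the
#' sampling step and is band-limited to the smoothing cutoff in the
#' frequency domain, then rescaled to unit peak, giving a smooth curve that
#' is spectrally confined below the cutoff and bit-reproducible under a
#' fixed seed.
#'
#' @param U Nominal dilution rate (1/day).
#' @param lambda Excitation scale (1/day).
#' @param horizon Record length (days).
#' @param step Sampling step (days), default 0.01.
#' @param seed RNG seed.
#' @param cutoff Smoothing cutoff (rad/day), default 1.
#' @param params Optional [chemostat_params()]; if given, an excitation
#'   leaving the admissible input range raises (no silent clipping).
#' @return Tibble `t, fw, u`.
#' @export
excitation_signal <- function(U, lambda, horizon, step = 0.01, seed = 1,
                              cutoff = 1, params = NULL) {
  stopifnot(lambda >= 0, horizon > 0)
  t <- seq(0, horizon, by = step)
  set.seed(seed)
  raw <- runif(length(t), -1, 1)
  fw <- fft_lowpass(raw, step, cutoff)
  pk <- max(abs(fw))
  if (pk > 0) fw <- fw / pk
  u <- U + lambda * fw
  if (!is.null(params)) {
    bounds <- admissible_input_bounds(params)
    if (min(u) <= bounds["Umin"] || max(u) >= bounds["Umax"]) {
      ss_abort("excitation drives the input outside the admissible range",
               "switchsense_admissibility_error")
    }
  }
  tibble::tibble(t = t, fw = fw, u = u)
}

#' Band-limited measurement noise
#'
#' Zero-mean (exactly demeaned) band-limited random series with prescribed
#' RMS amplitude: white Gaussian samples band-limited to `bandwidth` in the
#' frequency domain, demeaned, and rescaled so that the root-mean-square
#' equals `amplitude`. Doubling the amplitude doubles the RMS exactly.
#'
#' @param seed RNG seed.
#' @param amplitude Target RMS (kg/m^3); 0 yields the zero series.
#' @param bandwidth Band limit (rad/day), default 10.
#' @param horizon Record length (days).
#' @param step Sampling step (days).
#' @return Tibble `t, noise`.
#' @export
measurement_noise <- function(seed, amplitude, bandwidth = 10, horizon,
                              step = 0.01) {
  stopifnot(amplitude >= 0)
  t <- seq(0, horizon, by = step)
  if (amplitude == 0) return(tibble::tibble(t = t, noise = rep(0, length(t))))
  set.seed(seed + 104729L)   # decouple from the excitation stream
  w <- rnorm(length(t))
  w <- fft_lowpass(w, step, bandwidth)
  w <- w - mean(w)
  w <- w * amplitude / sqrt(mean(w^2))
  tibble::tibble(t = t, noise = w)
}

#' Simulate an identification experiment on the chemostat
#'
#' Drives the nonlinear plant with the smooth excitation around an
#' operating point and overlays measurement noise on the substrate output.
#' The default excitation scale follows the accuracy-based rule
#' \eqn{\lambda = 0.5\%} of the largest input deviation keeping the linear
#' approximant accurate ([max_input_deviation()] at 5%); the default noise
#' RMS is 3% of the resulting output-deviation scale
#' \eqn{\lambda h_N / h_D} (see the methods vignette for the
#' signal-to-noise rationale behind this default).
#'
#' @param params A [chemostat_params()] object.
#' @param U Operating dilution rate.
#' @param lambda Excitation scale (1/day); `NULL` for the accuracy rule.
#' @param noise_amplitude Noise RMS (kg/m^3); `NULL` for 1e-4 * Y, 0 for a
#'   noise-free record.
#' @param noise_bandwidth Noise band limit (rad/day).
#' @param horizon,step Record length and sampling step (days).
#' @param seed RNG seed (drives excitation and noise).
#' @param cutoff Excitation smoothing cutoff (rad/day).
#' @return Tibble `t, u, y, noise` with attributes `U`, `Y`, `lambda`.
#' @export
identification_experiment <- function(params, U, lambda = NULL,
                                      noise_amplitude = NULL,
                                      noise_bandwidth = 10,
                                      horizon = 400, step = 0.01, seed = 1,
                                      cutoff = 1) {
  op <- equilibrium_from_input(U, params)
  if (is.null(lambda)) lambda <- 0.005 * max_input_deviation(params, U)
  if (is.null(noise_amplitude)) {
    # sensor noise scaled to the probe: the excitation rule keeps the
    # output deviation near lambda * hN/hD, and the default noise RMS is
    # 3% of that scale (SNR ~ 30 on the deviation channel)
    io <- io_coefficients(params, U)
    noise_amplitude <- 0.03 * lambda * io$hN / io$hD
  }
  exc <- excitation_signal(U, lambda, horizon, step, seed, cutoff, params)
  tr <- simulate_chemostat(params, input = exc[, c("t", "u")],
                           x0 = c(op$X1, op$X2), horizon = horizon,
                           step = step)
  nz <- measurement_noise(seed, noise_amplitude, noise_bandwidth, horizon, step)
  out <- tibble::tibble(t = tr$t, u = tr$u, y = tr$x1 + nz$noise,
                        noise = nz$noise)
  attr(out, "U") <- U; attr(out, "Y") <- op$Y; attr(out, "lambda") <- lambda
  out
}

# Euclidean projection onto the admissible set H = {hD >= m, hN >= m,
# hN U - hD Y >= m} by Dykstra's alternating projections (3 halfspaces)
project_to_H <- function(h, U, Y, margin = 1e-8) {
  A <- rbind(c(1, 0), c(0, 1), c(-Y, U))     # A %*% h >= b
  b <- c(margin, margin, margin)
  x <- h
  p <- matrix(0, 3, 2)
  for (iter in 1:500) {
    x_prev <- x
    for (i in 1:3) {
      v <- x + p[i, ]
      a <- A[i, ]
      viol <- b[i] - sum(a * v)
      xi <- if (viol > 0) v + viol * a / sum(a^2) else v
      p[i, ] <- v - xi
      x <- xi
    }
    if (sum((x - x_prev)^2) < 1e-30) break
  }
  x
}

#' Identify the first-order I/O coefficients by recursive least squares
#'
#' Forms the regression \eqn{\dot y_f = -\hat h_D y_f + \hat h_N u_f} on
#' Butterworth state-variable-filtered deviation records (the derivative
#' channel comes from the filter's state realization, never from
#' differencing the measured output) and runs the standard recursive
#' least-squares update with inverse-correlation initialization
#' `init_scale * I` and zero initial estimates, no forgetting. The three
#' regression channels are normalized to unit RMS before the recursion
#' (and the estimates rescaled to physical units afterwards), so the
#' initialization refers to unit-scale regressors whatever the probing
#' amplitude. The final
#' coefficients are the time averages of the estimate traces over
#' `window`, with the per-coefficient percentage fluctuation
#' \eqn{100 (\max - \min) / |\mathrm{avg}|} reported, and the result is
#' projected onto the admissible set \eqn{\mathbb{H}} (nearest admissible
#' point, Euclidean metric).
#'
#' @param data Data frame `t, u, y` on a uniform grid (e.g. from
#'   [identification_experiment()] or a CSV record).
#' @param U,Y Operating input and output values the deviations refer to.
#' @param filter A [design_lowpass()] filter; default the 1 / 1.1 rad/day,
#'   1 / 40 dB specification.
#' @param init_scale Inverse-correlation initialization (default 1e4).
#' @param window Averaging window `c(t_start, t_end)` in days (default
#'   `c(200, 400)`); must lie inside the record.
#' @param margin Admissible-set boundary margin for the projection.
#' @return An `identification_result`: `io` (an identified `io_model`),
#'   `trace` (tibble `t, hD, hN`), `fluctuation_pct`, `projected`.
#' @export
rls_identify <- function(data, U, Y, filter = design_lowpass(),
                         init_scale = 1e4, window = c(200, 400),
                         margin = 1e-8) {
  stopifnot(all(c("t", "u", "y") %in% names(data)))
  h <- diff(data$t)
  if (max(abs(h - h[1])) > 1e-9 * h[1]) {
    ss_abort("identification requires a uniform time grid", "switchsense_grid_error")
  }
  if (window[1] < data$t[1] || window[2] > data$t[length(data$t)] ||
      window[1] >= window[2]) {
    ss_abort("averaging window outside the record horizon", "switchsense_config_error")
  }
  du <- data$u - U
  dy <- data$y - Y
  uf <- apply_lowpass(filter, du, h[1])
  yf_all <- apply_lowpass(filter, dy, h[1], derivative = TRUE)
  yf <- yf_all$y; dyf <- yf_all$dy
  if (stats::sd(uf) < 1e-12 * (abs(U) + 1)) {
    ss_abort("insufficient excitation: filtered input deviation is constant",
             "switchsense_identifiability_error")
  }
  # normalize each channel to unit RMS so the inverse-correlation
  # initialization refers to unit-scale regressors (the probing amplitudes
  # are deliberately tiny; a raw-scale prior would bias the estimates)
  sy <- sqrt(mean(yf^2)); su <- sqrt(mean(uf^2)); sd_ <- sqrt(mean(dyf^2))
  if (sy < 1e-300 || sd_ < 1e-300) {
    ss_abort("insufficient excitation: filtered output deviation is constant",
             "switchsense_identifiability_error")
  }
  yf_n <- yf / sy; uf_n <- uf / su; dyf_n <- dyf / sd_
  n <- length(uf)
  theta <- c(0, 0)                       # normalized (hD, hN)
  P <- diag(2) * init_scale
  trace <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    phi <- c(-yf_n[k], uf_n[k])
    Pphi <- P %*% phi
    denom <- 1 + sum(phi * Pphi)
    K <- Pphi / denom
    theta <- theta + K * (dyf_n[k] - sum(phi * theta))
    P <- P - K %*% t(Pphi)
    trace[k, ] <- theta
  }
  trace[, 1] <- trace[, 1] * sd_ / sy    # back to physical units
  trace[, 2] <- trace[, 2] * sd_ / su
  if (sum(diag(P)) > 0.5 * 2 * init_scale) {
    ss_abort("insufficient excitation: inverse-correlation matrix did not contract",
             "switchsense_identifiability_error")
  }
  inwin <- data$t >= window[1] & data$t <= window[2]
  est <- colMeans(trace[inwin, , drop = FALSE])
  fluct <- 100 * (apply(trace[inwin, , drop = FALSE], 2, max) -
                    apply(trace[inwin, , drop = FALSE], 2, min)) / abs(est)
  proj <- project_to_H(est, U, Y, margin)
  io <- new_io_model(hD = proj[1], hN = proj[2], identified = TRUE,
                     fluctuation_pct = setNames(fluct, c("hD", "hN")),
                     window = window)
  structure(list(io = io, U = U, Y = Y,
                 trace = tibble::tibble(t = data$t, hD = trace[, 1],
                                        hN = trace[, 2]),
                 init_scale = init_scale, window = window,
                 fluctuation_pct = io$fluctuation_pct,
                 projected = any(abs(proj - est) > 1e-12 * (abs(est) + 1))),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result>  U = %.6g, Y = %.6g\n", x$U, x$Y))
  cat(sprintf("  hD_hat = %.6g (fluctuation %.3g%%), hN_hat = %.6g (fluctuation %.3g%%)\n",
              x$io$hD, x$fluctuation_pct[1], x$io$hN, x$fluctuation_pct[2]))
  if (x$projected) cat("  (estimate projected onto the admissible set H)\n")
  invisible(x)
}

#' @method tidy identification_result
#' @export
tidy.identification_result <- function(x, ...) {
  tidy(x$io)
}

#' @method glance identification_result
#' @export
glance.identification_result <- function(x, ...) {
  tibble::tibble(U = x$U, Y = x$Y, hD = x$io$hD, hN = x$io$hN,
                 fluct_hD_pct = x$fluctuation_pct[[1]],
                 fluct_hN_pct = x$fluctuation_pct[[2]],
                 projected = x$projected)
}

#' Write an identification I/O record as CSV
#'
#' Columns `t, u, y` plus `noise` when present.
#' @param data The record tibble.
#' @param path File path.
#' @export
write_io_record <- function(data, path) {
  cols <- intersect(c("t", "u", "y", "noise"), names(data))
  utils::write.csv(as.data.frame(data)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_io_record
#' @export
read_io_record <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
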