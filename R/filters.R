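# Linear-system utilities: matrix exponential, first-order-hold (FOH)
# discretization, LTI simulation, and an analog Butterworth low-pass
# realized as cascaded second-order sections. The cascade keeps the design
# well conditioned at the high orders a tight passband/stopband spec
# demands (a monolithic polynomial realization is numerically useless
# beyond order ~20).

# Pade scaling-and-squaring matrix exponential (small dense matrices)
expm_ss <- function(A) {
  n <- nrow(A)
  if (n == 1L) return(matrix(exp(A[1, 1]), 1, 1))
  nrmA <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin) / 5.4)))
  A <- A / 2^s
  # degree-13 Pade
  b <- c(64764752532480000, 32382376266240000, 7771770303897600,
         1187353796428800, 129060195264000, 10559470521600, 670442572800,
         33522128640, 1323241920, 40840800, 960960, 16380, 182, 1)
  I <- diag(n)
  A2 <- A %*% A; A4 <- A2 %*% A2; A6 <- A2 %*% A4
  U <- A %*% (A6 %*% (b[14] * A6 + b[12] * A4 + b[10] * A2) +
                b[8] * A6 + b[6] * A4 + b[4] * A2 + b[2] * I)
  V <- A6 %*% (b[13] * A6 + b[11] * A4 + b[9] * A2) +
    b[7] * A6 + b[5] * A4 + b[3] * A2 + b[1] * I
  X <- solve(V - U, V + U)
  for (k in seq_len(s)) X <- X %*% X
  X
}

# FOH discretization of x' = A x + B u at step h, u piecewise linear:
# x[k+1] = Ad x[k] + B0 u[k] + B1 u[k+1]
foh_discretize <- function(A, B, h) {
  B <- as.matrix(B)
  n <- nrow(A); m <- ncol(B)
  Aug <- matrix(0, n + 2 * m, n + 2 * m)
  Aug[1:n, 1:n] <- A
  Aug[1:n, n + 1:m] <- B
  Aug[n + 1:m, n + m + 1:m] <- diag(m)
  E <- expm_ss(Aug * h)
  Ad <- E[1:n, 1:n, drop = FALSE]
  M0 <- E[1:n, n + 1:m, drop = FALSE]        # int e^{A(h-s)} B ds
  M1 <- E[1:n, n + m + 1:m, drop = FALSE]    # int e^{A(h-s)} B s ds
  list(Ad = Ad, B0 = M0 - M1 / h, B1 = M1 / h)
}

# simulate x' = A x + B u(t) on a uniform grid; u is an (nt x m) matrix of
# samples interpolated linearly (FOH-exact). Returns the (nt x n) state
# matrix.
lti_sim <- function(A, B, u, h, x0 = NULL) {
  u <- as.matrix(u)
  n <- nrow(A); nt <- nrow(u)
  d <- foh_discretize(A, B, h)
  X <- matrix(0, nt, n)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  X[1, ] <- x
  for (k in seq_len(nt - 1L)) {
    x <- d$Ad %*% x + d$B0 %*% u[k, ] + d$B1 %*% u[k + 1L, ]
    X[k + 1L, ] <- x
  }
  X
}

# second-order IIR y(z)/x(z) = (n0 z^2 + n1 z + n2)/(z^2 + d1 z + d2),
# zero initial conditions; implemented with stats::filter (C loops)
iir_apply <- function(num, den, x) {
  xp <- c(0, 0, x)
  ma <- stats::filter(xp, num, method = "convolution", sides = 1)
  ma <- as.numeric(ma)[-(1:2)]
  as.numeric(stats::filter(ma, -den[-1], method = "recursive"))
}

# discrete transfer functions of one FOH-discretized section, from its
# scalar input to each state
section_state_tfs <- function(Ad, b0, b1) {
  den <- c(1, -(Ad[1, 1] + Ad[2, 2]), Ad[1, 1] * Ad[2, 2] - Ad[1, 2] * Ad[2, 1])
  num1 <- c(b1[1],
            b0[1] - Ad[2, 2] * b1[1] + Ad[1, 2] * b1[2],
            -Ad[2, 2] * b0[1] + Ad[1, 2] * b0[2])
  num2 <- c(b1[2],
            b0[2] - Ad[1, 1] * b1[2] + Ad[2, 1] * b1[1],
            -Ad[1, 1] * b0[2] + Ad[2, 1] * b0[1])
  list(den = den, num1 = num1, num2 = num2)
}

#' Design an analog Butterworth low-pass filter
#'
#' Minimal-order analog Butterworth meeting a passband/stopband attenuation
#' specification, realized as cascaded unity-DC-gain second-order sections
#' (plus one first-order section for odd orders). Frequencies are in rad per
#' time unit of the series the filter is applied to. The defaults are the
#' tight specification used for identification prefiltering: passband edge
#' 1, stopband edge 1.1, attenuations 1 dB and 40 dB (realized order 56).
#'
#' @param wp,ws Passband and stopband edge frequencies (rad/unit), `ws > wp`.
#' @param Rp,Rs Maximum passband attenuation and minimum stopband
#'   attenuation, dB.
#' @return A `butter_filter`: order `n`, cutoff `wc`, section table.
#' @export
design_lowpass <- function(wp = 1, ws = 1.1, Rp = 1, Rs = 40) {
  if (!(ws > wp) || wp <= 0) {
    ss_abort("stopband edge must exceed passband edge (both > 0)",
             "switchsense_filter_error")
  }
  n <- ceiling(log10((10^(Rs / 10) - 1) / (10^(Rp / 10) - 1)) /
                 (2 * log10(ws / wp)))
  wc <- wp / (10^(Rp / 10) - 1)^(1 / (2 * n))
  # poles on the wc circle; pair into biquads by damping ratio
  k <- seq_len(floor(n / 2))
  zeta <- -cos(pi * (2 * k + n - 1) / (2 * n))   # in (0, 1)
  sections <- lapply(zeta, function(z) list(order = 2L, wc = wc, zeta = z))
  if (n %% 2 == 1L) {
    # real pole first so the final section is a biquad (clean derivative tap)
    sections <- c(list(list(order = 1L, wc = wc)), sections)
  }
  structure(list(n = n, wc = wc, wp = wp, ws = ws, Rp = Rp, Rs = Rs,
                 sections = sections),
            class = "butter_filter")
}

#' @export
print.butter_filter <- function(x, ...) {
  cat(sprintf("<butter_filter> order %d Butterworth low-pass, wc = %.6g rad/unit\n",
              x$n, x$wc))
  cat(sprintf("  spec: <=%g dB at %g, >=%g dB at %g\n", x$Rp, x$wp, x$Rs, x$ws))
  invisible(x)
}

#' Frequency response of a `butter_filter`
#'
#' @param filt A [design_lowpass()] filter.
#' @param w Frequencies (rad/unit).
#' @return Complex response values.
#' @export
filter_freq_response <- function(filt, w) {
  s <- 1i * w
  H <- rep(1 + 0i, length(w))
  for (sec in filt$sections) {
    H <- H * if (sec$order == 1L) {
      sec$wc / (s + sec$wc)
    } else {
      sec$wc^2 / (s^2 + 2 * sec$zeta * sec$wc * s + sec$wc^2)
    }
  }
  H
}

#' Apply a low-pass filter to a uniformly sampled series
#'
#' Runs the cascaded state realization with exact first-order-hold
#' discretization at the series' sampling step. With `derivative = TRUE`
#' the time derivative of the filtered output is also returned, taken from
#' the final section's state equation, so the derivative channel is
#' obtained without ever differencing the raw series (state-variable
#' filtering).
#'
#' @param filt A [design_lowpass()] filter.
#' @param x Numeric series sampled at step `step`.
#' @param step Sampling step (time units).
#' @param derivative Also return the derivative of the filtered series.
#' @return Filtered series, or `list(y, dy)` when `derivative = TRUE`.
#' @export
apply_lowpass <- function(filt, x, step, derivative = FALSE) {
  u <- as.numeric(x)
  last <- filt$sections[[length(filt$sections)]]
  for (i in seq_along(filt$sections)) {
    sec <- filt$sections[[i]]
    if (sec$order == 1L) {
      d <- foh_discretize(matrix(-sec$wc, 1, 1), matrix(1, 1, 1), step)
      xs <- iir_apply(c(d$B1[1], d$B0[1], 0), c(1, -d$Ad[1], 0), u)
      if (derivative && i == length(filt$sections)) {
        dy <- sec$wc * (-sec$wc * xs + u)
      }
      u <- sec$wc * xs
    } else {
      A <- matrix(c(0, -sec$wc^2, 1, -2 * sec$zeta * sec$wc), 2, 2)
      d <- foh_discretize(A, c(0, 1), step)
      tf <- section_state_tfs(d$Ad, d$B0, d$B1)
      x1 <- iir_apply(tf$num1, tf$den, u)
      if (derivative && i == length(filt$sections)) {
        x2 <- iir_apply(tf$num2, tf$den, u)
        dy <- sec$wc^2 * x2
      }
      u <- sec$wc^2 * x1
    }
  }
  if (derivative) list(y = u, dy = dy) else u
}
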