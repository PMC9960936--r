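# shared fixtures: benchmark parameters and a reference observer design
bench_params <- function() chemostat_params()

ref_design <- function() {
  io <- io_coefficients(bench_params(), 0.6)
  gains_from_poles(io, U = 0.6, Y = 4.95, delta = 1 / 6.6,
                   a = 3.5, rho1 = 3.6, rho2 = 7)
}

# independent Jacobian oracle: complex-step differentiation of the
# chemostat vector field (machine-precision derivatives of the rational rhs)
chemostat_field <- function(x, u, p) {
  f <- p$mu_m * x[1] / (x[1] + p$K)
  c(u * (p$s_in - x[1]) - f * x[2] / p$delta, f * x[2] - u * x[2])
}

complex_step_jacobian <- function(x, u, p) {
  hstep <- 1e-100
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    xz <- as.complex(x)
    xz[j] <- xz[j] + hstep * 1i
    J[, j] <- Im(chemostat_field(xz, u, p)) / hstep
  }
  J
}

complex_step_b <- function(x, u, p) {
  hstep <- 1e-100
  Im(chemostat_field(as.complex(x), u + hstep * 1i, p)) / hstep
}

# independent matrix exponential through the eigen decomposition
expm_eigen <- function(M, t) {
  e <- eigen(M)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

random_admissible_U <- function(n, params, lo_frac = 0.02, hi_frac = 0.98) {
  Umax <- admissible_input_bounds(params)["Umax"]
  runif(n, lo_frac * Umax, hi_frac * Umax)
}
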