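#' State-space linear approximant at an operating point
#'
#' Linearizes the chemostat about the equilibrium of an admissible dilution
#' rate `U`. In deviation variables \eqn{\Delta x = x - \tilde X},
#' \eqn{\Delta u = u - U}, the approximant is
#' \eqn{\dot{\Delta x} = A \Delta x + b \Delta u},
#' \eqn{\Delta y = c \Delta x} with
#' \deqn{A = \begin{pmatrix} -h_D - U & -U/\delta \\ h_D \delta & 0
#'  \end{pmatrix},\quad
#'  b = \begin{pmatrix} h_N \\ -\delta h_N \end{pmatrix},\quad c = (1\; 0),}
#' and poles \eqn{\{-U, -h_D\}}: both strictly negative for admissible `U`,
#' so every operating point is locally asymptotically stable.
#'
#' @param params A [chemostat_params()] object.
#' @param U Admissible dilution rate (1/day).
#' @return A `linear_approximant`: list with `A`, `b`, `c`, `op`
#'   (the [equilibrium_from_input()] row) and `poles`.
#' @export
linearize <- function(params, U) {
  op <- equilibrium_from_input(U, params)
  io <- io_coefficients(params, U)
  lin_from_io_op(io, op, params$delta)
}

lin_from_io_op <- function(io, op, delta) {
  U <- op$U
  A <- matrix(c(-io$hD - U, io$hD * delta, -U / delta, 0), 2, 2)
  b <- c(io$hN, -delta * io$hN)
  structure(list(A = A, b = b, c = c(1, 0), op = op,
                 poles = c(-U, -io$hD), io = io, delta = delta),
            class = "linear_approximant")
}

#' @export
print.linear_approximant <- function(x, ...) {
  cat("<linear_approximant>  U =", signif(x$op$U, 6),
      " Y =", signif(x$op$Y, 6), "\n")
  cat("  poles:", signif(x$poles, 6), "\n")
  cat("  A:\n"); print(signif(x$A, 7))
  cat("  b:", signif(x$b, 7), "  c:", x$c, "\n")
  invisible(x)
}

#' First-order I/O approximant coefficients
#'
#' The transfer function of the linear approximant from \eqn{\Delta u} to
#' \eqn{\Delta y} reduces (after cancelling the uncontrollable pole at
#' \eqn{-U}) to the first-order model
#' \eqn{\dot{\Delta y} + h_D \Delta y = h_N \Delta u} with
#' \deqn{h_D = \frac{[s_{in}(\mu_m - U) - K U](\mu_m - U)}{K \mu_m}, \qquad
#'       h_N = \frac{\mu_m s_{in} - (K + s_{in}) U}{\mu_m - U}.}
#' Both are strictly positive on the admissible range; \eqn{h_N \to 0^+} as
#' \eqn{U \to U_{max}}.
#'
#' @inheritParams linearize
#' @return An `io_model`: list with `hD`, `hN`, `nc = 1`,
#'   `identified = FALSE`.
#' @export
io_coefficients <- function(params, U) {
  check_admissible_U(U, params)
  hD <- (params$s_in * (params$mu_m - U) - params$K * U) *
    (params$mu_m - U) / (params$K * params$mu_m)
  hN <- (params$mu_m * params$s_in - (params$K + params$s_in) * U) /
    (params$mu_m - U)
  new_io_model(hD = hD, hN = hN)
}

new_io_model <- function(hD, hN, identified = FALSE, fluctuation_pct = NULL,
                         window = NULL) {
  structure(list(hD = hD, hN = hN, nc = 1L, identified = identified,
                 fluctuation_pct = fluctuation_pct, window = window),
            class = "io_model")
}

#' @export
print.io_model <- function(x, ...) {
  cat(sprintf("<io_model>  dy/dt + hD dy = hN du;  hD = %.6g 1/day, hN = %.6g\n",
              x$hD, x$hN))
  if (isTRUE(x$identified)) {
    cat(sprintf("  identified over window [%g, %g] days; fluctuation %% (hD, hN): %s\n",
                x$window[1], x$window[2],
                paste(signif(x$fluctuation_pct, 3), collapse = ", ")))
  }
  invisible(x)
}

# membership of the admissible coefficient set H:
# hD > 0, hN > 0, hN U - hD Y > 0 (needed for mu_m, K > 0 on inversion)
io_admissible <- function(io, U, Y, margin = 0) {
  io$hD > margin && io$hN > margin && (io$hN * U - io$hD * Y) > margin
}

#' Reconstruct physical parameters from I/O coefficients
#'
#' Inverts the coefficient map at a known operating point \eqn{(U, Y)} with
#' known yield \eqn{\delta}:
#' \deqn{\mu_m = \frac{h_N U^2}{h_N U - h_D Y},\quad s_{in} = h_N + Y,\quad
#'       K = \frac{h_D Y^2}{h_N U - h_D Y}.}
#' This is the I/O-reconstructability property that lets a purely data-driven
#' (identified) first-order model determine the full state-space approximant.
#' Requires \eqn{h_N U - h_D Y > 0}; at the boundary the reconstruction
#' degenerates (\eqn{\mu_m, K \to \infty}) and the function raises.
#'
#' @param io An `io_model`.
#' @param U,Y Operating input and output values.
#' @param delta Known yield constant.
#' @return A [chemostat_params()] object.
#' @export
reconstruct_parameters <- function(io, U, Y, delta) {
  w <- io$hN * U - io$hD * Y
  if (!(io$hD > 0 && io$hN > 0) || w <= 0) {
    ss_abort(sprintf(
      "I/O model outside the admissible set H (hD = %.4g, hN = %.4g, hN*U - hD*Y = %.4g): state-space approximant not reconstructable",
      io$hD, io$hN, w), "switchsense_reconstructability_error")
  }
  chemostat_params(delta = delta,
                   mu_m = io$hN * U^2 / w,
                   K = io$hD * Y^2 / w,
                   s_in = io$hN + Y)
}

#' State-space approximant directly from I/O coefficients
#'
#' Builds the `linear_approximant` from `(hD, hN)` and the operating point
#' without going through physical parameters: \eqn{A(h_D)}, \eqn{b(h_N)} as
#' in [linearize()], and operating state \eqn{\tilde X = (Y,\; \delta h_N)}.
#' Identical to `linearize(reconstruct_parameters(io, U, Y, delta), U)`.
#'
#' @inheritParams reconstruct_parameters
#' @return A `linear_approximant`.
#' @export
statespace_from_io <- function(io, U, Y, delta) {
  w <- io$hN * U - io$hD * Y
  if (!(io$hD > 0 && io$hN >= 0) || w <= 0) {
    ss_abort(sprintf(
      "I/O model outside the admissible set H (hN*U - hD*Y = %.4g)", w),
      "switchsense_reconstructability_error")
  }
  op <- new_operating_point(U = U, Y = Y, X1 = Y, X2 = delta * io$hN)
  lin_from_io_op(io, op, delta)
}

#' Observability of the linear approximant
#'
#' The observability matrix is
#' \eqn{O = [c; cA] = [(1, 0); (-h_D - U, -U/\delta)]} with determinant
#' \eqn{-U/\delta}: the approximant is observable iff \eqn{U \neq 0},
#' independently of the I/O coefficients.
#'
#' @param lin A `linear_approximant`.
#' @return List with `matrix` (2x2) and `observable` flag.
#' @export
observability <- function(lin) {
  O <- rbind(lin$c, as.numeric(lin$c %*% lin$A))
  list(matrix = O, observable = abs(det(O)) > .Machine$double.eps)
}

#' Read / write an I/O model as JSON
#'
#' Keys `hD, hN, nc, identified, fluctuation_pct, window`.
#' @param io An `io_model`.
#' @param path File path.
#' @export
write_io_model <- function(io, path) {
  jsonlite::write_json(unclass(io), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_io_model
#' @export
read_io_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_io_model(hD = x$hD, hN = x$hN,
               identified = isTRUE(x$identified),
               fluctuation_pct = x$fluctuation_pct,
               window = x$window)
}

#' @method tidy io_model
#' @export
tidy.io_model <- function(x, ...) {
  tibble::tibble(term = c("hD", "hN"),
                 estimate = c(x$hD, x$hN),
                 fluctuation_pct = if (is.null(x$fluctuation_pct)) c(NA_real_, NA_real_)
                                   else x$fluctuation_pct,
                 identified = x$identified)
}

#' @method tidy linear_approximant
#' @export
tidy.linear_approximant <- function(x, ...) {
  tibble::tibble(U = x$op$U, Y = x$op$Y, X1 = x$op$X1, X2 = x$op$X2,
                 hD = x$io$hD, hN = x$io$hN,
                 pole1 = x$poles[1], pole2 = x$poles[2])
}
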