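#' Plot a chemostat trajectory
#'
#' Substrate and biomass concentrations plus the dilution-rate input
#' against time, one facet per variable.
#'
#' @param object A `chemo_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chemo_trajectory
#' @export
autoplot.chemo_trajectory <- function(object, ...) {
  long <- tidyr_pivot(object[, c("t", "u", "x1", "x2")],
                      c(u = "dilution rate u [1/day]",
                        x1 = "substrate x1 [kg/m^3]",
                        x2 = "biomass x2 [kg/m^3]"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [days]", y = NULL)
}

# minimal long-format helper (keeps tidyr out of Imports)
tidyr_pivot <- function(df, labels) {
  purrr::map_dfr(names(labels), function(v) {
    tibble::tibble(t = df$t, variable = labels[[v]], value = df[[v]])
  })
}

#' Plot an identification estimate trace
#'
#' Coefficient estimates against time with the averaging window shaded.
#'
#' @param object An `identification_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot identification_result
#' @export
autoplot.identification_result <- function(object, ...) {
  long <- tidyr_pivot(object$trace,
                      c(hD = "hD estimate [1/day]", hN = "hN estimate"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::annotate("rect", xmin = object$window[1], xmax = object$window[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [days]", y = NULL)
}

#' Plot a switched soft-sensor run
#'
#' True states and their estimates, with stage boundaries marked.
#'
#' @param object A `switched_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot switched_run
#' @export
autoplot.switched_run <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(t = object$t, value = object$x1,
                   variable = "substrate [kg/m^3]", series = "plant"),
    tibble::tibble(t = object$t, value = object$xhat1,
                   variable = "substrate [kg/m^3]", series = "estimate"),
    tibble::tibble(t = object$t, value = object$x2,
                   variable = "biomass [kg/m^3]", series = "plant"),
    tibble::tibble(t = object$t, value = object$xhat2,
                   variable = "biomass [kg/m^3]", series = "estimate"))
  switches <- object$t[c(FALSE, diff(object$stage) != 0)]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     linetype = .data$series)) +
    ggplot2::geom_vline(xintercept = switches, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [days]", y = NULL, linetype = NULL)
}

#' Plot target operating areas
#'
#' One horizontal segment per observer over the dilution-rate axis, with
#' the nominal point marked; overlapping consecutive segments visualize
#' the dense web.
#'
#' @param areas Tibble from [target_areas()].
#' @return A ggplot object.
#' @export
plot_target_areas <- function(areas) {
  ggplot2::ggplot(areas) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       y = .data$i, yend = .data$i)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$U, y = .data$i)) +
    ggplot2::labs(x = "dilution rate U [1/day]", y = "observer index")
}

#' Plot a slice of an accuracy-region scan
#'
#' Pass/fail cells over the input and substrate-initial-condition
#' perturbations, at the biomass perturbation slice nearest `p2`.
#'
#' @param region Tibble from [accuracy_region()].
#' @param p2 Slice value (default 0).
#' @return A ggplot object.
#' @export
plot_accuracy_region <- function(region, p2 = 0) {
  p2s <- unique(region$p2)
  slice <- region[region$p2 == p2s[which.min(abs(p2s - p2))], ]
  ggplot2::ggplot(slice, ggplot2::aes(x = .data$pu, y = .data$p1,
                                      fill = .data$pass)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "input perturbation pu", y = "x1(0) perturbation p1",
                  fill = "accurate")
}
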