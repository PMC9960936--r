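#' Assemble a soft-sensor experiment configuration
#'
#' Collects everything the six-step design pipeline needs: plant
#' parameters, the bank point set (explicit nominal inputs or an automatic
#' search), the design thresholds, identification settings, and the
#' transition to execute. Configurations are plain lists and can be read
#' from / written to YAML with [read_experiment_config()].
#'
#' @param params A [chemostat_params()] object (the true plant used to
#'   generate identification data and to simulate the transition).
#' @param bank_U Nominal dilution rates for the bank, or `NULL` to search
#'   automatically over `bank_range` (see [auto_bank_points()]).
#' @param bank_range Range `c(from, to)` for the automatic point search.
#' @param a Stability margin (1/day), default 3.5.
#' @param zeta_oa Convergence threshold for pole optimization, default 0.5.
#' @param chi_oa,chi_ob Target-area thresholds, defaults 0.5 and 0.001.
#' @param from,to Transition endpoints (1/day).
#' @param intermediates Optional hand-picked intermediate destinations.
#' @param identify Run the identification step (default TRUE); when FALSE
#'   the exact I/O coefficients are used (a design-study shortcut).
#' @param ident_horizon,ident_step,ident_window Identification record
#'   length, sampling step, and averaging window (days).
#' @param noise_amplitude Measurement-noise RMS; `NULL` for the default
#'   rule (0.01% of each operating output).
#' @param timing_factor Switching-time multiple of the stage settling time.
#' @param step Simulation sampling step (days).
#' @param seed Base RNG seed.
#' @param symmetric Symmetric target areas (default TRUE).
#' @param out_dir Optional artifact directory.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(params = chemostat_params(), bank_U = NULL,
                              bank_range = NULL, a = 3.5, zeta_oa = 0.5,
                              chi_oa = 0.5, chi_ob = 0.001,
                              from, to, intermediates = NULL,
                              identify = TRUE, ident_horizon = 400,
                              ident_step = 0.01, ident_window = c(200, 400),
                              noise_amplitude = NULL, timing_factor = 1.1,
                              step = 0.01, seed = 1, symmetric = TRUE,
                              out_dir = NULL) {
  stopifnot(a > 0, zeta_oa > 0, chi_oa > 0, chi_ob > 0)
  structure(list(params = params, bank_U = bank_U, bank_range = bank_range,
                 a = a, zeta_oa = zeta_oa, chi_oa = chi_oa, chi_ob = chi_ob,
                 from = from, to = to, intermediates = intermediates,
                 identify = identify, ident_horizon = ident_horizon,
                 ident_step = ident_step, ident_window = ident_window,
                 noise_amplitude = noise_amplitude,
                 timing_factor = timing_factor, step = step, seed = seed,
                 symmetric = symmetric, out_dir = out_dir),
            class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  p <- x$params
  x$params <- chemostat_params(delta = p$delta, mu_m = p$mu_m, K = p$K,
                               s_in = p$s_in)
  if (!is.null(x$ident_window)) x$ident_window <- as.numeric(x$ident_window)
  if (!is.null(x$intermediates)) x$intermediates <- as.numeric(x$intermediates)
  do.call(experiment_config, x)
}

#' Automatic bank point search with overlapping symmetric areas
#'
#' Chains nominal points upward from `from`: given the optimized observer
#' at the current nominal, its symmetric half-width is estimated from the
#' closed-form metric as \eqn{u_{max} = \sqrt{\chi_{O,B} /
#' \tilde J_{e,O}}}, and the next nominal is placed so that consecutive
#' areas overlap with a safety fraction. The scan-based [target_areas()]
#' plus [dense_web_check()] remain the authority on the produced set.
#'
#' @param params A [chemostat_params()] object.
#' @param from,to Range of operating inputs to cover.
#' @param a,zeta_oa,chi_ob Design thresholds.
#' @param overlap Fraction of the half-width kept as overlap (default 0.5).
#' @param max_points Safety cap on the number of points.
#' @return Tibble `U, Y, hD, hN` (a [bank_points()] table).
#' @export
auto_bank_points <- function(params, from, to, a = 3.5, zeta_oa = 0.5,
                             chi_ob = 0.001, overlap = 0.5, max_points = 60) {
  umax_at <- function(U) {
    op <- equilibrium_from_input(U, params)
    io <- io_coefficients(params, U)
    opt <- optimize_poles(io, U, op$Y, params$delta, a, zeta_oa)
    min(sqrt(chi_ob / opt$value), U)    # cap: area cannot cross zero
  }
  Us <- from
  repeat {
    if (length(Us) >= max_points) {
      ss_abort("automatic point search exceeded max_points before covering the range",
               "switchsense_planning_error")
    }
    U_cur <- Us[length(Us)]
    u_cur <- umax_at(U_cur)
    if (U_cur + u_cur >= to) break
    reach <- U_cur + (1 - overlap) * u_cur
    g <- function(Unext) (Unext - (1 - overlap) * umax_at(Unext)) - reach
    hi <- min(to, admissible_input_bounds(params)["Umax"] * 0.999)
    U_next <- if (g(hi) <= 0) hi else
      uniroot(g, c(U_cur * (1 + 1e-6), hi), tol = 1e-6)$root
    if (U_next <= U_cur * (1 + 1e-9)) {
      ss_abort("automatic point search stalled (areas too narrow)",
               "switchsense_planning_error")
    }
    Us <- c(Us, U_next)
  }
  if (Us[length(Us)] < to) Us <- c(Us, to)
  bank_points(params, Us)
}

#' Run the six-step soft-sensor design pipeline
#'
#' Executes the full design procedure:
#' \enumerate{
#' \item fix the set of operating points (explicit or automatic search);
#' \item identify the I/O approximant at each point from simulated
#'   excitation records (skipped when `identify = FALSE`);
#' \item check reconstructability and recover the state-space approximants;
#' \item build the bank of pole-optimized observers;
#' \item determine each observer's target operating area;
#' \item gate on the dense-web principle — on failure the pipeline halts
#'   and reports the gaps (a denser point set is needed); otherwise plan
#'   and execute the requested transition.
#' }
#' All randomness derives from `config$seed` (entry `i` uses
#' `seed + i`); reruns with the same configuration reproduce every number.
#'
#' @param config An [experiment_config()].
#' @return A `sensor_pipeline` bundle: `config, points, identifications,
#'   bank, areas, web, plan, run, summary, status` (`status` is
#'   `"completed"` or `"halted_dense_web"`). When `config$out_dir` is set,
#'   artifacts (`manifest.json`, `areas.json`, `plan.json`, `run.csv`,
#'   `summary.csv`) are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  params <- config$params
  # Step 1: operating points
  pts <- if (is.null(config$bank_U)) {
    rng <- config$bank_range %||% c(config$from, config$to)
    auto_bank_points(params, rng[1], rng[2], config$a, config$zeta_oa,
                     config$chi_ob)
  } else bank_points(params, sort(config$bank_U))
  # Step 2: identification per operating point
  idents <- NULL
  if (isTRUE(config$identify)) {
    idents <- purrr::imap(pts$U, function(U, i) {
      rec <- identification_experiment(
        params, U, noise_amplitude = config$noise_amplitude,
        horizon = config$ident_horizon, step = config$ident_step,
        seed = config$seed + i)
      rls_identify(rec, U = U, Y = attr(rec, "Y"),
                   window = config$ident_window)
    })
    pts$io <- purrr::map(idents, "io")
    pts$hD <- purrr::map_dbl(idents, function(r) r$io$hD)
    pts$hN <- purrr::map_dbl(idents, function(r) r$io$hN)
  }
  # Step 3: reconstructability gate (raises if any identified model is
  # outside H even after projection)
  purrr::pwalk(list(pts$hD, pts$hN, pts$U, pts$Y), function(hD, hN, U, Y) {
    invisible(reconstruct_parameters(new_io_model(hD, hN), U, Y, params$delta))
  })
  # Step 4: observer bank
  bank <- build_bank(pts, params$delta, config$a, config$zeta_oa)
  # Step 5: target operating areas
  areas <- target_areas(bank, config$chi_oa, config$chi_ob,
                        symmetric = config$symmetric)
  # Step 6: dense-web gate, then transition
  web <- dense_web_check(areas)
  plan <- NULL; run <- NULL; summ <- NULL
  if (!web$pass) {
    status <- "halted_dense_web"
  } else {
    plan <- plan_transition(areas, config$from, config$to,
                            intermediates = config$intermediates,
                            bank = bank, timing_factor = config$timing_factor,
                            step = config$step)
    run <- execute_transition(plan, params, bank, step = config$step)
    summ <- summarize_run(run, bank)
    status <- "completed"
  }
  bundle <- structure(list(config = config, points = pts,
                           identifications = idents, bank = bank,
                           areas = areas, web = web, plan = plan, run = run,
                           summary = summ, status = status),
                      class = "sensor_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(bundle)
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_artifacts <- function(bundle) {
  dir.create(bundle$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- bundle$config$out_dir
  manifest <- list(status = bundle$status, seed = bundle$config$seed,
                   a = bundle$config$a, zeta_oa = bundle$config$zeta_oa,
                   chi_oa = bundle$config$chi_oa, chi_ob = bundle$config$chi_ob,
                   bank_U = bundle$bank$U,
                   params = unclass(bundle$config$params))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_areas(bundle$areas, file.path(od, "areas.json"))
  if (!is.null(bundle$plan)) write_plan(bundle$plan, file.path(od, "plan.json"))
  if (!is.null(bundle$run)) write_run(bundle$run, file.path(od, "run.csv"))
  if (!is.null(bundle$summary)) {
    utils::write.csv(as.data.frame(bundle$summary),
                     file.path(od, "summary.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(od)
}

#' @export
print.sensor_pipeline <- function(x, ...) {
  cat("<sensor_pipeline> status:", x$status, "\n")
  cat("  bank:", nrow(x$bank), "observers over U in [",
      signif(min(x$bank$U), 4), ",", signif(max(x$bank$U), 4), "]\n")
  if (!x$web$pass) {
    cat("  dense web FAILED; gaps:\n"); print(x$web$gaps)
  } else if (!is.null(x$summary)) {
    cat("  transition", attr(x$plan, "from"), "->", attr(x$plan, "to"),
        "in", nrow(x$plan), "stage(s)\n")
  }
  invisible(x)
}

#' Metrics table of a completed (or halted) pipeline
#'
#' Per-stage convergence metric, steady and peak estimation errors and
#' switch times; errors if the bundle holds no executed run.
#'
#' @param bundle A `sensor_pipeline`.
#' @return Tibble (one row per stage).
#' @export
summarize_pipeline <- function(bundle) {
  if (is.null(bundle$run)) {
    ss_abort("pipeline bundle holds no executed transition (halted or not run)",
             "switchsense_pipeline_error")
  }
  summarize_run(bundle$run, bundle$bank)
}
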