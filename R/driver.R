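# End-to-end orchestration: scene -> discretize -> per-step electrical
# rescale -> thermal step -> damage accumulation -> iso-surface
# extraction, plus the validation workflow.

#' Run configuration
#'
#' Bundles and validates everything a simulation run needs besides the
#' power trace.
#'
#' @param scene an \code{rfa_scene}.
#' @param resolution grid spacing, mm.
#' @param dt solver time step, s (the 1 Hz power trace is held by
#'   zero-order hold across sub-steps).
#' @param duration_s simulated duration; default the trace length.
#' @param constants constants list (see \code{\link{default_constants}}).
#' @param damage \code{\link{damage_parameters}}.
#' @param output_every_s optional snapshot cadence (s) for the
#'   temperature field series.
#' @param seed seed recorded in the manifest (the solver chain itself is
#'   deterministic).
#' @return a validated \code{run_config}.
#' @export
run_config <- function(scene, resolution = 1.5, dt = 0.5,
                       duration_s = NULL,
                       constants = default_constants("phantom"),
                       damage = damage_parameters(),
                       output_every_s = NULL, seed = 1L) {
  stopifnot(inherits(scene, "rfa_scene"))
  if (!is.finite(resolution) || resolution <= 0)
    stop("config error: resolution must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("config error: dt must be > 0")
  for (blk in c("electrical", "thermal", "vessel", "damage"))
    if (is.null(constants[[blk]]))
      stop("config error: constants block missing: ", blk)
  structure(list(scene = scene, resolution = resolution, dt = dt,
                 duration_s = duration_s, constants = constants,
                 damage = damage, output_every_s = output_every_s,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Simulate an ablation driven by a recorded power trace
#'
#' The time loop holds the recorded power over each solver step
#' (zero-order hold), rescales the cached unit-potential electrical
#' solution so the domain-integrated dissipated power matches the
#' recorded value exactly, advances the bioheat equation implicitly, and
#' accumulates the Arrhenius damage integral trapezoidally. The
#' electrical system is re-solved only when temperature-dependent
#' conductivity is enabled and the temperature has drifted beyond the
#' configured threshold since the last solve.
#'
#' @param config a \code{\link{run_config}}.
#' @param power a \code{\link{power_trace}} covering the duration.
#' @return an \code{rfa_simulation}: \code{ablation}
#'   (\code{ablation_volume}), \code{damage} (full-grid Omega),
#'   \code{thermal} (final \code{thermal_state}), \code{domain},
#'   \code{series} (per-step data frame: time, recorded and matched
#'   power, impedance), \code{snapshots}, \code{manifest}.
#' @export
simulate_ablation <- function(config, power) {
  stopifnot(inherits(config, "run_config"), inherits(power, "power_trace"))
  t_start <- proc.time()[["elapsed"]]
  duration <- config$duration_s %||% max(power$time_s)
  if (max(power$time_s) < duration - 1e-9)
    stop("power trace does not cover the simulated duration")

  domain <- discretize_scene(config$scene, config$resolution)
  cst <- config$constants
  N <- prod(domain$dims)

  sigma0 <- numeric(N)
  sigma0[domain$material == MATERIALS[["tissue"]]] <- cst$electrical$sigma_tissue
  sigma0[domain$material == MATERIALS[["lumen"]]] <- cst$electrical$sigma_lumen
  sigma0[sigma0 == 0] <- cst$electrical$sigma_tissue

  op_e <- assemble_diffusion_operator(
    domain, sigma0, dirichlet = list(electrode_surface = 1, ground = 0))
  s_cal <- calibrate_electrode_coupling(domain, sigma0)
  op_e <- scale_electrode_coupling(op_e, s_cal)
  V_unit <- solve_potential(domain, sigma0, 1, op = op_e)
  es_unit <- power_density(V_unit)
  if (es_unit$total_power <= 0)
    stop("numerical failure: zero baseline dissipated power")

  tsys <- build_thermal_system(domain, cst)
  state <- init_thermal_state(domain, cst)
  omega <- numeric(N)
  r_prev <- damage_rate(state$temperature, config$damage)
  T_at_solve <- state$temperature
  beta <- cst$electrical$beta_sigma

  nstep <- ceiling(duration / config$dt - 1e-9)
  series <- data.frame(time_s = numeric(nstep), recorded_W = numeric(nstep),
                       matched_W = numeric(nstep),
                       impedance_ohm = numeric(nstep))
  snapshots <- list()
  next_snap <- config$output_every_s %||% Inf

  for (k in seq_len(nstep)) {
    t0 <- (k - 1) * config$dt
    dt_k <- min(config$dt, duration - t0)
    P_k <- resample_power(power, t0)

    if (beta != 0 &&
        max(abs(state$temperature - T_at_solve)) > cst$electrical$resolve_dT) {
      sigT <- sigma0 * (1 + beta * (state$temperature -
                                      cst$thermal$initial_temperature))
      sigT <- pmax(sigT, 1e-3 * cst$electrical$sigma_tissue)
      op_e <- scale_electrode_coupling(assemble_diffusion_operator(
        domain, sigT, dirichlet = list(electrode_surface = 1, ground = 0)),
        s_cal)
      V_unit <- solve_potential(domain, sigT, 1, op = op_e, x0 = V_unit)
      es_unit <- power_density(V_unit)
      T_at_solve <- state$temperature
    }

    es <- scale_to_recorded_power(es_unit, P_k)
    state <- step_temperature(domain, state, es, cst, dt = dt_k,
                              system = tsys)
    r_cur <- damage_rate(state$temperature, config$damage)
    omega <- omega + dt_k * (r_prev + r_cur) / 2
    r_prev <- r_cur

    series$time_s[k] <- t0 + dt_k
    series$recorded_W[k] <- P_k
    series$matched_W[k] <- es$total_power
    series$impedance_ohm[k] <- es$effective_impedance
    if (state$time >= next_snap - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <-
        list(time_s = state$time, temperature = state$temperature)
      next_snap <- next_snap + config$output_every_s
    }
  }

  ablation <- extract_ablation_surface(omega, domain,
                                       config$damage$ablation_threshold)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rfasim")),
    config_fingerprint = fingerprint(list(config$resolution, config$dt,
                                          config$seed, power$power_W)),
    n_nodes = N, n_steps = nstep, resolution_mm = config$resolution,
    dt_s = config$dt, duration_s = duration, seed = config$seed,
    wall_time_s = proc.time()[["elapsed"]] - t_start)
  structure(list(ablation = ablation, damage = omega, thermal = state,
                 domain = domain, series = series, snapshots = snapshots,
                 manifest = manifest, config = config),
            class = "rfa_simulation")
}

#' @export
print.rfa_simulation <- function(x, ...) {
  cat(sprintf(
    "rfa_simulation: %.0f s ablation on %s grid (%.1f mm, dt %.2g s)\n",
    x$manifest$duration_s,
    paste(x$domain$dims, collapse = "x"), x$manifest$resolution_mm,
    x$manifest$dt_s))
  print(x$ablation)
  cat(sprintf("  peak T %.1f degC; wall time %.1f s\n",
              max(x$thermal$temperature), x$manifest$wall_time_s))
  invisible(x)
}

# Cheap deterministic fingerprint of an R object (FNV-style fold over
# the serialized bytes, vectorised).
fingerprint <- function(object) {
  b <- as.integer(serialize(object, NULL, xdr = TRUE))
  w <- (seq_along(b) %% 31) + 1
  sprintf("%08x", sum((b + 1) * w) %% 2147483647L)
}

#' Batch validation with the paired significance test
#'
#' Runs \code{\link{validate_run}} over a series of cases and compares
#' the per-case simulation errors against the chart-model errors with
#' the classical paired two-sided t-test, for mean and for maximum
#' error separately (the per-ablation maximum averaged over cases is
#' the "average max" convention).
#'
#' @param models list of \code{ablation_volume}/\code{tri_mesh} models,
#'   one per case.
#' @param truths list of true-boundary surfaces, one per case.
#' @param chart a \code{chart_model} applied to every case.
#' @param n_points,seed forwarded to \code{\link{validate_run}}.
#' @return list with \code{cases} (per-case report pairs),
#'   \code{summary} (data frame of mean/max errors per case and
#'   method), and \code{paired} (t-tests on mean and max errors).
#' @export
validate_batch <- function(models, truths, chart, n_points = NULL,
                           seed = 1L) {
  stopifnot(length(models) == length(truths), length(models) >= 2L)
  cases <- lapply(seq_along(models), function(i)
    validate_run(models[[i]], truths[[i]], chart = chart,
                 n_points = n_points, seed = seed + i))
  summary <- do.call(rbind, lapply(seq_along(cases), function(i) {
    m <- cases[[i]]$model_report; ch <- cases[[i]]$chart_report
    data.frame(case = i,
               model_mean = m$mean_error, model_max = m$max_error,
               chart_mean = ch$mean_error, chart_max = ch$max_error)
  }))
  list(cases = cases, summary = summary,
       paired = list(
         mean_error = paired_comparison(summary$model_mean,
                                        summary$chart_mean),
         max_error = paired_comparison(summary$model_max,
                                       summary$chart_max)))
}

#' Validate a simulated ablation against a true boundary
#'
#' Samples evenly distributed points on the true boundary and reports
#' their distances to the model surface (and, when given, to the
#' manufacturer-chart surface) in the direction true-to-model.
#' 3D truths (masks segmented to meshes) use the ~10,000-point protocol;
#' 2D section contours use the 64-point protocol.
#'
#' @param model an \code{ablation_volume}, \code{tri_mesh}, or (2D) a
#'   closed contour matrix.
#' @param truth a \code{tri_mesh} (3D) or closed 2D contour matrix.
#' @param chart optional \code{chart_model} for the paired comparison.
#' @param n_points points to sample on the truth (default 10000 for 3D,
#'   64 for 2D).
#' @param seed sampling seed.
#' @return list with \code{model_report}, optional \code{chart_report}
#'   (both \code{error_report}), and \code{true_points}.
#' @export
validate_run <- function(model, truth, chart = NULL, n_points = NULL,
                         seed = 1L) {
  if (inherits(model, "ablation_volume")) {
    if (model$empty) stop("model ablation volume is empty")
    model <- model$mesh
  }
  is3d <- inherits(truth, "tri_mesh")
  n_points <- n_points %||% if (is3d) 10000L else 64L
  pts <- sample_equidistant(truth, n_points, seed = seed)
  out <- list(model_report = surface_error(pts, model),
              true_points = pts)
  if (!is.null(chart))
    out$chart_report <- surface_error(pts, chart)
  out
}
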