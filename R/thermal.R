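# Pennes bioheat time march. Backward-Euler (unconditionally stable)
# finite-difference update in time on the shared structured grid:
#
#   rho c dT/dt = div(k grad T) + q - w_b rho_b c_b (T - T_art)
#
# with convective Robin boundaries on vessel walls (heat sink), insulated
# exterior faces, and an enthalpy-band treatment of evaporation: inside
# the band the effective volumetric heat capacity is augmented by the
# latent heat of the tissue water spread over the band, which produces
# the observed plateau near 100 degC; a ceiling clamp above the band
# guards against residual overshoot.

#' Initialise a thermal state
#'
#' @param domain an \code{rfa_domain}.
#' @param constants constants list (see \code{\link{default_constants}}).
#' @return A \code{thermal_state}: full-grid \code{temperature} (degC),
#'   \code{time} (s), and the cumulative energy ledger
#'   \code{energy_in}, \code{energy_out}, \code{energy_stored} (J).
#' @export
init_thermal_state <- function(domain, constants = default_constants()) {
  structure(list(temperature = rep(constants$thermal$initial_temperature,
                                   prod(domain$dims)),
                 time = 0, energy_in = 0, energy_out = 0,
                 energy_stored = 0),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf("thermal_state at t = %.1f s: T in [%.1f, %.1f] degC\n",
              x$time, min(x$temperature), max(x$temperature)))
  cat(sprintf("  energy ledger (kJ): in %.2f, out %.2f, stored %.2f\n",
              x$energy_in / 1e3, x$energy_out / 1e3, x$energy_stored / 1e3))
  invisible(x)
}

#' Vessel heat-sink boundary contribution
#'
#' Convective Robin boundary on the vessel wall: each tissue cell face
#' touching the lumen exchanges \code{h A (T - T_fluid)} watts, with
#' \code{h} from the laminar Nusselt correlation
#' (\code{\link{vessel_heat_transfer}}). With zero flow the contribution
#' is empty and the lumen participates as a stationary conductive fluid.
#'
#' @param domain an \code{rfa_domain}.
#' @param vessel a \code{\link{vessel_spec}}.
#' @param constants constants list.
#' @return list with \code{idx} (wall tissue nodes), \code{coeff}
#'   (\code{h A n_faces}, W/K per node), \code{T_fluid} (degC), and the
#'   correlation diagnostics \code{h}, \code{reynolds}, \code{nusselt}.
#' @export
apply_vessel_heat_sink <- function(domain, vessel,
                                   constants = default_constants()) {
  ht <- vessel_heat_transfer(vessel, constants)
  if (ht$h == 0)
    return(list(idx = integer(0), coeff = numeric(0),
                T_fluid = vessel$fluid_temperature,
                h = 0, reynolds = ht$reynolds, nusselt = ht$nusselt))
  d <- domain$dims
  N <- prod(d)
  tis <- domain$material == MATERIALS[["tissue"]]
  lum <- domain$material == MATERIALS[["lumen"]]
  counts <- integer(N)
  strides <- c(1L, d[1], d[1] * d[2])
  sizes <- d
  i0 <- seq_len(N) - 1L
  for (ax in 1:3) {
    p <- switch(ax, (i0 %% d[1]), ((i0 %/% d[1]) %% d[2]),
                (i0 %/% (d[1] * d[2]))) + 1L
    L <- which(p < sizes[ax])
    U <- L + strides[ax]
    sel <- tis[L] & lum[U]
    counts[L[sel]] <- counts[L[sel]] + 1L
    sel <- tis[U] & lum[L]
    counts[U[sel]] <- counts[U[sel]] + 1L
  }
  idx <- which(counts > 0L)
  A_face <- (domain$spacing * 1e-3)^2
  list(idx = idx, coeff = ht$h * A_face * counts[idx],
       T_fluid = vessel$fluid_temperature,
       h = ht$h, reynolds = ht$reynolds, nusselt = ht$nusselt)
}

#' Effective volumetric heat capacity with evaporation
#'
#' Enthalpy-band model: within the evaporation band the effective
#' volumetric heat capacity is \code{rho c + rho w L / (band width)}, so
#' traversing the band absorbs the full latent heat of the tissue water.
#' Outside the band the sensible capacity applies. (The time stepper
#' uses the secant capacity derived from the enthalpy function so that
#' band crossings within one step still pay the full latent toll; this
#' function gives the pointwise slope.)
#'
#' @param temperature full-grid temperature (degC).
#' @param domain an \code{rfa_domain}.
#' @param constants constants list.
#' @param evaporation logical; disable to get the pure sensible capacity.
#' @return full-grid volumetric heat capacity, J/(m^3 K).
#' @export
apply_evaporation <- function(temperature, domain,
                              constants = default_constants(),
                              evaporation = constants$thermal$evaporation) {
  th <- constants$thermal
  mat <- domain$material
  ceff <- numeric(length(mat))
  tis <- mat %in% MATERIALS[c("tissue")]
  lum <- mat == MATERIALS[["lumen"]]
  met <- mat %in% MATERIALS[c("electrode", "shaft")]
  ceff[tis] <- th$rho * th$c
  ceff[lum] <- 1000 * 4180          # stationary water column
  ceff[met] <- th$rho_metal * th$c_metal
  if (evaporation) {
    band <- th$evaporation_band
    inband <- tis & temperature >= band[1] & temperature < band[2]
    ceff[inband] <- ceff[inband] +
      th$rho * th$water_fraction * th$latent_heat / (band[2] - band[1])
  }
  ceff
}

# Volumetric enthalpy (J/m^3, relative to 0 degC): sensible part plus
# the latent ramp across the evaporation band. The integral of the
# effective capacity in apply_evaporation.
enthalpy_volumetric <- function(temperature, domain,
                                constants = default_constants(),
                                evaporation = constants$thermal$evaporation) {
  th <- constants$thermal
  mat <- domain$material
  cvol <- numeric(length(mat))
  tis <- mat == MATERIALS[["tissue"]]
  cvol[tis] <- th$rho * th$c
  cvol[mat == MATERIALS[["lumen"]]] <- 1000 * 4180
  cvol[mat %in% MATERIALS[c("electrode", "shaft")]] <-
    th$rho_metal * th$c_metal
  H <- cvol * temperature
  if (evaporation) {
    band <- th$evaporation_band
    frac <- pmin(pmax((temperature - band[1]) / (band[2] - band[1]), 0), 1)
    H[tis] <- H[tis] +
      (th$rho * th$water_fraction * th$latent_heat * frac)[tis]
  }
  H
}

# Exact inverse of the piecewise-linear volumetric enthalpy.
invert_enthalpy <- function(H, domain, constants = default_constants(),
                            evaporation = constants$thermal$evaporation) {
  th <- constants$thermal
  mat <- domain$material
  cvol <- numeric(length(mat))
  tis <- mat == MATERIALS[["tissue"]]
  cvol[tis] <- th$rho * th$c
  cvol[mat == MATERIALS[["lumen"]]] <- 1000 * 4180
  cvol[mat %in% MATERIALS[c("electrode", "shaft")]] <-
    th$rho_metal * th$c_metal
  cvol[cvol == 0] <- th$rho * th$c    # inactive filler, never used
  T_out <- H / cvol
  if (evaporation) {
    band <- th$evaporation_band
    Lv <- th$rho * th$water_fraction * th$latent_heat
    cb <- th$rho * th$c + Lv / (band[2] - band[1])
    H1 <- th$rho * th$c * band[1]
    H2 <- th$rho * th$c * band[2] + Lv
    inb <- tis & H > H1 & H <= H2
    T_out[inb] <- band[1] + (H[inb] - H1) / cb
    abv <- tis & H > H2
    T_out[abv] <- (H[abv] - Lv) / (th$rho * th$c)
  }
  T_out
}

# Conduction couplings + masks for the thermal march, built once per run.
build_thermal_system <- function(domain, constants = default_constants()) {
  th <- constants$thermal
  mat <- domain$material
  N <- length(mat)
  flows <- vapply(domain$scene$vessels, function(v) v$flow_speed, numeric(1))
  flowing <- length(flows) > 0 && any(flows > 0)

  unknown <- mat %in% MATERIALS[c("tissue", "electrode", "shaft")]
  if (!flowing) unknown <- unknown | mat == MATERIALS[["lumen"]]

  k <- numeric(N)
  k[mat == MATERIALS[["tissue"]]] <- th$k
  k[mat == MATERIALS[["lumen"]]] <- 0.6
  k[mat %in% MATERIALS[c("electrode", "shaft")]] <- th$k_metal
  k[k == 0] <- th$k  # inert filler for inactive cells (never used)

  op <- assemble_diffusion_operator(domain, k, unknown = unknown)

  robin <- list(idx = integer(0), coeff = numeric(0), T_fluid = NA_real_)
  if (flowing) {
    v <- domain$scene$vessels[[which(flows > 0)[1]]]
    robin <- apply_vessel_heat_sink(domain, v, constants)
  }
  perf <- numeric(N)
  if (th$perfusion_rate > 0) {
    vol <- (domain$spacing * 1e-3)^3
    perf[mat == MATERIALS[["tissue"]]] <-
      th$perfusion_rate * th$rho_blood * th$c_blood * vol
  }
  list(op = op, unknown = unknown, robin = robin, perfusion_WK = perf,
       vol = (domain$spacing * 1e-3)^3, constants = constants)
}

#' Advance tissue temperature by one implicit step
#'
#' Backward-Euler update of the Pennes bioheat balance with the current
#' dissipated power density as source. The effective heat capacity is
#' evaluated with a lagged Picard iteration so the evaporation band is
#' honoured; after the solve the ceiling clamp (band top +
#' \code{clamp_offset}) is applied and any clamped energy is booked as
#' vented output. The energy ledger (input, output, stored) is updated
#' with the discrete fluxes so closed systems balance to solver
#' tolerance.
#'
#' @param domain an \code{rfa_domain}.
#' @param state a \code{thermal_state}.
#' @param power an \code{electrical_state}, or a full-grid power vector
#'   in W per cell, or W/m^3 (see \code{power_unit}).
#' @param constants constants list.
#' @param dt time step in seconds.
#' @param system cached result of the internal system builder; pass the
#'   value returned in \code{attr(state, "system")} between steps (the
#'   driver does this automatically).
#' @param power_unit \code{"W"} or \code{"W/m^3"} when \code{power} is a
#'   bare vector.
#' @return the advanced \code{thermal_state} (with the cached system in
#'   \code{attr(, "system")}).
#' @export
step_temperature <- function(domain, state, power, constants = default_constants(),
                             dt = 0.5, system = NULL, power_unit = "W") {
  stopifnot(dt > 0)
  if (is.null(system)) system <- attr(state, "system")
  if (is.null(system)) system <- build_thermal_system(domain, constants)
  th <- constants$thermal
  N <- prod(domain$dims)

  q <- if (inherits(power, "electrical_state")) power$power_W
  else if (power_unit == "W") as.numeric(power)
  else as.numeric(power) * system$vol
  if (length(q) != N) stop("power field does not match the domain")
  q[!system$unknown] <- 0

  op <- system$op
  T_old <- state$temperature
  perf <- system$perfusion_WK
  robin_diag <- numeric(N)
  robin_rhs <- numeric(N)
  if (length(system$robin$idx)) {
    robin_diag[system$robin$idx] <- system$robin$coeff
    robin_rhs[system$robin$idx] <- system$robin$coeff * system$robin$T_fluid
  }
  T_art <- th$arterial_temperature

  # Enthalpy-corrected Picard iteration (Voller-style): solve the linear
  # step with the current apparent capacity, convert each node's
  # actually-delivered energy into a temperature through the exact
  # piecewise-linear enthalpy inverse, and re-derive the secant capacity
  # at that consistent point. Away from the evaporation band the first
  # correction is a no-op; for uniform heating across the band the
  # scheme is exact after one correction, and the kink cannot induce the
  # 2-cycles a pointwise lagged capacity suffers from.
  H_old <- enthalpy_volumetric(T_old, domain, constants)
  shifts <- vapply(op$links, `[[`, numeric(1), "shift")
  coups <- lapply(op$links, `[[`, "c")
  ceff_pt <- apply_evaporation(T_old, domain, constants)
  ceff <- ceff_pt
  T_new <- T_old
  for (iter in 1:8) {
    cap <- system$vol * ceff / dt      # W/K
    cap[!system$unknown] <- 0
    dg <- op$diag + cap + perf + robin_diag
    rhs <- cap * T_old + q + perf * T_art + robin_rhs
    rhs[!system$unknown] <- 0
    dg[!system$unknown] <- 0
    res <- .stencil_pcg(shifts, coups, dg, rhs, T_new, 1e-9, 500L)
    T_new <- res$x
    T_new[!system$unknown] <- T_old[!system$unknown]
    # energy actually delivered to each node under the discrete balance
    H_target <- H_old + cap * (T_new - T_old) * dt / system$vol
    T_corr <- invert_enthalpy(H_target, domain, constants)
    T_corr[!system$unknown] <- T_old[!system$unknown]
    if (max(abs(T_corr - T_new)) < 1e-3) break
    dT <- T_corr - T_old
    ceff <- ifelse(abs(dT) > 1e-9, (H_target - H_old) / dT, ceff_pt)
  }

  act <- system$unknown
  e_in <- sum(q) * dt
  e_perf <- sum(perf[act] * (T_new[act] - T_art)) * dt
  e_robin <- if (length(system$robin$idx))
    sum(robin_diag[act] * (T_new[act] - system$robin$T_fluid[1])) * dt else 0
  e_stored <- sum(cap[act] * (T_new[act] - T_old[act])) * dt

  # ceiling clamp above the evaporation band
  clamp <- th$evaporation_band[2] + th$clamp_offset
  over <- act & T_new > clamp
  e_vent <- 0
  if (any(over)) {
    e_vent <- sum(cap[over] * (T_new[over] - clamp)) * dt
    e_stored <- e_stored - e_vent
    T_new[over] <- clamp
  }

  state$temperature <- T_new
  state$time <- state$time + dt
  state$energy_in <- state$energy_in + e_in
  state$energy_out <- state$energy_out + e_perf + e_robin + e_vent
  state$energy_stored <- state$energy_stored + e_stored
  attr(state, "system") <- system
  state
}
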