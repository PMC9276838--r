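#' Default physical constants
#'
#' All tissue, phantom, electrical, vessel and damage constants live here,
#' each with a provenance note in the source. Two presets are provided:
#' \code{"phantom"} (agar-albumin beaker at room temperature, no
#' perfusion) and \code{"liver"} (in-vivo hepatic tissue at body
#' temperature with Pennes perfusion).
#'
#' Units are SI throughout (geometry elsewhere in the package is mm, and
#' is converted at assembly time).
#'
#' @param preset \code{"phantom"} or \code{"liver"}.
#' @return A nested list with blocks \code{electrical}, \code{thermal},
#'   \code{vessel} and \code{damage}.
#' @export
default_constants <- function(preset = c("phantom", "liver")) {
  preset <- match.arg(preset)
  liver <- preset == "liver"
  list(
    preset = preset,
    electrical = list(
      # tissue/agar conductivity at RF frequencies; the agar recipe is
      # tuned to liver-like conductivity (Stogryn-type saline values,
      # common RFA modelling figure)
      sigma_tissue = 0.333,     # S/m
      sigma_lumen = 0.333,      # S/m, water/blood column in the channel
      beta_sigma = 0,           # 1/K, optional linear sigma(T); 0 = off
      resolve_dT = 5            # degC drift triggering an electrical re-solve
    ),
    thermal = list(
      # agar ~ water; liver values from standard RFA modelling literature
      # (Tungjitkusolmun et al. 2002 lineage)
      rho = if (liver) 1060 else 1000,        # kg/m^3
      c = if (liver) 3600 else 4180,          # J/(kg K)
      k = if (liver) 0.512 else 0.60,         # W/(m K)
      rho_metal = 6450, c_metal = 840, k_metal = 18,  # NiTi tines/shaft
      rho_blood = 1060,                       # kg/m^3
      c_blood = 3617,                         # J/(kg K)
      perfusion_rate = if (liver) 6.4e-3 else 0,  # 1/s volumetric
      arterial_temperature = if (liver) 37 else 20,  # degC
      initial_temperature = if (liver) 37 else 20,   # degC
      latent_heat = 2.26e6,                   # J/kg water
      water_fraction = if (liver) 0.70 else 0.95,
      evaporation_band = c(99, 101),          # degC enthalpy band
      clamp_offset = 5,                       # ceiling = band top + offset
      evaporation = TRUE
    ),
    vessel = list(
      k_fluid = 0.60,       # W/(m K), water/blood
      nu_fluid = 1.0e-6,    # m^2/s kinematic viscosity
      nusselt_laminar = 3.66  # constant-wall-temperature laminar Nusselt
    ),
    damage = list(
      # Arrhenius coefficients for hepatic thermal injury (Chang-type
      # whole-liver fit); the albumin phantom is read with the same
      # kinetics unless overridden
      frequency_factor = 7.39e39,   # 1/s
      activation_energy = 2.577e5,  # J/mol
      gas_constant = 8.314,         # J/(mol K)
      ablation_threshold = 1.0      # Omega* ~ 63% cell kill (4.6 ~ 99%)
    )
  )
}

#' Convective heat-transfer coefficient of a vessel
#'
#' Laminar internal-flow correlation: Reynolds number \code{v d / nu}; in
#' the laminar regime (Re < 2300) the constant-wall-temperature Nusselt
#' number 3.66 applies, giving \code{h = Nu k_f / d}. Faster flows use
#' the Dittus-Boelter correlation. Zero flow returns \code{h = 0} (the
#' lumen then participates as a stationary conductive fluid column).
#'
#' @param vessel a \code{\link{vessel_spec}}.
#' @param constants constants list (block \code{vessel}).
#' @return list with \code{h} (W/m^2/K), \code{reynolds}, \code{nusselt}.
#' @export
vessel_heat_transfer <- function(vessel, constants = default_constants()) {
  vc <- constants$vessel
  d_m <- vessel$diameter * 1e-3
  v_m <- vessel$flow_speed * 1e-3
  re <- v_m * d_m / vc$nu_fluid
  if (v_m == 0) return(list(h = 0, reynolds = 0, nusselt = 0))
  nu <- if (re < 2300) vc$nusselt_laminar else {
    pr <- 7  # water near room temperature
    0.023 * re^0.8 * pr^0.4
  }
  list(h = nu * vc$k_fluid / d_m, reynolds = re, nusselt = nu)
}
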