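# Arrhenius thermal damage. Cell death is modelled as a first-order rate
# process: the damage integral
#   Omega(x) = integral of A exp(-Ea / (R T(x,t))) dt   (T in kelvin)
# accumulates over the temperature history; Omega = 1 corresponds to
# ~63% cell kill and is the conventional ablation boundary.

#' Arrhenius damage parameters
#'
#' @param frequency_factor Arrhenius pre-exponential A, 1/s.
#' @param activation_energy activation energy Ea, J/mol.
#' @param ablation_threshold Omega value defining the ablation boundary.
#' @return a \code{damage_parameters} object (gas constant fixed at
#'   8.314 J/(mol K)).
#' @export
damage_parameters <- function(frequency_factor = 7.39e39,
                              activation_energy = 2.577e5,
                              ablation_threshold = 1.0) {
  stopifnot(frequency_factor > 0, activation_energy > 0,
            ablation_threshold > 0)
  structure(list(frequency_factor = frequency_factor,
                 activation_energy = activation_energy,
                 gas_constant = 8.314,
                 ablation_threshold = ablation_threshold),
            class = "damage_parameters")
}

#' Arrhenius damage rate
#'
#' \code{A exp(-Ea / (R T_K))} evaluated at temperatures in degrees C
#' (kelvin conversion is centralised here).
#' @param temperature_C temperatures in degrees C.
#' @param params a \code{\link{damage_parameters}}.
#' @return damage rate, 1/s.
#' @export
damage_rate <- function(temperature_C, params = damage_parameters()) {
  T_K <- temperature_C + 273.15
  params$frequency_factor *
    exp(-params$activation_energy / (params$gas_constant * T_K))
}

#' Integrate the Arrhenius damage field from a temperature history
#'
#' Trapezoidal time integration of the damage rate over an ordered
#' temperature history.
#'
#' @param temperature_history list of full-grid temperature fields
#'   (degC), time-ordered, or a matrix with one column per time point.
#' @param params a \code{\link{damage_parameters}}.
#' @param dt time spacing in seconds (uniform), or a vector of times of
#'   length equal to the history.
#' @return full-grid damage field Omega (dimensionless).
#' @export
integrate_damage <- function(temperature_history, params = damage_parameters(),
                             dt = 1) {
  if (is.list(temperature_history))
    temperature_history <- do.call(cbind, temperature_history)
  temperature_history <- as.matrix(temperature_history)
  nt <- ncol(temperature_history)
  if (nt == 0L) stop("empty temperature history")
  times <- if (length(dt) == 1L) (seq_len(nt) - 1L) * dt else dt
  if (length(times) != nt) stop("time vector does not match the history")
  omega <- numeric(nrow(temperature_history))
  if (nt == 1L) return(omega)
  r_prev <- damage_rate(temperature_history[, 1L], params)
  for (j in 2:nt) {
    r_cur <- damage_rate(temperature_history[, j], params)
    omega <- omega + (times[j] - times[j - 1L]) * (r_prev + r_cur) / 2
    r_prev <- r_cur
  }
  omega
}

#' Extract the ablation iso-surface from a damage field
#'
#' Marching-tetrahedra extraction of the closed surface Omega =
#' threshold, with the enclosed volume computed by the divergence
#' theorem. An everywhere-sub-threshold field yields an empty volume
#' (flagged, not an error).
#'
#' @param damage_field full-grid damage values (or any scalar field).
#' @param domain the \code{rfa_domain} the field lives on.
#' @param threshold iso-level (default the conventional Omega = 1).
#' @return an \code{ablation_volume}: \code{mesh} (\code{tri_mesh}, mm),
#'   \code{volume} (mm^3), \code{threshold}, \code{empty} flag.
#' @export
extract_ablation_surface <- function(damage_field, domain, threshold = 1) {
  stopifnot(threshold > 0)
  f <- as.numeric(damage_field)
  # restrict to active cells; outside cells must never carry the level
  f[domain$material == 0L] <- 0
  mesh <- marching_tets(f, domain$dims, domain$origin, domain$spacing,
                        threshold)
  vol <- mesh_volume(mesh)
  structure(list(mesh = mesh, volume = vol, threshold = threshold,
                 empty = nrow(mesh$triangles) == 0L,
                 damage_field = damage_field),
            class = "ablation_volume")
}

#' Triangulate a labelled 3D mask into a closed surface
#'
#' Turns a binary/labelled volume (e.g. a manually segmented "true"
#' ablation mask) into the closed triangulated surface of the labelled
#' region, via marching tetrahedra at the half-level.
#'
#' @param mask a \code{ct_volume} (fields \code{volume}, \code{spacing},
#'   \code{origin}) or a 3D array (then \code{spacing}/\code{origin}
#'   apply).
#' @param level iso-level separating background from the labelled
#'   region.
#' @param spacing,origin geometry when \code{mask} is a bare array.
#' @return a \code{tri_mesh} in mm.
#' @export
mask_to_surface <- function(mask, level = 0.5, spacing = 1,
                            origin = c(0, 0, 0)) {
  if (inherits(mask, "ct_volume")) {
    spacing <- mask$spacing
    origin <- mask$origin
    mask <- mask$volume
  }
  mesh <- marching_tets(as.numeric(mask), dim(mask), origin, spacing,
                        level)
  if (nrow(mesh$triangles) == 0L)
    stop("mask has no region above the level")
  mesh
}

#' @export
print.ablation_volume <- function(x, ...) {
  if (x$empty) cat("ablation_volume: empty (no super-threshold region)\n")
  else cat(sprintf(
    "ablation_volume: %.2f cm^3 at Omega = %g (%d triangles)\n",
    x$volume / 1e3, x$threshold, nrow(x$mesh$triangles)))
  invisible(x)
}
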