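#' Build an idealised umbrella (LeVeen-style) electrode
#'
#' Constructs the parametric geometry of a multi-tine expandable umbrella
#' electrode in the electrode frame: tip at the origin, shaft along
#' \code{-z} (the handle side), tines opening towards \code{+z}. Each tine
#' is a circular arc in a plane through the shaft axis, starting at the tip
#' tangent to the radial direction and curving forward; tines are equally
#' spaced in azimuth. At full deployment the maximum radial extent of the
#' tines equals \code{nominal_diameter / 2}; partial deployment truncates
#' the arcs so the radial extent scales with \code{deployed_fraction}.
#'
#' The true vendor tine curve is proprietary; the circular-arc family
#' reproduces the umbrella appearance and the nominal-diameter constraint,
#' which is what the downstream physics needs.
#'
#' @param nominal_diameter nominal device diameter in mm (20--40 family).
#' @param n_tines number of tines (>= 4).
#' @param deployed_fraction deployment in (0, 1]; 1 = fully deployed.
#' @param points_per_tine polyline sampling density per tine.
#' @return An \code{electrode_spec}: fields \code{nominal_diameter},
#'   \code{n_tines}, \code{shaft_axis} (unit vector, handle direction),
#'   \code{tip_position}, \code{tine_paths} (list of k x 3 matrices, mm,
#'   each starting at the tip), \code{deployed_fraction}.
#' @examples
#' el <- build_leveen_electrode(30, 10)
#' max(sqrt(sapply(el$tine_paths, function(p) max(p[, 1]^2 + p[, 2]^2))))
#' @export
build_leveen_electrode <- function(nominal_diameter, n_tines,
                                   deployed_fraction = 1,
                                   points_per_tine = 25L) {
  if (!is.finite(nominal_diameter) || nominal_diameter < 20 ||
      nominal_diameter > 40)
    stop("nominal_diameter must be in [20, 40] mm")
  if (n_tines < 4L) stop("n_tines must be >= 4")
  if (!is.finite(deployed_fraction) || deployed_fraction <= 0 ||
      deployed_fraction > 1)
    stop("deployed_fraction must be in (0, 1]")

  rho <- nominal_diameter / 2           # arc radius, mm
  t_max <- asin(deployed_fraction)      # arc angle so max radius = f * D/2
  tt <- seq(0, t_max, length.out = points_per_tine)
  phi <- 2 * pi * (seq_len(n_tines) - 1L) / n_tines
  tine_paths <- lapply(phi, function(a) {
    r <- rho * sin(tt)
    z <- rho * (1 - cos(tt))
    cbind(r * cos(a), r * sin(a), z)
  })
  structure(list(nominal_diameter = nominal_diameter,
                 n_tines = as.integer(n_tines),
                 shaft_axis = c(0, 0, -1),
                 tip_position = c(0, 0, 0),
                 tine_paths = tine_paths,
                 deployed_fraction = deployed_fraction),
            class = "electrode_spec")
}

#' @export
print.electrode_spec <- function(x, ...) {
  cat(sprintf("electrode_spec: %g mm umbrella, %d tines, %.0f%% deployed\n",
              x$nominal_diameter, x$n_tines, 100 * x$deployed_fraction))
  cat(sprintf("  tip at (%s) mm, shaft axis (%s)\n",
              paste(format(x$tip_position, digits = 4), collapse = ", "),
              paste(format(x$shaft_axis, digits = 4), collapse = ", ")))
  invisible(x)
}

#' Maximum radial tine extent of an electrode
#'
#' Radial distance (mm) of tine points from the shaft axis, maximised over
#' all tine polyline vertices.
#' @param electrode an \code{electrode_spec}.
#' @return maximum radial extent in mm.
#' @export
electrode_radial_extent <- function(electrode) {
  axis <- electrode$shaft_axis / sqrt(sum(electrode$shaft_axis^2))
  tip <- electrode$tip_position
  max(vapply(electrode$tine_paths, function(p) {
    rel <- sweep(p, 2L, tip)
    ax <- rel %*% axis
    max(sqrt(pmax(rowSums(rel^2) - ax^2, 0)))
  }, numeric(1)))
}

#' Rigidly transform an electrode
#'
#' @param electrode an \code{electrode_spec}.
#' @param transform a \code{\link{rigid_transform}}.
#' @return the transformed \code{electrode_spec}.
#' @export
transform_electrode <- function(electrode, transform) {
  electrode$tip_position <- apply_rigid(transform, electrode$tip_position)
  electrode$shaft_axis <-
    as.numeric(transform$rotation %*% electrode$shaft_axis)
  electrode$tine_paths <-
    lapply(electrode$tine_paths, function(p) apply_rigid(transform, p))
  electrode
}

# Resample one polyline to n points equally spaced in arc length.
resample_polyline <- function(path, n) {
  path <- as.matrix(path)
  seg <- sqrt(rowSums((path[-1L, , drop = FALSE] -
                       path[-nrow(path), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(path[rep(1L, n), , drop = FALSE])
  tgt <- seq(0, s[length(s)], length.out = n)
  apply(path, 2L, function(col) approx(s, col, xout = tgt)$y)
}

#' Rigid pose from a measured electrode
#'
#' Least-squares (Kabsch) rigid transform mapping an ideal electrode's
#' frame onto a measured one, using the tip plus arc-length-resampled tine
#' points as corresponding landmarks. Both electrodes must have the same
#' tine count and ordering.
#'
#' @param measured,ideal \code{electrode_spec} objects with matching tine
#'   counts and ordering.
#' @param points_per_tine correspondence points sampled per tine.
#' @return A \code{\link{rigid_transform}} mapping ideal to measured
#'   coordinates, with attribute \code{rms_residual} (mm).
#' @export
pose_from_electrode <- function(measured, ideal, points_per_tine = 10L) {
  if (measured$n_tines != ideal$n_tines)
    stop("tine counts differ between measured and ideal electrodes")
  pts <- function(el) {
    do.call(rbind, c(list(matrix(el$tip_position, 1L)),
                     lapply(el$tine_paths, resample_polyline,
                            n = points_per_tine)))
  }
  fit_rigid(pts(ideal), pts(measured))
}

#' @importFrom stats approx
NULL
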