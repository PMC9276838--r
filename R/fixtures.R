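# Synthetic fixtures with known ground truth. These generate every input
# the pipeline consumes: analytic-solution scenes for solver validation,
# beaker-phantom scenes mirroring the bench experiments, plateaued
# generator power traces, noisy slice images of known boundaries, and
# CT-like volumes with painted tine curves. All randomness is seeded and
# reproducible (same recipe + seed = identical output).

#' Analytic-solution scenes
#'
#' Builds a scene together with a closed-form ground-truth handle for
#' solver acceptance tests.
#'
#' \describe{
#' \item{\code{concentric_spheres}}{inner sphere of radius \code{a} mm
#'   energized, outer sphere of radius \code{b} mm grounded, uniform
#'   conductivity \code{sigma}. Truth: the shell potential
#'   \code{V(r) = V0 a (b - r) / (r (b - a))}, the shell resistance
#'   \code{(1/a - 1/b) / (4 pi sigma)} and the spreading resistance
#'   \code{1 / (4 pi sigma a)}.}
#' \item{\code{perfused_box}}{insulated tissue box under uniform
#'   volumetric heating with perfusion. Truth: the scalar relaxation
#'   \code{T(t) = T_art + q/P (1 - exp(-t/tau)) + (T0 - T_art) exp(-t/tau)}
#'   with \code{P = w rho_b c_b} and \code{tau = rho c / P}.}
#' }
#'
#' @param kind \code{"concentric_spheres"} or \code{"perfused_box"}.
#' @param params named list of overrides (see details above; defaults
#'   \code{a = 1}, \code{b = 60} mm, \code{sigma = 0.333} S/m;
#'   \code{side = 20} mm).
#' @return list with \code{scene} and \code{truth} (list of closed-form
#'   functions and values).
#' @export
make_analytic_scene <- function(kind, params = list()) {
  if (kind == "concentric_spheres") {
    a <- params$a %||% 1
    b <- params$b %||% 60
    sigma <- params$sigma %||% 0.333
    scene <- new_scene(
      electrode = NULL,
      electrode_surface = list(type = "sphere", center = c(0, 0, 0),
                               radius = a),
      medium = list(type = "ball", center = c(0, 0, 0), radius = b),
      ground = list(type = "sphere", radius = b),
      initial_temperature = 20)
    truth <- list(
      potential = function(r, V0 = 1) V0 * a * (b - r) / (r * (b - a)),
      resistance = (1 / a - 1 / b) / (4 * pi * sigma) * 1e3,  # Ohm (mm -> m)
      spreading_resistance = 1e3 / (4 * pi * sigma * a),
      sigma = sigma, a = a, b = b)
    return(list(scene = scene, truth = truth))
  }
  if (kind == "perfused_box") {
    side <- params$side %||% 20
    scene <- new_scene(
      electrode = NULL, electrode_surface = NULL,
      medium = list(type = "box", lo = c(0, 0, 0),
                    hi = c(side, side, side)),
      ground = list(type = "none"),
      initial_temperature = params$T0 %||% 37)
    truth <- list(
      relaxation = function(t, q_vol, constants) {
        th <- constants$thermal
        P <- th$perfusion_rate * th$rho_blood * th$c_blood
        tau <- th$rho * th$c / P
        T0 <- scene$initial_temperature
        th$arterial_temperature + q_vol / P * (1 - exp(-t / tau)) +
          (T0 - th$arterial_temperature) * exp(-t / tau)
      },
      tau = function(constants) {
        th <- constants$thermal
        th$rho * th$c /
          (th$perfusion_rate * th$rho_blood * th$c_blood)
      })
    return(list(scene = scene, truth = truth))
  }
  stop("unknown analytic scene kind: ", kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic generator power trace
#'
#' Emulates the shape of a recorded RF generator log: a ramp from the
#' starting power to the plateau, the plateau held for the rest of a
#' 5-minute ablation, small seeded measurement jitter, and an optional
#' impedance roll-off dip near the end. Sampled at 1 Hz like the serial
#' logs the simulation consumes.
#'
#' @param duration_s total duration in seconds.
#' @param start_power,plateau_power watts.
#' @param ramp_s ramp duration in seconds.
#' @param noise_sd jitter standard deviation in watts.
#' @param rolloff if \code{TRUE}, power drops to 10% of plateau for the
#'   last 20 s (post roll-off behaviour).
#' @param seed RNG seed.
#' @return a \code{\link{power_trace}} (with synthesized impedance).
#' @export
make_power_trace <- function(duration_s = 300, start_power = 20,
                             plateau_power = 80, ramp_s = 60,
                             noise_sd = 0.5, rolloff = FALSE, seed = 1L) {
  t <- 0:duration_s
  base <- start_power + (plateau_power - start_power) * pmin(t / ramp_s, 1)
  if (rolloff) base[t > duration_s - 20] <- 0.1 * plateau_power
  with_seed(seed, {
    p <- pmax(base + rnorm(length(t), 0, noise_sd), 0)
    z <- 75 - 15 * pmin(t / ramp_s, 1) + rnorm(length(t), 0, 0.5)
    power_trace(t, p, z)
  })
}

#' Beaker-phantom fixture
#'
#' Scene and driving power trace mirroring the bench protocol: 2 L
#' beaker, bottom return pad, 4 cm umbrella electrode inserted from the
#' top, optional vertical 5 mm water channel at a given offset from the
#' shaft with 10.5 cm/s flow, and a seeded ramp-plateau power trace.
#'
#' @param vessel_offset \code{NULL}, or the shaft-to-centerline offset in
#'   mm (the bench series used 25, 30 and 35 mm).
#' @param seed RNG seed for the power trace.
#' @param electrode_diameter electrode nominal diameter, mm.
#' @param duration_s ablation duration, s.
#' @param plateau_power plateau power, W.
#' @return list with \code{scene}, \code{trace}, \code{phantom},
#'   \code{electrode}.
#' @export
make_phantom_fixture <- function(vessel_offset = NULL, seed = 1L,
                                 electrode_diameter = 40,
                                 duration_s = 300, plateau_power = 80) {
  phantom <- phantom_spec()
  electrode <- build_leveen_electrode(electrode_diameter, 10L)
  scene <- build_phantom_scene(phantom, electrode,
                               vessel_offset = vessel_offset)
  trace <- make_power_trace(duration_s = duration_s,
                            plateau_power = plateau_power, seed = seed)
  list(scene = scene, trace = trace, phantom = phantom,
       electrode = electrode)
}

#' Synthetic slice image of a known boundary
#'
#' Rasterises a closed contour into a grayscale image (bright interior
#' on a darker background, like a scanned agar section), with optional
#' Gaussian blur and seeded Gaussian noise. The exact contour is
#' returned as ground truth.
#'
#' @param boundary closed 2D polyline (mm).
#' @param spacing pixel spacing in mm.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param blur_px Gaussian blur sigma in pixels (0 = none).
#' @param contrast foreground-background intensity difference.
#' @param background background intensity.
#' @param margin_mm image margin around the contour bounding box.
#' @param plane plane tag for the resulting scan.
#' @param seed RNG seed.
#' @return list with \code{scan} (a \code{\link{slice_scan}} whose
#'   origin is the lower-left pixel center at (0,0) mm) and
#'   \code{truth} (the contour shifted into image coordinates).
#' @export
make_slice_image <- function(boundary, spacing = 0.25, noise_sd = 0.05,
                             blur_px = 1, contrast = 0.5,
                             background = 0.25, margin_mm = 8,
                             plane = "coronal", seed = 1L) {
  p <- as.matrix(boundary)
  if (nrow(p) < 3L) stop("boundary must be a closed polygon")
  lo <- apply(p, 2L, min) - margin_mm
  shifted <- sweep(p, 2L, lo)
  ext <- apply(shifted, 2L, max) + margin_mm
  nxp <- ceiling(ext[1] / spacing); nyp <- ceiling(ext[2] / spacing)
  xs <- (seq_len(nxp) - 1L) * spacing
  ys <- (seq_len(nyp) - 1L) * spacing
  inside <- point_in_polygon(
    cbind(rep(xs, times = nyp), rep(ys, each = nxp)), shifted)
  img <- matrix(background + contrast * inside, nxp, nyp)
  if (blur_px > 0) img <- gaussian_blur(img, blur_px)
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img)))
  img <- pmin(pmax(img, 0), 1)
  list(scan = slice_scan(img, spacing, plane), truth = shifted)
}

# Even-odd (crossing number) point-in-polygon test, vectorised over
# points.
point_in_polygon <- function(points, poly) {
  poly <- as.matrix(poly)
  if (all(poly[1L, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  x <- points[, 1]; y <- points[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    n <- nrow(m)
    pad <- m[c(rep(1L, r), 1:n, rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * pad[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' CT-like volume with painted tine curves
#'
#' Builds a soft-tissue-intensity volume in the electrode frame and
#' paints each (optionally deflected) tine centerline at metal
#' intensity. Deflections displace each tine azimuthally, growing
#' quadratically with arc length so the stated deflection is reached at
#' the tine tip — emulating tines bent away from their ideal positions.
#'
#' @param electrode an \code{electrode_spec} (electrode frame).
#' @param deflections per-tine deflection magnitudes in mm (length
#'   \code{n_tines}).
#' @param voxel_mm isotropic voxel spacing.
#' @param noise_sd background HU noise.
#' @param seed RNG seed.
#' @return a \code{ct_volume}: \code{volume} (3D array, HU-like),
#'   \code{spacing}, \code{origin} (mm of voxel (1,1,1) center),
#'   \code{tip_mm}, \code{truth} (list of deflected centerline
#'   polylines).
#' @export
make_tine_ct <- function(electrode, deflections = NULL, voxel_mm = 0.5,
                         noise_sd = 15, seed = 1L) {
  n <- electrode$n_tines
  if (is.null(deflections)) deflections <- rep(0, n)
  if (length(deflections) != n)
    stop("deflections must have one entry per tine")
  rho <- electrode$nominal_diameter / 2
  lo <- c(-rho - 6, -rho - 6, -6)
  hi <- c(rho + 6, rho + 6, rho + 6)
  dims <- as.integer(ceiling((hi - lo) / voxel_mm))
  origin <- lo + voxel_mm / 2

  truth <- vector("list", n)
  for (i in seq_len(n)) {
    path <- electrode$tine_paths[[i]]
    if (deflections[i] != 0) {
      seg <- sqrt(rowSums(diff(path)^2))
      s <- c(0, cumsum(seg)); L <- s[length(s)]
      phi <- atan2(path[nrow(path), 2], path[nrow(path), 1])
      e_phi <- c(-sin(phi), cos(phi), 0)
      path <- path + outer((s / L)^2 * deflections[i], e_phi)
    }
    if (any(sweep(path, 2L, lo) < 0) || any(sweep(path, 2L, hi) > 0))
      stop("deflection moves tine outside the volume")
    truth[[i]] <- path
  }

  vol <- with_seed(seed, array(50 + rnorm(prod(dims), 0, noise_sd), dims))
  for (path in truth) {
    fine <- resample_polyline(path, max(50L, round(4 * rho / voxel_mm)))
    vi <- round(sweep(fine, 2L, origin) / voxel_mm) + 1L
    ok <- vi[, 1] >= 1 & vi[, 1] <= dims[1] & vi[, 2] >= 1 &
      vi[, 2] <= dims[2] & vi[, 3] >= 1 & vi[, 3] <= dims[3]
    vol[vi[ok, , drop = FALSE]] <- 3000
  }
  structure(list(volume = vol, spacing = voxel_mm, origin = origin,
                 tip_mm = electrode$tip_position, truth = truth),
            class = "ct_volume")
}
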