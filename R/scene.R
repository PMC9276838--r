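#' Vessel specification
#'
#' A cylindrical vessel (or phantom water channel) given by its centerline
#' polyline, lumen diameter, mean flow speed and fluid temperature. The
#' paper's phantom channel is 5 mm diameter with 10.5 cm/s water flow.
#'
#' @param centerline k x 3 matrix of centerline points (mm); a straight
#'   vessel needs only its two endpoints.
#' @param diameter lumen diameter in mm (> 0).
#' @param flow_speed mean flow speed in mm/s (>= 0); 0 degrades the vessel
#'   to a conduction-only stationary fluid column.
#' @param fluid_temperature blood or water temperature in degrees C.
#' @return A \code{vessel_spec} object.
#' @export
vessel_spec <- function(centerline, diameter = 5, flow_speed = 105,
                        fluid_temperature = 20) {
  centerline <- as.matrix(centerline)
  stopifnot(ncol(centerline) == 3L, nrow(centerline) >= 2L)
  if (!is.finite(diameter) || diameter <= 0) stop("vessel diameter must be > 0")
  if (!is.finite(flow_speed) || flow_speed < 0) stop("flow_speed must be >= 0")
  structure(list(centerline = centerline, diameter = diameter,
                 flow_speed = flow_speed,
                 fluid_temperature = fluid_temperature),
            class = "vessel_spec")
}

#' Agar phantom specification
#'
#' Geometry of the beaker phantom: a cylinder of agar with a return pad on
#' the bottom surface. Defaults approximate a two-liter beaker filled with
#' 1.9 L of agar (radius 65 mm, height 145 mm).
#'
#' @param beaker_radius beaker inner radius, mm.
#' @param beaker_height agar fill height, mm.
#' @param pad_radius radius of the circular return pad on the beaker
#'   bottom, mm.
#' @return A \code{phantom_spec} object.
#' @export
phantom_spec <- function(beaker_radius = 65, beaker_height = 145,
                         pad_radius = 50) {
  stopifnot(beaker_radius > 0, beaker_height > 0,
            pad_radius > 0, pad_radius <= beaker_radius)
  structure(list(beaker_radius = beaker_radius,
                 beaker_height = beaker_height,
                 pad_radius = pad_radius),
            class = "phantom_spec")
}

# Material class codes used on grids and in scenes.
MATERIALS <- c(outside = 0L, tissue = 1L, lumen = 2L, electrode = 3L,
               shaft = 4L)

new_scene <- function(electrode, electrode_surface, medium, ground,
                      vessels = list(), shaft = NULL,
                      initial_temperature = 20) {
  structure(list(electrode = electrode,
                 electrode_surface = electrode_surface,
                 medium = medium, ground = ground, vessels = vessels,
                 shaft = shaft,
                 initial_temperature = initial_temperature),
            class = "rfa_scene")
}

#' @export
print.rfa_scene <- function(x, ...) {
  cat("rfa_scene\n")
  cat("  medium:", x$medium$type,
      paste(names(x$medium)[-1],
            vapply(x$medium[-1], function(v) paste(format(v, digits = 4),
                                                   collapse = ","),
                   character(1)),
            collapse = " "), "\n")
  cat("  electrode surface:", x$electrode_surface$type, "\n")
  cat("  ground:", x$ground$type, "\n")
  cat("  vessels:", length(x$vessels), "\n")
  invisible(x)
}

#' Build a beaker-phantom simulation scene
#'
#' Places an umbrella electrode on the beaker axis (inserted from the top,
#' tines opening downwards), with the return pad on the beaker bottom as
#' the ground boundary and an optional straight vertical water channel at
#' a given offset from the shaft axis. The offset is measured from the
#' shaft axis to the vessel \emph{centerline} (configurable convention via
#' \code{offset_to_wall}).
#'
#' @param phantom a \code{\link{phantom_spec}}.
#' @param electrode an \code{\link{electrode_spec}} (in electrode frame,
#'   as returned by \code{\link{build_leveen_electrode}}).
#' @param vessel_offset optional distance from the shaft axis to the
#'   vessel centerline, mm; \code{NULL} for no vessel.
#' @param vessel optional \code{\link{vessel_spec}} template supplying
#'   diameter, flow and temperature (centerline is ignored; the channel is
#'   vertical through the full phantom height).
#' @param tip_height height of the electrode tip above the beaker bottom,
#'   mm.
#' @param offset_to_wall if \code{TRUE}, \code{vessel_offset} is measured
#'   to the near lumen wall instead of the centerline.
#' @return An \code{rfa_scene}.
#' @export
build_phantom_scene <- function(phantom, electrode, vessel_offset = NULL,
                                vessel = NULL, tip_height = 85,
                                offset_to_wall = FALSE) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(electrode, "electrode_spec"))
  # electrode frame -> world: handle points up (+z), tines open downwards
  flip <- rigid_transform(rotation_about_axis(c(1, 0, 0), pi),
                          c(0, 0, tip_height))
  el <- transform_electrode(electrode, flip)
  shaft <- list(
    from = el$tip_position,
    to = el$tip_position + el$shaft_axis *
      (phantom$beaker_height - tip_height + 20),
    radius = 1.25)

  vessels <- list()
  if (!is.null(vessel_offset)) {
    if (is.null(vessel)) vessel <- vessel_spec(matrix(0, 2, 3))
    off <- vessel_offset + if (offset_to_wall) vessel$diameter / 2 else 0
    if (off + vessel$diameter / 2 >= phantom$beaker_radius)
      stop("vessel channel does not fit inside the beaker")
    vessel$centerline <- rbind(c(off, 0, 0),
                               c(off, 0, phantom$beaker_height))
    vessels <- list(vessel)
  }

  new_scene(
    electrode = el,
    electrode_surface = list(type = "tines", tine_radius = 0.4),
    medium = list(type = "cylinder", radius = phantom$beaker_radius,
                  height = phantom$beaker_height),
    ground = list(type = "bottom_pad", radius = phantom$pad_radius),
    vessels = vessels,
    shaft = shaft,
    initial_temperature = 20)
}

# Shortest distance from points (n x 3, mm) to a polyline (k x 3).
dist_to_polyline <- function(points, path) {
  points <- as.matrix(points)
  path <- as.matrix(path)
  d2 <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(path) - 1L)) {
    a <- path[s, ]; b <- path[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    rel <- sweep(points, 2L, a)
    t <- if (len2 > 0) pmin(pmax(as.numeric(rel %*% ab) / len2, 0), 1) else 0
    dd <- rel - outer(t, ab)
    d2 <- pmin(d2, rowSums(dd^2))
  }
  sqrt(d2)
}

# Distance to all electrode tine polylines (mm).
dist_to_tines <- function(points, electrode) {
  d <- rep(Inf, nrow(points))
  for (p in electrode$tine_paths) d <- pmin(d, dist_to_polyline(points, p))
  d
}

#' Classify points into scene material classes
#'
#' Every query point maps to exactly one material class; precedence is
#' electrode metal, insulated shaft, vessel lumen, tissue/agar, outside.
#'
#' @param scene an \code{rfa_scene}.
#' @param points n x 3 matrix of query points (mm).
#' @param resolution optional grid spacing used to thicken thin tines to
#'   a resolvable radius (as during discretization); default 0 uses the
#'   geometric tine radius.
#' @return character vector of material class names.
#' @export
scene_material <- function(scene, points, resolution = 0) {
  points <- as.matrix(points)
  n <- nrow(points)
  m <- rep("outside", n)

  med <- scene$medium
  inside <- switch(med$type,
    cylinder = points[, 1]^2 + points[, 2]^2 <= med$radius^2 &
      points[, 3] >= 0 & points[, 3] <= med$height,
    ball = rowSums(sweep(points, 2L, med$center)^2) <= med$radius^2,
    box = points[, 1] >= med$lo[1] & points[, 1] <= med$hi[1] &
      points[, 2] >= med$lo[2] & points[, 2] <= med$hi[2] &
      points[, 3] >= med$lo[3] & points[, 3] <= med$hi[3],
    stop("unknown medium type: ", med$type))
  m[inside] <- "tissue"

  for (v in scene$vessels) {
    dl <- dist_to_polyline(points, v$centerline)
    m[inside & dl <= v$diameter / 2] <- "lumen"
  }
  if (!is.null(scene$shaft)) {
    ds <- dist_to_polyline(points, rbind(scene$shaft$from, scene$shaft$to))
    m[inside & ds <= max(scene$shaft$radius, 0.6 * resolution)] <- "shaft"
  }
  phi <- scene_electrode_phi(scene, points, resolution)
  m[inside & phi <= 0] <- "electrode"
  m
}

# Signed distance to the energized electrode surface: negative inside.
scene_electrode_phi <- function(scene, points, resolution = 0) {
  es <- scene$electrode_surface
  if (es$type == "sphere") {
    sqrt(rowSums(sweep(as.matrix(points), 2L, es$center)^2)) - es$radius
  } else if (es$type == "tines") {
    r_eff <- max(es$tine_radius, 0.6 * resolution)
    dist_to_tines(points, scene$electrode) - r_eff
  } else stop("unknown electrode surface type: ", es$type)
}
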