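# File formats: NIfTI volumes (CT-like inputs, temperature/damage
# exports), YAML scene/run configs, CSV tine detections, legacy-VTK
# domain export for inspection.

#' Write a 3D volume as NIfTI
#'
#' @param volume 3D array, or a \code{ct_volume}.
#' @param file output path (\code{.nii} or \code{.nii.gz}).
#' @param spacing voxel spacing in mm (taken from a \code{ct_volume}).
#' @return \code{file}, invisibly.
#' @export
write_volume <- function(volume, file, spacing = 1) {
  if (inherits(volume, "ct_volume")) {
    spacing <- volume$spacing
    volume <- volume$volume
  }
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(spacing, 3L)
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a 3D volume from NIfTI
#'
#' @param file NIfTI path.
#' @param origin physical position of voxel (1,1,1) center, mm.
#' @return a \code{ct_volume} (fields \code{volume}, \code{spacing},
#'   \code{origin}).
#' @export
read_volume <- function(file, origin = c(0, 0, 0)) {
  img <- RNifti::readNifti(file)
  structure(list(volume = array(as.numeric(img), dim(img)),
                 spacing = RNifti::pixdim(img)[1],
                 origin = origin),
            class = "ct_volume")
}

#' Export tine detections as a point-list CSV
#' @param detection result of \code{\link{detect_tines}}.
#' @param file output CSV path.
#' @return \code{file}, invisibly.
#' @export
write_tine_csv <- function(detection, file) {
  rows <- do.call(rbind, lapply(seq_along(detection$tines), function(i) {
    p <- detection$tines[[i]]
    data.frame(tine = i, point = seq_len(nrow(p)),
               x_mm = p[, 1], y_mm = p[, 2], z_mm = p[, 3])
  }))
  write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Serialize a scene to a YAML config
#'
#' Phantom scenes round-trip through a compact key/value form; the
#' electrode is regenerated parametrically on read.
#' @param scene an \code{rfa_scene} built by
#'   \code{\link{build_phantom_scene}}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_scene_yaml <- function(scene, file) {
  el <- scene$electrode
  v <- if (length(scene$vessels)) scene$vessels[[1]] else NULL
  cfg <- list(
    kind = "phantom",
    beaker_radius_mm = scene$medium$radius,
    beaker_height_mm = scene$medium$height,
    pad_radius_mm = scene$ground$radius,
    electrode = list(nominal_diameter_mm = el$nominal_diameter,
                     n_tines = el$n_tines,
                     deployed_fraction = el$deployed_fraction,
                     tip_height_mm = el$tip_position[3]),
    vessel = if (!is.null(v)) list(offset_mm = v$centerline[1, 1],
                                   diameter_mm = v$diameter,
                                   flow_speed_mm_s = v$flow_speed,
                                   temperature_C = v$fluid_temperature))
  yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Read a scene from a YAML config
#' @param file path written by \code{\link{write_scene_yaml}} (or
#'   hand-authored in the same schema).
#' @return an \code{rfa_scene}.
#' @export
read_scene_yaml <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!identical(cfg$kind, "phantom"))
    stop("unsupported scene kind: ", cfg$kind)
  ph <- phantom_spec(beaker_radius = cfg$beaker_radius_mm,
                     beaker_height = cfg$beaker_height_mm,
                     pad_radius = cfg$pad_radius_mm)
  el <- build_leveen_electrode(cfg$electrode$nominal_diameter_mm,
                               cfg$electrode$n_tines,
                               cfg$electrode$deployed_fraction %||% 1)
  vs <- NULL
  off <- NULL
  if (!is.null(cfg$vessel)) {
    off <- cfg$vessel$offset_mm
    vs <- vessel_spec(matrix(0, 2, 3), diameter = cfg$vessel$diameter_mm,
                      flow_speed = cfg$vessel$flow_speed_mm_s,
                      fluid_temperature = cfg$vessel$temperature_C)
  }
  build_phantom_scene(ph, el, vessel_offset = off, vessel = vs,
                      tip_height = cfg$electrode$tip_height_mm %||% 85)
}

#' Read an ASCII PLY triangle mesh
#' @param file PLY path (as written by \code{\link{write_ply}}).
#' @return a \code{tri_mesh}.
#' @export
read_ply <- function(file) {
  lines <- readLines(file)
  endh <- match("end_header", lines)
  if (is.na(endh)) stop("format error: not an ASCII PLY file")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)[1]))
  v <- matrix(scan(text = lines[(endh + 1):(endh + nv)], quiet = TRUE),
              ncol = 3L, byrow = TRUE)
  f <- matrix(scan(text = lines[(endh + nv + 1):(endh + nv + nf)],
                   quiet = TRUE), ncol = 4L, byrow = TRUE)
  tri_mesh(v, f[, 2:4, drop = FALSE] + 1L)
}

#' Export a domain as a legacy-VTK structured-points file
#'
#' Writes the material labels (and optionally one scalar field) for
#' inspection in standard mesh viewers.
#' @param domain an \code{rfa_domain}.
#' @param file output \code{.vtk} path.
#' @param field optional full-grid scalar field to include.
#' @param field_name name for the optional field.
#' @return \code{file}, invisibly.
#' @export
write_vtk_domain <- function(domain, file, field = NULL,
                             field_name = "field") {
  con <- file(file, "w")
  on.exit(close(con))
  d <- domain$dims
  writeLines(c("# vtk DataFile Version 3.0", "rfasim domain", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", domain$origin[1],
                       domain$origin[2], domain$origin[3]),
               sprintf("SPACING %g %g %g", domain$spacing, domain$spacing,
                       domain$spacing),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS material int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(domain$material), con)
  if (!is.null(field)) {
    writeLines(c(sprintf("SCALARS %s double 1", field_name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(field, digits = 9, trim = TRUE, scientific = TRUE),
               con)
  }
  invisible(file)
}
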