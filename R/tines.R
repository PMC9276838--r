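# Tine detection in CT-like volumes. The deployed tines are the only
# metal-density structures near the electrode tip; detection is
# intensity thresholding at a metal-range cutoff, azimuthal clustering
# of the metal voxels about the shaft axis, and per-cluster centerline
# extraction by binning along the distance-from-tip parameter (which is
# monotone along an umbrella tine). This mirrors the kind of
# special-purpose routine used to recover deployed tine positions from
# intra-procedural CT.

#' Detect electrode tines in a CT-like volume
#'
#' @param ct a \code{ct_volume} (fields \code{volume}, \code{spacing},
#'   \code{origin}), e.g. from \code{\link{make_tine_ct}} or
#'   \code{\link{read_volume}}.
#' @param tip_seed electrode tip position in mm.
#' @param intensity_threshold metal-range cutoff (HU-like units).
#' @param expected_tines optional expected count; fewer detections
#'   produce a warning with the partial result.
#' @param ideal optional ideal \code{electrode_spec} (same frame): when
#'   given, each detected tine is matched by azimuth and its maximum
#'   deflection from the ideal curve is reported.
#' @param gap_rad azimuthal gap (radians) separating tine clusters.
#' @return list with \code{tines} (list of ordered k x 3 centerline
#'   polylines, each rooted at the tip), \code{n_detected}, and
#'   \code{deflections_mm} when \code{ideal} is given.
#' @export
detect_tines <- function(ct, tip_seed, intensity_threshold = 1500,
                         expected_tines = NULL, ideal = NULL,
                         gap_rad = 0.15) {
  vol <- ct$volume
  idx <- which(vol > intensity_threshold)
  if (!length(idx)) stop("detection error: no metal-range voxels in volume")
  d <- dim(vol)
  i0 <- idx - 1L
  pts <- cbind(ct$origin[1] + ct$spacing * (i0 %% d[1]),
               ct$origin[2] + ct$spacing * ((i0 %/% d[1]) %% d[2]),
               ct$origin[3] + ct$spacing * (i0 %/% (d[1] * d[2])))
  rel <- sweep(pts, 2L, tip_seed)
  if (min(sqrt(rowSums(rel^2))) > 10)
    stop("detection error: no metal-range voxels near the tip seed")

  # cluster by azimuth about the shaft axis, ignoring the near-axis
  # cone where all tines converge on the tip
  rad <- sqrt(rel[, 1]^2 + rel[, 2]^2)
  far <- rad > 3 * ct$spacing
  if (!any(far)) stop("detection error: no deployed tines visible")
  ang <- atan2(rel[far, 2], rel[far, 1])
  ord <- order(ang)
  a_sorted <- ang[ord]
  gaps <- diff(c(a_sorted, a_sorted[1] + 2 * pi))
  cut <- which(gaps > gap_rad)
  n_cl <- length(cut)
  if (n_cl == 0L) stop("detection error: tines not separable in azimuth")
  # cluster id for each sorted point: segment between successive cuts
  cl_id <- integer(length(a_sorted))
  start <- c(1L, head(cut, -1L) + 1L)
  for (k in seq_len(n_cl)) cl_id[start[k]:cut[k]] <- k
  cl_of_point <- integer(sum(far))
  cl_of_point[ord] <- cl_id

  fp <- which(far)
  tines <- vector("list", n_cl)
  for (k in seq_len(n_cl)) {
    sel <- fp[cl_of_point == k]
    p <- pts[sel, , drop = FALSE]
    s <- sqrt(rowSums(sweep(p, 2L, tip_seed)^2))
    bins <- floor(s / ct$spacing)
    ub <- sort(unique(bins))
    ctr <- t(vapply(ub, function(b) colMeans(p[bins == b, , drop = FALSE]),
                    numeric(3)))
    tines[[k]] <- rbind(matrix(tip_seed, 1L), ctr)
  }
  # stable ordering by mean azimuth
  mean_az <- vapply(tines, function(p)
    atan2(mean(p[-1L, 2] - tip_seed[2]), mean(p[-1L, 1] - tip_seed[1])),
    numeric(1))
  tines <- tines[order(mean_az)]

  out <- list(tines = tines, n_detected = length(tines))
  if (!is.null(ideal)) {
    az_ideal <- vapply(ideal$tine_paths, function(p) {
      e <- p[nrow(p), ] - ideal$tip_position
      atan2(e[2], e[1])
    }, numeric(1))
    defl <- vapply(tines, function(p) {
      e <- colMeans(p[-1L, , drop = FALSE]) - tip_seed
      az <- atan2(e[2], e[1])
      dd <- abs(((az - az_ideal + pi) %% (2 * pi)) - pi)
      ip <- ideal$tine_paths[[which.min(dd)]]
      max(dist_to_polyline(p, ip))
    }, numeric(1))
    out$deflections_mm <- defl
  }
  if (!is.null(expected_tines) && length(tines) < expected_tines)
    warning(sprintf("detected %d of %d expected tines",
                    length(tines), expected_tines))
  out
}
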