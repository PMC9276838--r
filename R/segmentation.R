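# Region-based level-set segmentation of grayscale slice scans. The
# denatured (ablated) agar is bright against the semi-transparent
# background; a Chan-Vese evolution initialised from an automatic
# intensity threshold recovers the closed ablation boundary with
# sub-pixel positions.

#' Construct a slice scan
#'
#' @param image numeric matrix in [0, 1]; rows index x, columns y.
#' @param spacing pixel spacing in mm (> 0).
#' @param plane \code{"coronal"} or \code{"axial"} (metadata tag: coronal
#'   sections for plain phantoms, axial for vessel phantoms).
#' @return a \code{slice_scan}.
#' @export
slice_scan <- function(image, spacing, plane = c("coronal", "axial")) {
  plane <- match.arg(plane)
  image <- as.matrix(image)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0")
  structure(list(image = image, spacing = spacing, plane = plane),
            class = "slice_scan")
}

#' @export
print.slice_scan <- function(x, ...) {
  cat(sprintf("slice_scan: %d x %d px at %g mm/px (%s plane)\n",
              nrow(x$image), ncol(x$image), x$spacing, x$plane))
  invisible(x)
}

#' Read/write a grayscale slice scan as PNG with a spacing sidecar
#'
#' The pixel spacing travels in a small JSON sidecar
#' (\code{<file>.json}) next to the image.
#' @param file PNG path.
#' @param scan a \code{slice_scan} (for writing).
#' @return \code{read_slice_scan}: a \code{slice_scan};
#'   \code{write_slice_scan}: \code{file}, invisibly.
#' @export
read_slice_scan <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  side <- paste0(file, ".json")
  if (!file.exists(side)) stop("missing spacing sidecar: ", side)
  meta <- jsonlite::read_json(side)
  slice_scan(t(img)[, rev(seq_len(nrow(img))), drop = FALSE],
             spacing = meta$spacing_mm, plane = meta$plane)
}

#' @rdname read_slice_scan
#' @export
write_slice_scan <- function(scan, file) {
  # PNG rows run top-to-bottom; the scan matrix is x (rows) by y (cols)
  img <- t(scan$image[, rev(seq_len(ncol(scan$image))), drop = FALSE])
  png::writePNG(pmin(pmax(img, 0), 1), file)
  jsonlite::write_json(list(spacing_mm = scan$spacing, plane = scan$plane),
                       paste0(file, ".json"), auto_unbox = TRUE)
  invisible(file)
}

# Isodata (Ridler-Calvard) automatic threshold.
isodata_threshold <- function(x, iters = 50L) {
  thr <- mean(range(x))
  for (i in seq_len(iters)) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    if (!length(lo) || !length(hi)) break
    new <- (mean(lo) + mean(hi)) / 2
    if (abs(new - thr) < 1e-6) break
    thr <- new
  }
  thr
}

#' Segment the ablation boundary in a slice scan
#'
#' Region-based (intensity homogeneity) level-set evolution of the
#' Chan-Vese type: the level-set function is initialised from an isodata
#' intensity threshold and evolved under the competition of the two
#' region means plus a curvature regulariser; the zero level set at
#' convergence is extracted with sub-pixel precision and returned as a
#' closed contour in mm.
#'
#' @param scan a \code{\link{slice_scan}}.
#' @param mu curvature (length) penalty weight.
#' @param iterations evolution steps.
#' @param dt pseudo-time step.
#' @return a closed 2D polyline (k x 2 matrix, mm), the largest boundary
#'   loop, with attribute \code{phi} (final level-set field).
#' @export
segment_boundary <- function(scan, mu = 0.2, iterations = 200L, dt = 0.45) {
  I <- scan$image
  rng <- diff(range(I))
  if (rng < 0.05)
    stop("segmentation error: no distinguishable foreground region")
  I <- (I - min(I)) / rng
  thr <- isodata_threshold(I)
  phi <- ifelse(I > thr, 1, -1)
  eps <- 1

  for (it in seq_len(iterations)) {
    inside <- phi > 0
    if (!any(inside) || all(inside))
      stop("segmentation error: region collapsed")
    c1 <- mean(I[inside]); c2 <- mean(I[!inside])
    force <- (I - c2)^2 - (I - c1)^2
    kappa <- curvature2d(phi)
    delta <- eps / (pi * (eps^2 + phi^2))
    phi <- phi + dt * delta * (mu * kappa + force)
    phi <- pmin(pmax(phi, -3), 3)
    if (it %% 25L == 0L) phi <- smooth3x3(phi)
  }

  px <- seq_len(nrow(I)); py <- seq_len(ncol(I))
  cl <- grDevices::contourLines(px, py, phi, levels = 0)
  if (!length(cl)) stop("segmentation error: no boundary found")
  len <- vapply(cl, function(c) polygon_area(cbind(c$x, c$y)), numeric(1))
  c0 <- cl[[which.max(abs(len))]]
  contour <- cbind(c0$x - 1, c0$y - 1) * scan$spacing
  attr(contour, "phi") <- phi
  contour
}

# Mean-curvature of a 2D field (central differences, regularised).
curvature2d <- function(phi) {
  n <- nrow(phi); m <- ncol(phi)
  pad <- function(p) p[c(1, 1:n, n), c(1, 1:m, m)]
  P <- pad(phi)
  ix <- 2:(n + 1); iy <- 2:(m + 1)
  px <- (P[ix + 1, iy] - P[ix - 1, iy]) / 2
  py <- (P[ix, iy + 1] - P[ix, iy - 1]) / 2
  pxx <- P[ix + 1, iy] - 2 * P[ix, iy] + P[ix - 1, iy]
  pyy <- P[ix, iy + 1] - 2 * P[ix, iy] + P[ix, iy - 1]
  pxy <- (P[ix + 1, iy + 1] - P[ix + 1, iy - 1] -
            P[ix - 1, iy + 1] + P[ix - 1, iy - 1]) / 4
  den <- (px^2 + py^2)^1.5 + 1e-8
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) / den
}

smooth3x3 <- function(x) {
  n <- nrow(x); m <- ncol(x)
  P <- x[c(1, 1:n, n), c(1, 1:m, m)]
  ix <- 2:(n + 1); iy <- 2:(m + 1)
  (P[ix, iy] * 4 + P[ix - 1, iy] + P[ix + 1, iy] +
     P[ix, iy - 1] + P[ix, iy + 1]) / 8
}

#' Signed area of a closed 2D polygon (shoelace)
#' @param contour k x 2 matrix; closing edge implicit.
#' @return signed area (same squared unit as the input).
#' @export
polygon_area <- function(contour) {
  p <- as.matrix(contour)
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}
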