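#' Rigid transforms between simulation and image coordinates
#'
#' A rigid transform maps points \code{x} (rows, mm) to
#' \code{x \%*\% t(rotation) + translation}. Rotations are proper
#' (determinant +1); reflections are rejected.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @return An object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (reflection, not rigid)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation (mm):", format(x$translation, digits = 6), "\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A \code{\link{rigid_transform}}.
#' @param points n x 3 matrix of points (mm); a length-3 vector is accepted.
#' @return Transformed points, same shape as the input.
#' @export
apply_rigid <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1L) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Compose two rigid transforms
#'
#' \code{compose_rigid(a, b)} applies \code{b} first, then \code{a}.
#' @param a,b \code{\link{rigid_transform}} objects.
#' @return The composed \code{rigid_transform}.
#' @export
compose_rigid <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A \code{\link{rigid_transform}}.
#' @return The inverse \code{rigid_transform}.
#' @export
invert_rigid <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Axis-angle rotation helper
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Least-squares rigid fit (Kabsch): find transform T with
# T(source) ~= target. Returns the transform with RMS residual attached.
fit_rigid <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  stopifnot(nrow(source) == nrow(target), ncol(source) == 3L)
  if (nrow(source) < 3L) stop("need at least 3 point pairs for a rigid fit")
  cs <- colMeans(source); ct <- colMeans(target)
  S <- sweep(source, 2L, cs); Tm <- sweep(target, 2L, ct)
  # degenerate (collinear) configurations have rank < 2 covariance
  H <- crossprod(S, Tm)
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) point set: rigid pose is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - as.numeric(R %*% cs)
  out <- rigid_transform(R, tr)
  res <- apply_rigid(out, source) - target
  attr(out, "rms_residual") <- sqrt(mean(rowSums(res^2)))
  out
}
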