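# Accuracy analysis: equidistant boundary-point sampling, point-to-surface
# distance reports, the manufacturer-chart comparator and the paired
# significance test.

#' Sample equidistant points on a closed boundary
#'
#' 2D contours get exactly \code{n} points equally spaced in arc length
#' (the 64-point protocol for sectioned phantoms). Triangle meshes get
#' approximately \code{n} evenly distributed surface points
#' (the ~10,000-point protocol for in-vivo surfaces): area-weighted
#' random candidates are thinned to a Poisson-disk set whose radius is
#' tuned by bisection so the accepted count lands within 1% of \code{n}.
#'
#' @param boundary closed 2D polyline (k x 2 matrix, mm; the closing
#'   segment is implicit) or a \code{tri_mesh}.
#' @param n number of points (>= 3).
#' @param seed RNG seed for surface sampling (2D sampling is
#'   deterministic).
#' @return n x 2 or ~n x 3 matrix of points (mm).
#' @export
sample_equidistant <- function(boundary, n, seed = 1L) {
  if (n < 3L) stop("need n >= 3 sample points")
  if (inherits(boundary, "tri_mesh")) return(sample_mesh_points(boundary, n, seed))
  contour_equidistant(boundary, n)
}

contour_equidistant <- function(contour, n) {
  p <- as.matrix(contour)
  if (nrow(p) < 3L) stop("degenerate boundary: fewer than 3 vertices")
  if (all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  closed <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums((closed[-1L, , drop = FALSE] -
                       closed[-nrow(closed), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  if (L <= 0) stop("degenerate boundary: zero perimeter")
  tgt <- (seq_len(n) - 1L) * L / n
  out <- vapply(seq_len(ncol(p)), function(j)
    approx(s, closed[, j], xout = tgt)$y, numeric(n))
  matrix(out, ncol = ncol(p))
}

sample_mesh_points <- function(mesh, n, seed = 1L) {
  A <- mesh_area(mesh)
  if (A <= 0) stop("degenerate boundary: zero surface area")
  d_star <- sqrt(A / n)
  cand <- with_seed(seed, random_surface_points(mesh, 30L * n))
  lo <- 0.5 * d_star; hi <- 1.3 * d_star
  pick <- NULL
  for (it in 1:14) {
    r <- (lo + hi) / 2
    idx <- .poisson_disk_thin(cand, r, as.integer(ceiling(1.01 * n)))
    if (length(idx) >= n) {
      pick <- idx[seq_len(n)]
      lo <- r
    } else hi <- r
    if ((hi - lo) < 0.005 * d_star && !is.null(pick)) break
  }
  if (is.null(pick)) {  # extremely coarse mesh: fall back to candidates
    pick <- seq_len(min(n, nrow(cand)))
  }
  cand[pick, , drop = FALSE]
}

# Area-weighted random points on a mesh surface (uniform per triangle).
random_surface_points <- function(mesh, n) {
  v <- mesh$vertices; f <- mesh$triangles
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  area <- sqrt(cx^2 + cy^2 + cz^2) / 2
  ti <- sample.int(nrow(f), n, replace = TRUE, prob = area)
  r1 <- sqrt(runif(n)); r2 <- runif(n)
  w1 <- 1 - r1; w2 <- r1 * (1 - r2); w3 <- r1 * r2
  v[f[ti, 1], , drop = FALSE] * w1 + v[f[ti, 2], , drop = FALSE] * w2 +
    v[f[ti, 3], , drop = FALSE] * w3
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Point-to-surface error report
#'
#' Distance from each "true"-boundary sample point to the closest point
#' of the model surface (point-to-triangle for meshes, point-to-segment
#' for 2D contours; never vertex-only). The report is directional
#' (true boundary to model) by construction; swap the arguments for the
#' reverse direction — it is never substituted silently.
#'
#' @param true_points n x 3 (or n x 2) matrix of points sampled on the
#'   true ablation boundary.
#' @param model a \code{tri_mesh} (3D) or closed 2D polyline matrix.
#' @param direction label recorded in the report.
#' @return an \code{error_report}: \code{distances} (mm),
#'   \code{mean_error}, \code{max_error}, \code{n_points},
#'   \code{direction}.
#' @export
surface_error <- function(true_points, model,
                          direction = "true_to_model") {
  true_points <- as.matrix(true_points)
  if (nrow(true_points) == 0L) stop("empty point set")
  if (inherits(model, "ablation_volume")) model <- model$mesh
  if (inherits(model, "chart_model")) model <- model$mesh
  if (inherits(model, "tri_mesh")) {
    if (nrow(model$triangles) == 0L) stop("empty model surface")
    d <- .point_mesh_distance(true_points, model$vertices,
                              model$triangles)
  } else {
    d <- point_contour_distance(true_points, as.matrix(model))
  }
  structure(list(distances = as.numeric(d), mean_error = mean(d),
                 max_error = max(d), n_points = length(d),
                 direction = direction),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error_report (%s): mean %.2f mm, max %.2f mm over %d points\n",
              x$direction, x$mean_error, x$max_error, x$n_points))
  invisible(x)
}

# Distances from 2D points to a closed polyline (point-to-segment).
point_contour_distance <- function(points, contour) {
  if (all(contour[1L, ] == contour[nrow(contour), ]))
    contour <- contour[-nrow(contour), , drop = FALSE]
  cl <- rbind(contour, contour[1L, ])
  d2 <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(cl) - 1L)) {
    a <- cl[s, ]; b <- cl[s + 1L, ]
    ab <- b - a; len2 <- sum(ab^2)
    rel <- sweep(points, 2L, a)
    tt <- if (len2 > 0) pmin(pmax((rel %*% ab) / len2, 0), 1) else 0
    dd <- rel - outer(as.numeric(tt), ab)
    d2 <- pmin(d2, rowSums(dd^2))
  }
  sqrt(d2)
}

# Brute-force point-to-mesh distance in plain R: the independent oracle
# for the compiled nearest-distance path (kept naive on purpose).
point_mesh_distance_bruteforce <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  apply(as.matrix(points), 1L, function(p) {
    best <- Inf
    for (t in seq_len(nrow(f))) {
      a <- v[f[t, 1], ]; b <- v[f[t, 2], ]; c <- v[f[t, 3], ]
      best <- min(best, point_triangle_distance_r(p, a, b, c))
    }
    best
  })
}

point_triangle_distance_r <- function(p, a, b, c) {
  # minimise |a + u(b-a) + v(c-a) - p| over the triangle by projecting
  # and clamping to edges
  ab <- b - a; ac <- c - a; ap <- p - a
  M <- rbind(c(sum(ab * ab), sum(ab * ac)), c(sum(ab * ac), sum(ac * ac)))
  rhs <- c(sum(ab * ap), sum(ac * ap))
  uv <- tryCatch(solve(M, rhs), error = function(e) c(-1, -1))
  if (length(uv) == 2L && uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) {
    q <- a + uv[1] * ab + uv[2] * ac
    return(sqrt(sum((q - p)^2)))
  }
  seg <- function(s, e) {
    d <- e - s; t <- sum((p - s) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((s + t * d - p)^2))
  }
  min(seg(a, b), seg(a, c), seg(b, c))
}

#' Manufacturer-chart ablation model
#'
#' Builds the closed two-half-ellipsoid surface from the vendor chart for
#' the given probe diameter, positioned by the electrode pose. The chart
#' ships with the 3 cm entry (proximal depth 9 mm, distal depth 16 mm,
#' radial semi-axis 15 mm); other diameters require a user-supplied
#' table. In the electrode frame the equatorial plane passes through the
#' tip, the distal half extends towards the opening tines (+z) and the
#' proximal half along the shaft.
#'
#' @param probe_diameter probe diameter in mm.
#' @param pose a \code{\link{rigid_transform}} placing the electrode
#'   frame in world coordinates (default identity).
#' @param chart_table named list: entries \code{list(proximal, distal,
#'   radial)} in mm keyed by diameter.
#' @return a \code{chart_model} with the posed \code{mesh} and the
#'   closed-form \code{volume} (mm^3).
#' @export
build_chart_model <- function(probe_diameter, pose = rigid_transform(),
                              chart_table = list(
                                `30` = list(proximal = 9, distal = 16,
                                            radial = 15))) {
  key <- as.character(probe_diameter)
  if (!key %in% names(chart_table))
    stop("no chart entry for a ", probe_diameter,
         " mm probe; supply chart_table")
  e <- chart_table[[key]]
  mesh <- half_ellipsoid_union(e$radial, c_pos = e$distal, c_neg = e$proximal)
  structure(list(probe_diameter = probe_diameter,
                 proximal_depth = e$proximal, distal_depth = e$distal,
                 radial_semi_axis = e$radial,
                 mesh = transform_mesh(mesh, pose),
                 volume = 2 * pi / 3 * e$radial^2 * (e$proximal + e$distal),
                 pose = pose),
            class = "chart_model")
}

#' @export
print.chart_model <- function(x, ...) {
  cat(sprintf(
    "chart_model: %g mm probe, depths %g (proximal) / %g (distal) mm, radial %g mm\n",
    x$probe_diameter, x$proximal_depth, x$distal_depth, x$radial_semi_axis))
  invisible(x)
}

#' Paired two-sided t-test on per-case errors
#'
#' Classical paired t statistic on the differences
#' \code{t = mean(d) / (sd(d) / sqrt(n))} with \code{n - 1} degrees of
#' freedom. A zero-variance difference vector is a degenerate case and is
#' reported as an error rather than silently returning a p-value.
#'
#' @param errors_a,errors_b equal-length (>= 2) per-case error values,
#'   paired by case.
#' @return list with \code{statistic}, \code{df}, \code{p_value},
#'   \code{mean_difference}.
#' @export
paired_comparison <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b))
    stop("paired samples must have equal length")
  n <- length(errors_a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- errors_a - errors_b
  s <- sd(d)
  if (s == 0)
    stop("degenerate paired comparison: differences have zero variance")
  t_stat <- mean(d) / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1L)
  list(statistic = t_stat, df = n - 1L, p_value = p,
       mean_difference = mean(d))
}

#' Extract a planar contour from a simulated field
#'
#' Cuts the domain with an axis-aligned plane and returns the iso-contour
#' of the field in that plane — the simulated analogue of a sectioned
#' phantom slice, used for the 64-point comparisons.
#'
#' @param field full-grid scalar field (e.g. damage Omega).
#' @param domain the \code{rfa_domain}.
#' @param axis \code{"x"}, \code{"y"} or \code{"z"}: the plane normal.
#' @param coord plane position in mm (snapped to the nearest grid layer).
#' @param level iso-level.
#' @return closed 2D polyline (mm) in the in-plane coordinates, or
#'   \code{NULL} when the level is absent in the plane.
#' @export
slice_contour <- function(field, domain, axis = "z", coord, level = 1) {
  d <- domain$dims
  ax <- match(axis, c("x", "y", "z"))
  layer <- round((coord - domain$origin[ax]) / domain$spacing) + 1L
  layer <- min(max(layer, 1L), d[ax])
  arr <- array(field, d)
  sl <- switch(ax, arr[layer, , ], arr[, layer, ], arr[, , layer])
  uv <- setdiff(1:3, ax)
  u <- domain$origin[uv[1]] + domain$spacing * (seq_len(d[uv[1]]) - 1L)
  v <- domain$origin[uv[2]] + domain$spacing * (seq_len(d[uv[2]]) - 1L)
  cl <- grDevices::contourLines(u, v, sl, levels = level)
  if (!length(cl)) return(NULL)
  len <- vapply(cl, function(c) length(c$x), integer(1))
  c0 <- cl[[which.max(len)]]
  cbind(c0$x, c0$y)
}
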