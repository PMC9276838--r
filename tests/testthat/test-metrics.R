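circle_contour <- function(r, n = 720L, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

test_that("64-point contour sampling is exactly equidistant in arc length", {
  ct <- circle_contour(20, n = 64 * 8)
  pts <- sample_equidistant(ct, 64)
  expect_equal(nrow(pts), 64L)
  # arc spacing along the polyline equals perimeter / 64 exactly
  per <- sum(sqrt(rowSums((rbind(ct[-1, ], ct[1, ]) - ct)^2)))
  seg <- sqrt(rowSums((rbind(pts[-1, ], pts[1, ]) - pts)^2))
  # chord of equal arcs on a circle: constant
  expect_lt(diff(range(seg)), 1e-9)
  expect_equal(mean(seg), per / 64, tolerance = 2e-3)

  tri <- sample_equidistant(circle_contour(10, n = 3 * 400), 3)
  d <- dist(tri)
  expect_equal(as.numeric(d) / max(d), c(1, 1, 1), tolerance = 1e-4)
})

test_that("surface sampling on a sphere is even at the target density", {
  m <- icosphere(4)
  n <- 2000L
  pts <- sample_equidistant(m, n, seed = 11)
  expect_equal(nrow(pts), n, tolerance = 0.01)
  # nearest-neighbour spacing statistics of an even spherical covering
  nn <- sapply(seq_len(500), function(i) {
    d2 <- rowSums(sweep(pts[-i, , drop = FALSE], 2L, pts[i, ])^2)
    sqrt(min(d2))
  })
  target <- sqrt(4 * pi / n)
  expect_lt(abs(mean(nn) - target) / target, 0.15)
  expect_lt(sd(nn) / mean(nn), 0.10)  # spacing CV
})

test_that("point-to-surface error has exact closed forms on spheres", {
  inner <- icosphere(4, radius = 20)
  outer <- icosphere(3, radius = 23)
  pts <- sample_equidistant(outer, 500, seed = 2)
  # push sampled points onto the exact sphere to remove faceting
  pts <- pts * 23 / sqrt(rowSums(pts^2))
  rep_ <- surface_error(pts, inner)
  # faceting of the model sphere biases distances high by its sagitta
  expect_equal(rep_$mean_error, 3, tolerance = 0.01)
  expect_equal(rep_$max_error, 3, tolerance = 0.01)
  expect_equal(rep_$direction, "true_to_model")

  # identical surfaces: zero error at the vertices
  rep0 <- surface_error(inner$vertices, inner)
  expect_lt(rep0$max_error, 1e-9)
})

test_that("compiled nearest-distance agrees with the brute-force oracle", {
  set.seed(5)
  m <- icosphere(1, radius = 10)  # 80 triangles
  m$vertices <- m$vertices + matrix(rnorm(length(m$vertices)), ncol = 3)
  pts <- matrix(rnorm(60, sd = 12), ncol = 3)
  fast <- surface_error(pts, m)$distances
  slow <- rfasim:::point_mesh_distance_bruteforce(pts, m)
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("error report is rigid-invariant and direction-aware", {
  m <- half_ellipsoid_union(15, 16, 9, n_theta = 16L, n_phi = 32L)
  pts <- sample_equidistant(icosphere(3, radius = 18), 300, seed = 3)
  base <- surface_error(pts, m)
  tr <- rigid_transform(rotation_about_axis(c(2, 1, 1), 0.8), c(5, 5, 5))
  moved <- surface_error(apply_rigid(tr, pts), transform_mesh(m, tr))
  expect_equal(moved$distances, base$distances, tolerance = 1e-9)
})

test_that("2D contour distances use segments, not vertices", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  r <- surface_error(rbind(c(5, -3)), sq)
  expect_equal(r$mean_error, 3, tolerance = 1e-12)  # mid-edge, not corner
})

test_that("manufacturer chart model matches the printed 3 cm entry", {
  cm <- build_chart_model(30)
  expect_equal(cm$proximal_depth, 9)
  expect_equal(cm$distal_depth, 16)
  expect_equal(cm$radial_semi_axis, 15)
  expect_equal(diff(range(cm$mesh$vertices[, 3])), 25, tolerance = 1e-9)
  expect_equal(diff(range(cm$mesh$vertices[, 1])), 30, tolerance = 1e-6)
  expect_equal(mesh_volume(cm$mesh), cm$volume, tolerance = 0.01)
  expect_error(build_chart_model(20), "chart")

  tr <- rigid_transform(rotation_about_axis(c(0, 1, 0), 1), c(1, 2, 3))
  cmp <- build_chart_model(30, pose = tr)
  expect_equal(mesh_volume(cmp$mesh), cm$volume, tolerance = 0.01)
})

test_that("paired t-test matches the closed-form hand computation", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 5, 7)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(4))
  p_hand <- 2 * pt(-abs(t_hand), df = 3)
  got <- paired_comparison(a, b)
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  expect_equal(got$df, 3L)
  # cross-check against the stats implementation
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  # swapping the arguments flips the sign, p unchanged
  rev <- paired_comparison(b, a)
  expect_equal(rev$statistic, -got$statistic, tolerance = 1e-12)
  expect_equal(rev$p_value, got$p_value, tolerance = 1e-12)

  expect_error(paired_comparison(c(1, 2), c(2, 3)), "zero variance")
  expect_error(paired_comparison(1, 1), "at least 2")
})
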