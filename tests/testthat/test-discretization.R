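box_scene <- function(side = 10) {
  make_analytic_scene("perfused_box", list(side = side))$scene
}

test_that("phantom discretization produces the labelled boundary sets", {
  sc <- build_phantom_scene(phantom_spec(), build_leveen_electrode(40, 10),
                            vessel_offset = 25)
  dom <- discretize_scene(sc, 3)
  expect_gt(length(dom$labels$electrode_surface), 0L)
  expect_gt(length(dom$labels$ground), 0L)
  expect_gt(length(dom$labels$vessel_wall), 0L)
  expect_gt(length(dom$labels$insulated_exterior), 0L)
  # electrode and ground sets are disjoint
  expect_length(intersect(dom$labels$electrode_surface,
                          dom$labels$ground), 0L)

  # no vessel -> no vessel_wall label
  dom0 <- discretize_scene(
    build_phantom_scene(phantom_spec(), build_leveen_electrode(40, 10)), 3)
  expect_length(dom0$labels$vessel_wall, 0L)

  # too coarse to resolve the electrode is an error
  expect_error(discretize_scene(sc, 25), "resolution")
})

test_that("halving the resolution refines the cell count by ~8x", {
  sc <- box_scene(12)
  n2 <- sum(discretize_scene(sc, 2)$material > 0L)
  n1 <- sum(discretize_scene(sc, 1)$material > 0L)
  expect_gte(n1 / n2, 4)
  expect_equal(n1 / n2, 8, tolerance = 0.2)
})

test_that("diffusion operator is symmetric with zero interior row sums", {
  sc <- box_scene(6)
  dom <- discretize_scene(sc, 1)
  op <- assemble_diffusion_operator(dom, 0.5)
  A <- operator_matrix(op)
  expect_equal(max(abs(A - Matrix::t(A))), 0)
  expect_lt(max(abs(Matrix::rowSums(A))), 1e-12)
  # PSD: smallest eigenvalue of the pure-Neumann operator is ~0
  ev <- eigen(as.matrix(A), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))
})

test_that("Dirichlet faces give the exact linear potential profile", {
  sc <- box_scene(8)
  dom <- discretize_scene(sc, 1)
  op <- assemble_diffusion_operator(
    dom, 1.0, dirichlet = list(face_zmin = 0, face_zmax = 1))
  u <- solve_operator(op, tol = 1e-12)
  z <- domain_coords(dom)[, 3]
  expect_lt(max(abs(u - z / 8)[op$unknown]), 1e-8)
})

test_that("two-material slab flux matches the harmonic-mean closed form", {
  sc <- box_scene(8)
  dom <- discretize_scene(sc, 1)
  z <- domain_coords(dom)[, 3]
  k <- ifelse(z < 4, 2.0, 0.5)   # series conduction k1 then k2
  op <- assemble_diffusion_operator(
    dom, k, dirichlet = list(face_zmin = 1, face_zmax = 0))
  u <- solve_operator(op, tol = 1e-12)
  # flux through the slab: conductance per unit area = harm. series value
  # 1 / (L1/k1 + L2/k2) over L = 8 mm with dT = 1
  g_true <- 1 / (4e-3 / 2 + 4e-3 / 0.5)
  gl <- op$dir_links[[1]]
  flux <- sum(gl$c * (gl$value - u[gl$idx]))   # W into the hot face
  area <- (8e-3)^2
  expect_equal(abs(flux) / area, g_true, tolerance = 1e-8)
})

test_that("solutions obey the discrete maximum principle", {
  sc <- box_scene(8)
  dom <- discretize_scene(sc, 1)
  set.seed(1)
  k <- exp(rnorm(prod(dom$dims), sd = 0.5))
  op <- assemble_diffusion_operator(
    dom, k, dirichlet = list(face_xmin = 0, face_xmax = 1))
  u <- solve_operator(op, tol = 1e-10)
  expect_gte(min(u[op$unknown]), -1e-9)
  expect_lte(max(u[op$unknown]), 1 + 1e-9)
})

test_that("potential error shrinks monotonically under refinement", {
  fx <- make_analytic_scene("concentric_spheres",
                            list(a = 2, b = 16, sigma = 1))
  errs <- vapply(c(2, 1, 0.5), function(h) {
    dom <- discretize_scene(fx$scene, h)
    V <- solve_potential(dom, 1, 1, tol = 1e-9,
                         near_field_calibration = FALSE, cascade = FALSE)
    co <- domain_coords(dom)
    r <- sqrt(rowSums(co^2))
    sel <- attr(V, "operator")$unknown & r > 4 & r < 14
    mean(abs(V[sel] - fx$truth$potential(r[sel])))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # at least first-order: halving h at least halves the error overall
  expect_lt(errs[3], errs[1] / 4)
})

test_that("nonpositive coefficients are rejected", {
  dom <- discretize_scene(box_scene(5), 1)
  expect_error(assemble_diffusion_operator(dom, -1), "positive")
})
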