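test_that("umbrella electrode geometry honours the nominal diameter", {
  el <- build_leveen_electrode(30, 10)
  expect_equal(electrode_radial_extent(el), 15, tolerance = 1e-10)
  expect_length(el$tine_paths, 10L)
  # every tine starts at the tip
  for (p in el$tine_paths)
    expect_equal(unname(p[1, ]), c(0, 0, 0), tolerance = 1e-12)

  # partial deployment scales the radial extent linearly
  half <- build_leveen_electrode(30, 10, deployed_fraction = 0.5)
  expect_equal(electrode_radial_extent(half), 7.5, tolerance = 1e-10)
  # tines shorten consistently: every tine has the same arc length
  lens <- vapply(half$tine_paths, function(p)
    sum(sqrt(rowSums(diff(p)^2))), numeric(1))
  expect_lt(diff(range(lens)), 1e-9)

  el40 <- build_leveen_electrode(40, 12)
  expect_equal(electrode_radial_extent(el40), 20, tolerance = 1e-10)

  expect_error(build_leveen_electrode(50, 10), "nominal_diameter")
  expect_error(build_leveen_electrode(30, 10, deployed_fraction = 0),
               "deployed_fraction")
  expect_error(build_leveen_electrode(30, 2), "n_tines")
})

test_that("rigid transforms compose, invert and reject reflections", {
  R1 <- rotation_about_axis(c(1, 2, 3), 0.7)
  tr <- rigid_transform(R1, c(4, -2, 1))
  inv <- invert_rigid(tr)
  id <- compose_rigid(inv, tr)
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)

  p <- matrix(rnorm(30), 10)
  expect_equal(apply_rigid(inv, apply_rigid(tr, p)), p, tolerance = 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("electrode pose recovery round-trips a known transform", {
  ideal <- build_leveen_electrode(30, 10)
  expect_equal(pose_from_electrode(ideal, ideal)$rotation, diag(3),
               tolerance = 1e-9)

  tr <- rigid_transform(rotation_about_axis(c(0, 0, 1), pi / 6),
                        c(10, 0, 0))
  measured <- transform_electrode(ideal, tr)
  got <- pose_from_electrode(measured, ideal)
  expect_equal(got$rotation, tr$rotation, tolerance = 1e-9)
  expect_equal(got$translation, tr$translation, tolerance = 1e-9)
  expect_lt(attr(got, "rms_residual"), 1e-9)

  # property: random rigid transforms are recovered exactly
  set.seed(42)
  for (i in 1:5) {
    tri <- rigid_transform(rotation_about_axis(rnorm(3), runif(1, 0, pi)),
                           rnorm(3, sd = 20))
    gi <- pose_from_electrode(transform_electrode(ideal, tri), ideal)
    expect_equal(gi$rotation, tri$rotation, tolerance = 1e-8)
    expect_equal(gi$translation, tri$translation, tolerance = 1e-8)
  }
})

test_that("pose recovery tolerates measurement noise and flags degeneracy", {
  ideal <- build_leveen_electrode(30, 10)
  tr <- rigid_transform(rotation_about_axis(c(1, 1, 0), 0.3), c(5, 5, 40))
  measured <- transform_electrode(ideal, tr)
  set.seed(7)
  measured$tine_paths <- lapply(measured$tine_paths, function(p)
    p + matrix(rnorm(length(p), sd = 1), nrow(p)))
  got <- pose_from_electrode(measured, ideal)
  expect_lt(sqrt(sum((got$translation - tr$translation)^2)), 1)

  expect_error(rfasim:::fit_rigid(cbind(1:5, 0, 0), cbind(2:6, 0, 0)),
               "degenerate")
})

test_that("phantom scene places vessel channels per the bench layout", {
  ph <- phantom_spec()
  el <- build_leveen_electrode(40, 10)
  sc <- build_phantom_scene(ph, el, vessel_offset = 25)
  v <- sc$vessels[[1]]
  expect_equal(v$centerline[1, 1], 25)
  expect_equal(v$diameter, 5)
  expect_equal(v$flow_speed, 105)  # 10.5 cm/s
  # wall-offset convention: centerline moves out by a lumen radius
  sc35w <- build_phantom_scene(ph, el, vessel_offset = 35,
                               offset_to_wall = TRUE)
  expect_equal(sc35w$vessels[[1]]$centerline[1, 1], 37.5)

  sc0 <- build_phantom_scene(ph, el)
  expect_length(sc0$vessels, 0L)
  expect_error(build_phantom_scene(ph, el, vessel_offset = 64),
               "fit inside")
})

test_that("every query point maps to exactly one material class", {
  sc <- build_phantom_scene(phantom_spec(), build_leveen_electrode(40, 10),
                            vessel_offset = 25)
  set.seed(3)
  pts <- cbind(runif(500, -80, 80), runif(500, -80, 80),
               runif(500, -20, 160))
  m <- scene_material(sc, pts)
  expect_true(all(m %in% c("outside", "tissue", "lumen", "electrode",
                           "shaft")))
  expect_length(m, 500L)
  # vessel center is lumen; a point far outside the beaker is outside
  expect_equal(scene_material(sc, rbind(c(25, 0, 50))), "lumen")
  expect_equal(scene_material(sc, rbind(c(100, 0, 50))), "outside")
  expect_equal(scene_material(sc, rbind(c(40, 40, 20))), "tissue")
})
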