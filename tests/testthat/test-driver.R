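small_cfg <- function(scene, duration = 30, res = 4, dt = 1) {
  run_config(scene, resolution = res, dt = dt, duration_s = duration)
}

test_that("zero-power traces leave the phantom cold and unablated", {
  fx <- make_phantom_fixture()
  tr <- power_trace(0:30, rep(0, 31))
  sim <- simulate_ablation(small_cfg(fx$scene), tr)
  expect_true(sim$ablation$empty)
  expect_equal(sim$ablation$volume, 0)
  expect_lt(max(abs(sim$thermal$temperature - 20)), 1e-9)
  expect_equal(max(sim$series$matched_W), 0)
})

test_that("a short phantom burn is deterministic end to end", {
  fx <- make_phantom_fixture(seed = 6)
  tr <- make_power_trace(duration_s = 60, plateau_power = 70, ramp_s = 15,
                         seed = 6)
  cfg <- small_cfg(fx$scene, duration = 60)
  s1 <- simulate_ablation(cfg, tr)
  s2 <- simulate_ablation(cfg, tr)
  expect_identical(s1$damage, s2$damage)
  expect_identical(s1$thermal$temperature, s2$thermal$temperature)
  expect_identical(s1$ablation$mesh, s2$ablation$mesh)
  expect_identical(s1$series$matched_W, s2$series$matched_W)
  expect_identical(s1$manifest$config_fingerprint,
                   s2$manifest$config_fingerprint)

  # power matching: per-step integrated power equals the trace exactly
  expect_lt(max(abs(s1$series$matched_W - s1$series$recorded_W) /
                  pmax(s1$series$recorded_W, 1e-12)), 1e-6)
})

test_that("a full-length phantom burn heats and ablates around the tines", {
  fx <- make_phantom_fixture(seed = 6)
  cfg <- run_config(fx$scene, resolution = 2.5, dt = 1)
  sim <- simulate_ablation(cfg, fx$trace)
  expect_gt(max(sim$thermal$temperature), 50)
  expect_false(sim$ablation$empty)
  expect_gt(sim$ablation$volume, 1e3)   # > 1 cm^3
  # the ablation shell sits around the tine array, inside the beaker
  v <- sim$ablation$mesh$vertices
  expect_lt(max(abs(v[, 1])), 40)
  expect_gt(min(v[, 3]), 40)
  expect_lt(max(v[, 3]), 100)
})

test_that("validation workflow reports exact distances on known pairs", {
  model <- icosphere(4, radius = 20)
  truth <- icosphere(4, radius = 22)   # a 2 mm dilation
  out <- validate_run(model, truth, n_points = 400, seed = 5)
  expect_equal(out$model_report$mean_error, 2, tolerance = 0.02)
  expect_equal(out$model_report$max_error, 2, tolerance = 0.03)

  # identical surfaces: essentially zero error
  same <- validate_run(model, model, n_points = 300, seed = 5)
  expect_lt(same$model_report$mean_error, 1e-6)

  # with a chart comparator, two reports and a paired test downstream
  chart <- build_chart_model(30)
  both <- validate_run(model, truth, chart = chart, n_points = 300)
  expect_s3_class(both$chart_report, "error_report")
  expect_gt(both$chart_report$mean_error, both$model_report$mean_error)
})

test_that("config validation catches bad inputs", {
  fx <- make_phantom_fixture()
  expect_error(run_config(fx$scene, resolution = -1), "config error")
  expect_error(run_config(fx$scene, dt = 0), "config error")
  cst <- default_constants(); cst$thermal <- NULL
  expect_error(run_config(fx$scene, constants = cst), "constants block")
  cfg <- small_cfg(fx$scene, duration = 100)
  expect_error(simulate_ablation(cfg, power_trace(0:30, rep(10, 31))),
               "cover")
})

test_that("scene configs round-trip through YAML", {
  fx <- make_phantom_fixture(vessel_offset = 30)
  f <- tempfile(fileext = ".yaml")
  write_scene_yaml(fx$scene, f)
  back <- read_scene_yaml(f)
  expect_equal(back$medium, fx$scene$medium)
  expect_equal(back$vessels[[1]]$diameter, 5)
  expect_equal(back$vessels[[1]]$centerline, fx$scene$vessels[[1]]$centerline)
  expect_equal(back$electrode$tine_paths, fx$scene$electrode$tine_paths,
               tolerance = 1e-12)
})

test_that("simulation artifacts export to standard formats", {
  fx <- make_phantom_fixture()
  tr <- make_power_trace(duration_s = 40, plateau_power = 70, seed = 2)
  sim <- simulate_ablation(small_cfg(fx$scene, duration = 40), tr)
  fply <- tempfile(fileext = ".ply")
  write_ply(sim$ablation$mesh, fply)
  expect_gt(file.size(fply), 100)
  expect_match(readLines(fply, n = 1), "ply")
  fvtk <- tempfile(fileext = ".vtk")
  write_vtk_domain(sim$domain, fvtk, field = sim$damage,
                   field_name = "omega")
  expect_match(readLines(fvtk, n = 4)[4], "STRUCTURED_POINTS")
})

test_that("batch validation pairs simulation and chart errors per case", {
  set.seed(21)
  chart <- build_chart_model(30)
  models <- lapply(1:4, function(i) icosphere(3, radius = 14 + i / 4))
  truths <- lapply(1:4, function(i)
    icosphere(3, radius = 15 + i / 4 + 0.2 * rnorm(1)))
  out <- validate_batch(models, truths, chart, n_points = 300)
  expect_equal(nrow(out$summary), 4L)
  expect_true(all(c("mean_error", "max_error") %in% names(out$paired)))
  expect_true(is.finite(out$paired$max_error$p_value))
  # the sphere models hug their truths tighter than the ellipsoid chart
  expect_true(all(out$summary$model_mean < out$summary$chart_mean))
})

test_that("label masks triangulate into closed measurable surfaces", {
  sc <- make_analytic_scene("perfused_box", list(side = 30))$scene
  dom <- discretize_scene(sc, 0.75)
  co <- domain_coords(dom)
  mask <- array(as.numeric(rowSums(sweep(co, 2, c(15, 15, 15))^2) < 100),
                dom$dims)
  m <- mask_to_surface(mask, spacing = dom$spacing, origin = dom$origin)
  expect_true(mesh_is_closed(m))
  expect_equal(mesh_volume(m), 4 / 3 * pi * 1000, tolerance = 0.02)
  expect_error(mask_to_surface(mask * 0, spacing = 1), "no region")
})
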