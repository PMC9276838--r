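test_that("fixtures are bit-identical under a fixed seed", {
  expect_identical(make_power_trace(seed = 5), make_power_trace(seed = 5))
  el <- build_leveen_electrode(30, 8)
  expect_identical(make_tine_ct(el, seed = 2)$volume,
                   make_tine_ct(el, seed = 2)$volume)
  fx1 <- make_phantom_fixture(vessel_offset = 25, seed = 3)
  fx2 <- make_phantom_fixture(vessel_offset = 25, seed = 3)
  expect_identical(fx1$trace, fx2$trace)
})

test_that("phantom fixtures mirror the bench layout", {
  fx <- make_phantom_fixture(vessel_offset = 25)
  expect_length(fx$scene$vessels, 1L)
  expect_equal(fx$scene$vessels[[1]]$flow_speed, 105)
  expect_equal(fx$scene$vessels[[1]]$diameter, 5)
  expect_equal(fx$electrode$nominal_diameter, 40)
  expect_equal(length(fx$trace$time_s), 301L)  # 1 Hz over 5 minutes

  fx0 <- make_phantom_fixture()
  expect_length(fx0$scene$vessels, 0L)
})

test_that("unknown analytic scene kinds are rejected", {
  expect_error(make_analytic_scene("vortex"), "unknown")
})

test_that("power traces ramp to a plateau and optionally roll off", {
  tr <- make_power_trace(duration_s = 300, start_power = 20,
                         plateau_power = 80, ramp_s = 60, noise_sd = 0,
                         seed = 1)
  expect_equal(tr$power_W[1], 20)
  expect_equal(tr$power_W[301], 80)
  expect_true(all(diff(tr$power_W[1:61]) > 0))
  expect_lt(diff(range(tr$power_W[62:281])), 1e-9)

  ro <- make_power_trace(duration_s = 300, rolloff = TRUE, noise_sd = 0)
  expect_equal(tail(ro$power_W, 10), rep(8, 10))
})

test_that("tine CT fixtures paint recoverable centerlines", {
  el <- build_leveen_electrode(30, 10)
  ct <- make_tine_ct(el, voxel_mm = 0.5, seed = 1)
  det <- detect_tines(ct, tip_seed = c(0, 0, 0), expected_tines = 10,
                      ideal = el)
  expect_equal(det$n_detected, 10L)
  # each detected centerline within one voxel of a painted truth curve
  mean_d <- vapply(det$tines, function(p) {
    best <- Inf
    for (tp in ct$truth) best <- min(best, mean(dist_to_polyline(p, tp)))
    best
  }, numeric(1))
  expect_lt(max(mean_d), ct$spacing)
  expect_lt(max(det$deflections_mm), 2 * ct$spacing)
})

test_that("a 5 mm deflected tine is detected with its deflection", {
  el <- build_leveen_electrode(30, 10)
  defl <- c(5, rep(0, 9))
  ct <- make_tine_ct(el, deflections = defl, voxel_mm = 0.5, seed = 2)
  det <- detect_tines(ct, tip_seed = c(0, 0, 0), expected_tines = 10,
                      ideal = el)
  expect_equal(det$n_detected, 10L)
  expect_equal(max(det$deflections_mm), 5, tolerance = 0.2)
  # truth reflects the deflection exactly: tip of tine 1 moved by 5 mm
  ideal_tip <- el$tine_paths[[1]][nrow(el$tine_paths[[1]]), ]
  defl_tip <- ct$truth[[1]][nrow(ct$truth[[1]]), ]
  expect_equal(sqrt(sum((defl_tip - ideal_tip)^2)), 5, tolerance = 1e-9)
})

test_that("volumes without metal voxels are a detection error", {
  el <- build_leveen_electrode(30, 8)
  ct <- make_tine_ct(el, voxel_mm = 0.5, seed = 1)
  ct$volume[] <- 50
  expect_error(detect_tines(ct, c(0, 0, 0)), "detection error")
})

test_that("tine CT volumes round-trip through NIfTI", {
  el <- build_leveen_electrode(30, 8)
  ct <- make_tine_ct(el, voxel_mm = 1, seed = 4)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(ct, f)
  back <- read_volume(f, origin = ct$origin)
  expect_equal(back$spacing, 1)
  expect_equal(back$volume, ct$volume, tolerance = 1e-6)
})

test_that("deflections that leave the volume are rejected", {
  el <- build_leveen_electrode(30, 8)
  expect_error(make_tine_ct(el, deflections = c(50, rep(0, 7))),
               "outside")
})
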