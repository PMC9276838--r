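test_that("concentric-sphere potential matches the closed form", {
  fx <- make_analytic_scene("concentric_spheres")
  dom <- discretize_scene(fx$scene, 1)
  V <- solve_potential(dom, fx$truth$sigma, 10, tol = 1e-6)
  op <- attr(V, "operator")
  co <- domain_coords(dom)
  r <- sqrt(rowSums(co^2))
  # mid-shell comparison: inside r < 5 the 1 mm grid barely resolves
  # the 1/r singularity, and near the ground the reference tends to 0.
  # With a grid-scale electrode (a = h) the calibrated solver carries a
  # few-percent uniform current deficit at this spacing; the profile
  # tightens to ~2% at half the spacing (asserted with the convergence
  # checks in the acceptance suite).
  sel <- op$unknown & r > 5 & r < 30
  rel <- abs(V[sel] - fx$truth$potential(r[sel], 10)) /
    fx$truth$potential(r[sel], 10)
  expect_lt(mean(rel), 0.05)

  # discrete maximum principle: potential within [0, V0]
  expect_gte(min(V), -1e-9)
  expect_lte(max(V), 10 + 1e-9)

  # zero applied potential -> identically zero field
  V0 <- solve_potential(dom, fx$truth$sigma, 0, op = op)
  expect_equal(max(abs(V0)), 0)
})

test_that("potential is invariant and impedance inversely proportional under uniform sigma scaling", {
  fx <- make_analytic_scene("concentric_spheres",
                            list(a = 2, b = 20, sigma = 0.333))
  dom <- discretize_scene(fx$scene, 1)
  V1 <- solve_potential(dom, 0.333, 5, tol = 1e-10)
  V2 <- solve_potential(dom, 0.666, 5, tol = 1e-10)
  expect_equal(as.numeric(V1), as.numeric(V2), tolerance = 1e-6)
  z1 <- power_density(V1)$effective_impedance
  z2 <- power_density(V2)$effective_impedance
  expect_equal(z1 / z2, 2, tolerance = 1e-6)
})

test_that("power density integrates exactly to the total power", {
  fx <- make_analytic_scene("concentric_spheres",
                            list(a = 2, b = 20, sigma = 0.333))
  dom <- discretize_scene(fx$scene, 1)
  es <- power_density(solve_potential(dom, 0.333, 10))
  vol <- (dom$spacing * 1e-3)^3
  expect_equal(sum(es$power_density) * vol, es$total_power,
               tolerance = 1e-12)
  expect_true(all(es$power_density >= 0))
})

test_that("power rescaling is exact and linear", {
  fx <- make_analytic_scene("concentric_spheres",
                            list(a = 2, b = 20, sigma = 0.333))
  dom <- discretize_scene(fx$scene, 1.5)
  es <- power_density(solve_potential(dom, 0.333, 1))
  s50 <- scale_to_recorded_power(es, 50)
  expect_equal(s50$total_power, 50, tolerance = 1e-12)
  expect_equal(s50$power_density, es$power_density * 50 / es$total_power,
               tolerance = 1e-12)
  expect_equal(s50$effective_impedance, es$effective_impedance,
               tolerance = 1e-9)
  vol <- (dom$spacing * 1e-3)^3
  s30 <- scale_to_recorded_power(es, 30)
  expect_equal(sum(s30$power_density) * vol, 30, tolerance = 1e-9)

  s0 <- scale_to_recorded_power(es, 0)
  expect_equal(s0$total_power, 0)
  expect_equal(max(abs(s0$power_density)), 0)
  expect_error(scale_to_recorded_power(s0, 10), "zero")
})

test_that("power logs round-trip and reject malformed input", {
  tr <- make_power_trace(duration_s = 299, seed = 4)
  expect_length(tr$time_s, 300L)
  expect_equal(diff(range(tr$time_s)), 299)
  f <- tempfile(fileext = ".csv")
  write_power_log(tr, f)
  tr2 <- read_power_log(f)
  expect_identical(tr2$time_s, tr$time_s)
  expect_identical(tr2$power_W, tr$power_W)
  expect_identical(tr2$impedance_ohm, tr$impedance_ohm)

  bad <- data.frame(time_s = c(0, 1, 1, 2), power_W = 10)
  fb <- tempfile(fileext = ".csv")
  write.csv(bad, fb, row.names = FALSE)
  expect_error(read_power_log(fb), "row 3")

  bad2 <- data.frame(time_s = 0:2, power_W = c(5, -1, 5))
  write.csv(bad2, fb, row.names = FALSE)
  expect_error(read_power_log(fb), "row 2")

  writeLines("time_s,power_W", fb)
  expect_error(read_power_log(fb), "empty")

  bad3 <- data.frame(t = 0:2, watts = 1)
  write.csv(bad3, fb, row.names = FALSE)
  expect_error(read_power_log(fb), "columns")
})

test_that("zero-order hold resamples the trace correctly", {
  tr <- power_trace(0:5, c(10, 20, 30, 40, 50, 60))
  expect_equal(resample_power(tr, c(0, 0.4, 0.99, 1, 2.5, 5)),
               c(10, 10, 10, 20, 30, 60))
})
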