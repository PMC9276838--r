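test_that("uniform insulated field is a steady state", {
  fx <- make_analytic_scene("perfused_box", list(side = 8))
  dom <- discretize_scene(fx$scene, 1)
  cst <- default_constants("phantom")   # no perfusion
  st <- init_thermal_state(dom, cst)
  for (i in 1:3)
    st <- step_temperature(dom, st, numeric(prod(dom$dims)), cst, dt = 1)
  expect_lt(max(abs(st$temperature - cst$thermal$initial_temperature)),
            1e-9)
})

test_that("perfused-medium relaxation matches the scalar ODE closed form", {
  fx <- make_analytic_scene("perfused_box", list(side = 6, T0 = 37))
  dom <- discretize_scene(fx$scene, 1)
  cst <- default_constants("liver")
  cst$thermal$evaporation <- FALSE
  th <- cst$thermal
  tau <- fx$truth$tau(cst)
  q_vol <- 2e4                                # W/m^3, uniform
  q <- rep(q_vol * (dom$spacing * 1e-3)^3, prod(dom$dims))
  st <- init_thermal_state(dom, cst)
  dt <- tau / 200
  sys <- NULL
  n_steps <- ceiling(5 * tau / dt)
  for (i in seq_len(n_steps)) {
    st <- step_temperature(dom, st, q, cst, dt = dt, system = sys)
    sys <- attr(st, "system")
  }
  Texp <- fx$truth$relaxation(st$time, q_vol, cst)
  Tgot <- mean(st$temperature[sys$unknown])
  expect_equal(Tgot, Texp, tolerance = 0.01)
  # spatially uniform (insulated, uniform source)
  expect_lt(diff(range(st$temperature[sys$unknown])), 1e-6)
  # asymptote: T_art + q / (w rho_b c_b)
  Tinf <- th$arterial_temperature +
    q_vol / (th$perfusion_rate * th$rho_blood * th$c_blood)
  expect_equal(Tgot, Tinf, tolerance = 0.01)
})

test_that("vessel heat-transfer correlation reproduces the laminar regime", {
  v <- vessel_spec(matrix(0, 2, 3), diameter = 5, flow_speed = 105)
  ht <- vessel_heat_transfer(v)
  expect_equal(ht$reynolds, 0.105 * 0.005 / 1e-6, tolerance = 1e-12)
  expect_lt(ht$reynolds, 2300)              # laminar
  expect_equal(ht$nusselt, 3.66)
  expect_equal(ht$h, 3.66 * 0.6 / 0.005, tolerance = 1e-12)

  v0 <- vessel_spec(matrix(0, 2, 3), flow_speed = 0)
  expect_equal(vessel_heat_transfer(v0)$h, 0)
})

test_that("vessel heat sink cools every point versus the no-vessel run", {
  el <- build_leveen_electrode(40, 10)
  sc_v <- build_phantom_scene(phantom_spec(), el, vessel_offset = 25)
  sc_0 <- build_phantom_scene(phantom_spec(), el)
  tr <- make_power_trace(duration_s = 40, plateau_power = 60, ramp_s = 10,
                         noise_sd = 0, seed = 1)
  run <- function(sc) {
    cfg <- run_config(sc, resolution = 4, dt = 1, duration_s = 40)
    simulate_ablation(cfg, tr)
  }
  sv <- run(sc_v); s0 <- run(sc_0)
  # compare on the cells active in both runs (lumen removed in sv)
  both <- attr(sv$thermal, "system")$unknown &
    attr(s0$thermal, "system")$unknown
  expect_true(all(sv$thermal$temperature[both] <=
                    s0$thermal$temperature[both] + 1e-6))
  # and strictly cooler near the vessel wall
  wall <- sv$domain$labels$vessel_wall
  expect_gt(mean(s0$thermal$temperature[wall] -
                   sv$thermal$temperature[wall]), 0.05)
})

test_that("evaporation produces a latent plateau with closed energy books", {
  fx <- make_analytic_scene("perfused_box", list(side = 5, T0 = 95))
  dom <- discretize_scene(fx$scene, 1)
  cst <- default_constants("phantom")
  cst$thermal$initial_temperature <- 95
  N <- prod(dom$dims)
  vol <- (dom$spacing * 1e-3)^3
  q_vol <- 5e6
  q <- rep(q_vol * vol, N)   # sustained uniform heating
  st <- init_thermal_state(dom, cst)
  sys <- NULL
  hist <- numeric(0)
  for (i in 1:520) {
    st <- step_temperature(dom, st, q, cst, dt = 1, system = sys)
    sys <- attr(st, "system")
    hist <- c(hist, max(st$temperature[sys$unknown]))
  }
  band <- cst$thermal$evaporation_band
  # time spent inside the band ~ (latent + sensible band energy) / power
  t_in_band <- sum(hist >= band[1] & hist < band[2])
  t_expected <- cst$thermal$rho * cst$thermal$water_fraction *
    cst$thermal$latent_heat / q_vol +
    cst$thermal$rho * cst$thermal$c * diff(band) / q_vol
  expect_equal(t_in_band, t_expected, tolerance = 0.05)
  # energy books: input = stored (insulated, below clamp -> no venting)
  expect_equal(st$energy_in, st$energy_stored + st$energy_out,
               tolerance = 1e-6)
  # stored splits into sensible + latent consistently
  sensible <- sum(cst$thermal$rho * cst$thermal$c *
                    (st$temperature[sys$unknown] - 95)) * vol
  latent <- st$energy_stored - sensible
  n_act <- sum(sys$unknown)
  latent_expected <- cst$thermal$rho * cst$thermal$water_fraction *
    cst$thermal$latent_heat * vol * n_act   # whole block crossed the band
  expect_equal(latent, latent_expected, tolerance = 0.01)

  # heating that never reaches the band: evaporation on/off identical
  cst2 <- cst; cst2$thermal$initial_temperature <- 20
  q2 <- rep(1e5 * vol, N)
  run <- function(evap) {
    c3 <- cst2; c3$thermal$evaporation <- evap
    s <- init_thermal_state(dom, c3)
    for (i in 1:20) s <- step_temperature(dom, s, q2, c3, dt = 1)
    s$temperature
  }
  expect_identical(run(TRUE), run(FALSE))
})

test_that("the ceiling clamp bounds temperature above the band", {
  fx <- make_analytic_scene("perfused_box", list(side = 4, T0 = 103))
  dom <- discretize_scene(fx$scene, 1)
  cst <- default_constants("phantom")
  cst$thermal$initial_temperature <- 103
  vol <- (dom$spacing * 1e-3)^3
  q <- rep(5e6 * vol, prod(dom$dims))
  st <- init_thermal_state(dom, cst)
  for (i in 1:200) {
    st <- step_temperature(dom, st, q, cst, dt = 1,
                           system = attr(st, "system"))
  }
  clamp <- cst$thermal$evaporation_band[2] + cst$thermal$clamp_offset
  expect_lte(max(st$temperature), clamp + 1e-9)
  expect_gt(st$energy_out, 0)   # vented energy is booked
  expect_equal(st$energy_in, st$energy_stored + st$energy_out,
               tolerance = 1e-6)
})

test_that("time refinement changes the solution at first order only", {
  fx <- make_analytic_scene("perfused_box", list(side = 6))
  dom <- discretize_scene(fx$scene, 1)
  cst <- default_constants("liver")
  vol <- (dom$spacing * 1e-3)^3
  co <- domain_coords(dom)
  q <- 5e5 * vol * exp(-rowSums(sweep(co, 2, c(3, 3, 3))^2) / 4)
  final_T <- function(dt) {
    st <- init_thermal_state(dom, cst)
    for (i in seq_len(round(30 / dt)))
      st <- step_temperature(dom, st, q, cst, dt = dt,
                             system = attr(st, "system"))
    st$temperature
  }
  T1 <- final_T(1); T05 <- final_T(0.5); T025 <- final_T(0.25)
  e1 <- max(abs(T1 - T025)); e05 <- max(abs(T05 - T025))
  expect_lt(e05, e1)            # no oscillation/blow-up, first order
  expect_gt(max(T1) - cst$thermal$initial_temperature, 1)
})
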