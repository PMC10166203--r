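test_that("initial state is uniform and at rest", {
  m <- quiet_mesh(nr = 8, nz = 16)
  cfg <- solver_config(m, initial_temperature = 341.15)
  st <- initialize_state(cfg)
  expect_true(all(st$T == 341.15))
  expect_equal(volume_mean(m, st$T), 341.15)
  expect_true(all(st$ur == 0) && all(st$uz == 0))
  expect_error(solver_config(m, initial_temperature = 200), "valid range")
})

test_that("a uniform state at the wall temperature is a fixed point", {
  m <- quiet_mesh(nr = 8, nz = 16)
  cfg <- solver_config(m, dt = 2, mode = "convection",
                       initial_temperature = 394.15)
  s <- constant_retort(394.15, 100)
  st <- run_steps(initialize_state(cfg), s, cfg, 5)
  expect_equal(max(abs(st$T - 394.15)), 0, tolerance = 1e-9)
  expect_equal(peak_speed(st), 0, tolerance = 1e-12)
})

test_that("zero gravity leaves the fluid at rest in convection mode", {
  m <- quiet_mesh(nr = 8, nz = 16)
  cfg <- solver_config(m, dt = 2, mode = "convection", gravity = 0)
  s <- constant_retort(394.15, 100)
  st <- run_steps(initialize_state(cfg), s, cfg, 5)
  expect_equal(peak_speed(st), 0, tolerance = 1e-12)
  expect_gt(max(st$T), 341.15)   # heat still enters by conduction
})

test_that("conduction mode matches the Fourier-Bessel series at Fo = 0.1", {
  props <- const_props()
  alpha <- 0.58 / (1070 * 3860)
  R <- 0.04945; H <- 0.121
  m <- solid_mesh(nr = 48, nz = 96)
  tF <- 0.1 * R^2 / alpha
  cfg <- solver_config(m, properties = props, dt = 2, mode = "conduction",
                       initial_temperature = 341.15)
  s <- constant_retort(394.15, ceiling(tF) + 10)
  st <- initialize_state(cfg)
  while (st$time < tF - 1e-9) st <- advance(st, s, cfg)
  pts <- expand.grid(i = c(1, 12, 24, 40), j = c(10, 24, 48, 80))
  Tnum <- st$T[cbind(pts$i, pts$j)]
  Tana <- analytic_cylinder_temperature(m$r_centers[pts$i], m$z_centers[pts$j],
                                        tF, alpha, 394.15, 341.15, R, H,
                                        n_terms = 60)
  expect_lt(max(abs(Tnum - Tana)) / (394.15 - 341.15), 0.01)
})

test_that("analytic series honours its initial and steady limits", {
  alpha <- 1.4e-7; R <- 0.05; H <- 0.12
  T0 <- analytic_cylinder_temperature(0.02, 0.06, 0, alpha, 394, 341, R, H,
                                      n_terms = 400)
  expect_equal(T0, 341, tolerance = 0.02 * (394 - 341))
  Tinf <- analytic_cylinder_temperature(0.02, 0.06, 5e5, alpha, 394, 341, R, H)
  expect_equal(Tinf, 394, tolerance = 1e-6)
  expect_error(analytic_cylinder_temperature(0.02, 0.06, -1, alpha, 394, 341, R, H),
               ">= 0")
  expect_error(analytic_cylinder_temperature(0.06, 0.06, 10, alpha, 394, 341, R, H),
               "outside")
})

test_that("insulated conduction conserves thermal energy to round-off", {
  props <- const_props()
  m <- solid_mesh(nr = 10, nz = 20)
  cfg <- solver_config(m, properties = props, dt = 5, mode = "conduction",
                       wall_bc = "adiabatic", initial_temperature = 341.15)
  st <- initialize_state(cfg)
  # non-uniform start so conduction actually redistributes heat
  st$T <- st$T + outer(seq(0, 5, length.out = m$nr), seq(0, 3, length.out = m$nz), "+")
  s <- constant_retort(341.15, 1e5)
  E0 <- volume_mean(m, st$T)
  st <- run_steps(st, s, cfg, 1000)
  expect_lt(abs(volume_mean(m, st$T) - E0) / E0, 1e-3)
  expect_lt(abs(volume_mean(m, st$T) - E0) / E0, 1e-10)  # implicit FV is exact
})

test_that("conduction field stays symmetric about the axial midplane", {
  props <- const_props()
  m <- solid_mesh(nr = 10, nz = 20)
  cfg <- solver_config(m, properties = props, dt = 5, mode = "conduction")
  st <- run_steps(initialize_state(cfg), constant_retort(394.15, 1e4), cfg, 60)
  expect_equal(st$T, st$T[, m$nz:1], tolerance = 1e-9)
})

test_that("heating drives a bounded, divergence-free buoyant flow", {
  m <- quiet_mesh(nr = 16, nz = 32)
  cfg <- solver_config(m, dt = 2, mode = "convection")
  s <- parse_schedule("5-20-5/121")
  res <- simulate_can(cfg, s, probes = list(c(0, 0.0188)))
  expect_lt(res$final_state$div_rms, 1e-6)
  # discrete maximum principle over the whole run
  allT <- range(vapply(res$snapshots, function(x) range(x$T), numeric(2)))
  expect_gte(allT[1], min(341.15, s$cooling_water) - 0.5)
  expect_lte(allT[2], 394.15 + 0.5)
  # during heating the instantaneous coldest puree point sits in the lower
  # half, on-axis or moderately off-axis (it wanders while the flow develops)
  mid_heat <- res$snapshots[[which.min(abs(res$snapshot_times - 900))]]
  Tp <- mid_heat$T[, seq_len(m$n_puree_rows)]
  idx <- which(Tp == min(Tp), arr.ind = TRUE)[1, ]
  expect_lt(m$z_centers[idx[2]], 0.5 * (m$n_puree_rows * m$dz))
  expect_lt(m$r_centers[idx[1]], 0.75 * m$geometry$inner_radius)
  # at cooling onset the near-wall fluid cools before the interior
  t_cool <- 5 * 60 + 20 * 60   # cooling starts here
  pre <- res$snapshots[[which.min(abs(res$snapshot_times - (t_cool - 60)))]]
  post <- res$snapshots[[which.min(abs(res$snapshot_times - (t_cool + 120)))]]
  drop_wall <- pre$T[m$nr, 16] - post$T[m$nr, 16]
  drop_core <- pre$T[2, 16] - post$T[2, 16]
  expect_gt(drop_wall, drop_core)
})

test_that("flow weakens through the hold and reverses soon after cooling starts", {
  m <- quiet_mesh(nr = 16, nz = 32)
  cfg <- solver_config(m, dt = 2, mode = "convection")
  s <- parse_schedule("5-30-5/121")
  res <- simulate_can(cfg, s)
  snap_at <- function(t) res$snapshots[[which.min(abs(res$snapshot_times - t))]]
  u_early <- peak_speed(snap_at(10 * 60))   # early hold
  u_late <- peak_speed(snap_at(34 * 60))    # end of hold
  expect_lt(u_late, u_early)
  # vertical velocity near the wall: up while heating, down within 5 min of cooling
  iw <- m$nr - 1L; jm <- 16L
  expect_gt(snap_at(30 * 60)$uz[iw, jm], 0)
  expect_lt(snap_at(35 * 60 + 240)$uz[iw, jm], 0)
})

test_that("a cool-hold schedule caps the lethal rate by the maximum principle", {
  m <- quiet_mesh(nr = 8, nz = 16)
  cfg <- solver_config(m, dt = 5, mode = "conduction")
  s <- parse_schedule("5-10-5/60", cooling_water = 298.15)  # holds below T_0
  res <- simulate_can(cfg, s, probes = list(c(0, 0.02)), keep_snapshots = FALSE)
  cap <- 10^((341.15 + 0.5 - 394.25) / 10)   # rate at T_0 (+ bounds tolerance)
  expect_lte(max(res$probes$lethal_rate), cap)
  expect_lte(max(lethal_rate(res$final_state$T)), cap)
})
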