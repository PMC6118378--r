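test_that("grid spec enforces exact extent division", {
  g <- grid_spec(50, 100, 0.25)
  expect_equal(c(g$nx, g$ny), c(200L, 400L))
  expect_error(grid_spec(50, 100, 0.3), "divide")
  expect_error(grid_spec(50, 100, -1))
})

test_that("obstacle rasterisation is a centre-within-radius stamp", {
  g <- grid_spec(20, 30, 1)
  cfg <- wind_config(inflow_speed = 1, dt_wind = 0.1)
  # no penguins: all clear
  expect_false(any(rasterize_obstacles(numeric(0), numeric(0), 0.25, g, cfg)))
  # one penguin exactly at a cell centre with radius = dx: the cell and its
  # 4 edge neighbours (centres at distance dx; diagonals at sqrt(2) dx miss)
  m1 <- rasterize_obstacles(10.5, 20.5, 1, g, cfg)
  expect_equal(sum(m1), 5)
  expect_true(m1[11, 21] && m1[10, 21] && m1[12, 21] && m1[11, 20] &&
              m1[11, 22])
  # brute-force distance check over all cells
  cx <- (seq_len(g$nx) - 0.5) * g$dx
  cy <- (seq_len(g$ny) - 0.5) * g$dx
  want <- outer(cx, cy, function(a, b) sqrt((a - 10.5)^2 + (b - 20.5)^2)) <= 1
  expect_identical(m1, want)
  # two distant penguins: mask is the union of the single stamps
  m2 <- rasterize_obstacles(c(5, 15), c(10, 25), 0.6, g, cfg)
  ma <- rasterize_obstacles(5, 10, 0.6, g, cfg)
  mb <- rasterize_obstacles(15, 25, 0.6, g, cfg)
  expect_identical(m2, ma | mb)
  expect_error(rasterize_obstacles(25, 10, 0.5, g, cfg), "agent 1")
})

test_that("momentum predictor: uniform flow is invariant, shear diffuses viscously", {
  g <- grid_spec(10, 16, 1)
  cfg <- wind_config(inflow_speed = 2, dt_wind = 0.1, nu = 0.05)
  st <- flow_state(g, cfg)
  pred <- momentum_predictor(st, cfg)
  expect_equal(pred$u, st$u, tolerance = 1e-14)
  expect_equal(pred$v, st$v, tolerance = 1e-14)
  # cross-stream shear v(x), u = 0: advection vanishes, interior change is
  # nu * v_xx * dt
  prof <- 2 + sin(seq_len(g$nx) * 0.6)
  st$v <- matrix(prof, g$nx, g$ny + 1)
  pred <- momentum_predictor(st, cfg)
  vxx <- (prof[1:8] - 2 * prof[2:9] + prof[3:10])   # dx = 1
  dv <- pred$v[2:9, 5] - prof[2:9]
  expect_equal(dv, cfg$nu * cfg$dt_wind * vxx, tolerance = 1e-12)
  # CFL guard
  st$v <- matrix(50, g$nx, g$ny + 1)
  expect_error(momentum_predictor(st, cfg), "CFL")
})

test_that("momentum predictor matches an independent loop implementation on an 8x8 grid", {
  g <- grid_spec(8, 8, 1)
  cfg <- wind_config(inflow_speed = 1, dt_wind = 0.05, nu = 0.02)
  st <- flow_state(g, cfg)
  set.seed(31)
  st$u <- matrix(runif(9 * 8, -1, 1), 9, 8)
  st$u[1, ] <- 0; st$u[9, ] <- 0
  st$v <- matrix(runif(8 * 9, 0, 2), 8, 9)
  st$mask[4, 5] <- TRUE
  st$u[4:5, 5] <- 0; st$v[4, 5:6] <- 0
  pred <- momentum_predictor(st, cfg)
  want <- oracle_predictor(st$u, st$v, st$mask, cfg$dt_wind, g$dx, cfg$nu,
                           cfg$inflow_speed)
  expect_equal(pred$u, want$u, tolerance = 1e-12)
  expect_equal(pred$v, want$v, tolerance = 1e-12)
})

test_that("Poisson solver: constant solution, fixed point, and O(dx^2) convergence", {
  # divergence-free rhs = 0: pressure constant at the pinned reference
  g <- grid_spec(10, 20, 1)
  sol0 <- solve_poisson(matrix(0, 10, 20), matrix(FALSE, 10, 20), 1,
                        tol = 1e-10)
  expect_lt(max(abs(sol0$p)), 1e-9)
  expect_true(sol0$converged)

  # manufactured solution compatible with the discrete boundary conditions:
  # p = cos(pi y / (2 Lt)) with the zero at the outflow ghost centre
  err_for <- function(dx) {
    Lx <- 8; Ly <- 16
    nx <- Lx / dx; ny <- Ly / dx
    Lt <- Ly + dx / 2
    yc <- (seq_len(ny) - 0.5) * dx
    pex <- matrix(cos(pi * yc / (2 * Lt)), nx, ny, byrow = TRUE)
    rhs <- -(pi / (2 * Lt))^2 * pex
    sol <- solve_poisson(rhs, matrix(FALSE, nx, ny), dx, tol = 1e-9,
                         max_iter = 50000)
    expect_true(sol$converged)
    max(abs(sol$p - pex))
  }
  e1 <- err_for(1); e2 <- err_for(0.5)
  expect_gt(e1 / e2, 3)   # ~4 for a second-order discretisation
  expect_lt(e1 / e2, 5.5)

  # converged solution is a fixed point under a larger iteration cap
  rhs <- matrix(rnorm(200, sd = 0.01), 10, 20)
  s1 <- solve_poisson(rhs, matrix(FALSE, 10, 20), 1, tol = 1e-9,
                      max_iter = 20000)
  s2 <- solve_poisson(rhs, matrix(FALSE, 10, 20), 1, tol = 1e-9,
                      max_iter = 40000, p0 = s1$p)
  expect_equal(s1$p, s2$p, tolerance = 1e-6)
})

test_that("projection removes divergence and leaves gradient-free fields alone", {
  g <- grid_spec(12, 20, 0.5)
  cfg <- wind_config(inflow_speed = 2, dt_wind = 0.05)
  st <- flow_state(g, cfg)
  # zero pressure gradient: velocity unchanged
  st2 <- project_velocity(st$u, st$v, matrix(0, g$nx, g$ny), st, cfg)
  expect_equal(st2$u, st$u, tolerance = 1e-14)
  expect_equal(st2$v[, 1:g$ny], st$v[, 1:g$ny], tolerance = 1e-14)
  # random smooth intermediate fields: post-projection divergence <= tol
  set.seed(5)
  for (rep in 1:20) {
    st <- flow_state(g, cfg)
    st$u <- st$u + 0.3 * matrix(rnorm((g$nx + 1) * g$ny), g$nx + 1)
    st$u[1, ] <- 0; st$u[g$nx + 1, ] <- 0
    st$v <- st$v + 0.3 * matrix(rnorm(g$nx * (g$ny + 1)), g$nx)
    st$v[, 1] <- cfg$inflow_speed
    sol <- solve_pressure_poisson(st$u, st$v, st, cfg)
    st3 <- project_velocity(st$u, st$v, sol$p, st, cfg)
    expect_lt(oracle_max_div(st3$u, st3$v, st3$mask, g$dx), cfg$ppe_tol)
    expect_lt(st3$max_div, cfg$ppe_tol)
  }
})

test_that("quasi-steady stepping: free stream, sheltering, mass balance, convergence", {
  g <- grid_spec(25, 50, 1)
  cfg <- wind_config(inflow_speed = 5, dt_wind = 0.1,
                     quasi_steady_steps = 30)
  # empty mask: converges to the uniform inflow profile within 1%
  st <- flow_state(g, cfg)
  st <- step_to_quasi_steady(st, cfg)
  sp <- cell_speed(st)
  expect_true(all(abs(sp - cfg$inflow_speed) / cfg$inflow_speed < 0.01))
  # and is a fixed point: another pass changes almost nothing
  st_b <- step_to_quasi_steady(st, cfg)
  expect_lt(max(abs(cell_speed(st_b) - sp)), 0.01 * cfg$inflow_speed)

  # square block: wake slower than free stream, inflow ~ outflow flux
  st <- flow_state(g, cfg)
  st$mask[11:15, 20:24] <- TRUE
  for (k in 1:6) st <- step_to_quasi_steady(st, cfg)
  sp <- cell_speed(st)
  wake <- mean(sp[12:14, 26:30])
  free <- mean(sp[3:5, 26:30])
  expect_lt(wake, 0.7 * free)
  fl <- boundary_fluxes(st)
  expect_lt(abs(fl$inflow - fl$outflow) / fl$inflow, 0.01)

  # doubling the substep count changes probe speeds by < 2% once converged
  cfg2 <- wind_config(inflow_speed = 5, dt_wind = 0.1,
                      quasi_steady_steps = 60)
  st2 <- flow_state(g, cfg2)
  st2$mask[11:15, 20:24] <- TRUE
  for (k in 1:3) st2 <- step_to_quasi_steady(st2, cfg2)
  sp2 <- cell_speed(st2)
  probes <- cbind(c(3, 8, 13, 18, 22, 5, 12, 20, 13, 7),
                  c(10, 15, 30, 40, 45, 28, 14, 33, 45, 5))
  expect_lt(max(abs(sp[probes] - sp2[probes]) / cfg$inflow_speed), 0.02)
})

test_that("grid refinement barely changes the obstacle-free channel speed", {
  speeds <- vapply(c(1, 0.5), function(dx) {
    g <- grid_spec(10, 20, dx)
    cfg <- wind_config(inflow_speed = 4, dt_wind = 0.05 * dx,
                       quasi_steady_steps = 25)
    st <- step_to_quasi_steady(flow_state(g, cfg), cfg)
    mean(cell_speed(st)[round(g$nx / 2), ])
  }, numeric(1))
  expect_lt(abs(speeds[1] - speeds[2]) / speeds[2], 0.01)
})

test_that("temperature transport: identity, plume translation, mass decay, positivity", {
  g <- grid_spec(10, 40, 1)
  cfg <- wind_config(inflow_speed = 1, dt_wind = 0.1, theta_kappa = 0,
                     theta_dt = 1)
  # zero wind, zero sources, zero diffusion: theta unchanged
  st <- flow_state(g, wind_config(inflow_speed = 0, dt_wind = 0.1,
                                  theta_kappa = 0))
  st$u[] <- 0; st$v[] <- 0
  st$theta[5, 10] <- 3
  st2 <- advect_temperature(st, NULL, cfg, interval = 10)
  expect_equal(st2$theta, st$theta, tolerance = 1e-14)

  # uniform wind: plume centroid translates downstream by U * t within one
  # cell over 10 unit-CFL steps
  st <- flow_state(g, cfg)
  st$theta[, 5] <- 1
  y0 <- sum(st$theta * col(st$theta)) / sum(st$theta)
  for (k in 1:10) st <- advect_temperature(st, NULL, cfg, interval = 1)
  y1 <- sum(st$theta * col(st$theta)) / sum(st$theta)
  expect_equal(y1 - y0, 10, tolerance = 1)   # cells travelled, dx = 1
  expect_true(all(st$theta >= 0))

  # total anomaly mass non-increasing in the absence of sources
  st <- flow_state(g, cfg)
  set.seed(8)
  st$theta <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  masses <- numeric(12)
  for (k in 1:12) {
    st <- advect_temperature(st, NULL, cfg, interval = 2)
    masses[k] <- sum(st$theta)
  }
  expect_true(all(diff(masses) <= 1e-10))
  expect_lt(masses[12], g$nx * g$ny * 0.5)   # flushing actually removes mass
})
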