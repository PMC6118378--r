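#' Finite-difference grid specification
#'
#' Cell-centred uniform grid covering `Lx` x `Ly` metres with spacing `dx`.
#' Cell centres sit at `(i - 0.5) * dx` for 1-based index `i`. The default
#' reproduces the 50 m x 100 m domain at 0.25 m spacing, matching the nominal
#' penguin body radius so each bird occupies about one cell.
#'
#' @param Lx,Ly domain extent in metres (default 50 x 100).
#' @param dx grid spacing in metres (default 0.25); must divide both extents.
#' @return An object of class `grid_spec` with `nx`, `ny`, `dx`, `Lx`, `Ly`.
#' @export
grid_spec <- function(Lx = 50, Ly = 100, dx = 0.25) {
  stopifnot(is.numeric(dx), length(dx) == 1L, dx > 0, Lx > 0, Ly > 0)
  nx <- round(Lx / dx); ny <- round(Ly / dx)
  if (abs(nx * dx - Lx) > 1e-9 || abs(ny * dx - Ly) > 1e-9)
    stop("grid spacing `dx` must divide both domain extents exactly")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 dx = dx, Lx = Lx, Ly = Ly),
            class = "grid_spec")
}

#' Wind solver configuration
#'
#' @param inflow_speed free-stream wind speed at the inflow boundary (m/s).
#' @param nu kinematic viscosity (m^2/s); default is air at cold conditions.
#' @param rho_air_dyn air density used in the momentum/pressure coupling
#'   (kg/m^3).
#' @param dt_wind explicit solver time step (s); must satisfy the advective
#'   CFL condition `inflow_speed * dt_wind / dx < 1`. The default 0.01 s
#'   keeps the inflow CFL number at 0.4 on the 0.25 m grid, leaving headroom
#'   for the local speed-up around bluff obstacles (which can exceed 2x the
#'   free stream and is covered by the same stability bound).
#' @param ppe_tol divergence tolerance (1/s) enforced after each projection.
#' @param ppe_max_iter iteration cap for the pressure Poisson relaxation.
#' @param quasi_steady_steps number of predictor/PPE/projection cycles run
#'   after each obstacle-mask update (quasi-steady continuation).
#' @param theta_kappa diffusivity of the temperature anomaly (m^2/s);
#'   molecular air value by default so transport is advection-dominated.
#' @param theta_dt target substep (s) of the implicit anomaly-transport
#'   sweeps; sets accuracy, not stability.
#' @param inflow_axis `"y"` (inflow on a short edge, flow along the long
#'   axis; default) or `"x"`.
#' @return An object of class `wind_config`.
#' @export
wind_config <- function(inflow_speed = 10, nu = 1.5e-5, rho_air_dyn = 1.4224,
                        dt_wind = 0.01, ppe_tol = 2e-3, ppe_max_iter = 6000,
                        quasi_steady_steps = 25, theta_kappa = 2e-5,
                        theta_dt = 5, inflow_axis = c("y", "x")) {
  inflow_axis <- match.arg(inflow_axis)
  stopifnot(inflow_speed >= 0, nu >= 0, rho_air_dyn > 0, dt_wind > 0,
            ppe_tol > 0, ppe_max_iter >= 1, quasi_steady_steps >= 1,
            theta_kappa >= 0, theta_dt > 0)
  structure(list(inflow_speed = inflow_speed, nu = nu,
                 rho_air_dyn = rho_air_dyn, dt_wind = dt_wind,
                 ppe_tol = ppe_tol, ppe_max_iter = as.integer(ppe_max_iter),
                 quasi_steady_steps = as.integer(quasi_steady_steps),
                 theta_kappa = theta_kappa, theta_dt = theta_dt,
                 inflow_axis = inflow_axis),
            class = "wind_config")
}

# map physical (x, y) to solver-frame coordinates (streamwise axis second)
solver_xy <- function(x, y, cfg) {
  if (cfg$inflow_axis == "y") list(x = x, y = y) else list(x = y, y = x)
}
solver_dims <- function(grid, cfg) {
  if (cfg$inflow_axis == "y") c(grid$nx, grid$ny) else c(grid$ny, grid$nx)
}
solver_extent <- function(grid, cfg) {
  if (cfg$inflow_axis == "y") c(grid$Lx, grid$Ly) else c(grid$Ly, grid$Lx)
}

#' Initialise a flow state
#'
#' Velocity is set to the uniform inflow profile, pressure and temperature
#' anomaly to zero, and the obstacle mask to all-clear. Fields are stored on
#' the staggered (MAC) layout in a frame whose second index runs along the
#' flow axis; accessors and samplers take physical coordinates.
#'
#' @param grid a [grid_spec()].
#' @param cfg a [wind_config()].
#' @return An object of class `flow_state` with `u`, `v` (staggered, m/s),
#'   `p` (Pa), `theta` (degC anomaly, >= 0), `mask` (logical), plus solver
#'   diagnostics.
#' @export
flow_state <- function(grid, cfg = wind_config()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(cfg, "wind_config"))
  if (cfg$inflow_speed * cfg$dt_wind / grid$dx >= 1)
    stop("dt_wind violates the advective CFL condition for this grid")
  d <- solver_dims(grid, cfg)
  nx <- d[1]; ny <- d[2]
  structure(list(
    grid = grid,
    u = matrix(0, nx + 1, ny),
    v = matrix(cfg$inflow_speed, nx, ny + 1),
    p = matrix(0, nx, ny),
    theta = matrix(0, nx, ny),
    mask = matrix(FALSE, nx, ny),
    max_div = 0, ppe_converged = TRUE
  ), class = "flow_state")
}

#' Rasterise penguin bodies onto the obstacle mask
#'
#' A cell is masked if and only if its centre lies within `radius` of any
#' penguin position (stair-step immersed boundary). At the default spacing
#' (`dx = 0.25` m, equal to the body radius) every bird masks at least the
#' cell containing it.
#'
#' @param x,y penguin positions in physical coordinates (m).
#' @param radius body radius (m, default 0.25).
#' @param grid a [grid_spec()].
#' @param cfg a [wind_config()] (sets the storage frame).
#' @return Logical mask matrix in the solver frame.
#' @export
rasterize_obstacles <- function(x, y, radius = 0.25, grid, cfg = wind_config()) {
  stopifnot(radius > 0)
  n <- length(x)
  d <- solver_dims(grid, cfg)
  mask <- matrix(FALSE, d[1], d[2])
  if (n == 0L) return(mask)
  bad <- which(x < 0 | x > grid$Lx | y < 0 | y > grid$Ly)
  if (length(bad))
    stop("penguin position outside domain (first offender: agent ",
         bad[1], ")")
  s <- solver_xy(x, y, cfg)
  dx <- grid$dx
  win <- ceiling(radius / dx)
  for (k in seq_len(n)) {
    ic <- floor(s$x[k] / dx) + 1; jc <- floor(s$y[k] / dx) + 1
    is <- max(1, ic - win):min(d[1], ic + win)
    js <- max(1, jc - win):min(d[2], jc + win)
    cxs <- (is - 0.5) * dx - s$x[k]
    cys <- (js - 0.5) * dx - s$y[k]
    hit <- outer(cxs^2, cys^2, `+`) <= radius^2
    mask[is, js] <- mask[is, js] | hit
  }
  mask
}

#' Explicit momentum predictor
#'
#' Advances the staggered velocity by one `dt_wind` step with conservative
#' donor-cell (upwind) advection and viscous diffusion, excluding the
#' pressure gradient. Masked faces stay zero.
#'
#' @param state a [flow_state()].
#' @param cfg a [wind_config()].
#' @return List with intermediate `u`, `v`.
#' @export
momentum_predictor <- function(state, cfg = wind_config()) {
  res <- cpp_predictor(state$u, state$v, storage_mask(state),
                       cfg$dt_wind, state$grid$dx, cfg$nu, cfg$inflow_speed)
  if (res$cfl >= 1)
    stop("advective CFL violated (max |u| dt / dx = ",
         signif(res$cfl, 3), "); reduce dt_wind")
  res[c("u", "v")]
}

storage_mask <- function(state) {
  m <- state$mask
  storage.mode(m) <- "integer"
  m
}

#' Solve the discrete Poisson equation
#'
#' Red-black successive over-relaxation of `laplacian(p) = rhs` with Neumann
#' conditions on walls, inflow, and obstacle cells, and the pressure pinned
#' to zero just past the outflow edge.
#'
#' @param rhs right-hand side at cell centres (solver frame).
#' @param mask logical obstacle mask (same shape).
#' @param dx grid spacing (m).
#' @param tol max-norm residual tolerance.
#' @param max_iter iteration cap.
#' @param p0 optional warm-start field.
#' @param omega over-relaxation factor; default near-optimal for the grid.
#' @return List `p`, `iters`, `converged`, `max_residual`.
#' @export
solve_poisson <- function(rhs, mask, dx, tol = 1e-6, max_iter = 5000,
                          p0 = NULL, omega = NULL) {
  if (is.null(p0)) p0 <- matrix(0, nrow(rhs), ncol(rhs))
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(dim(rhs))))
  m <- mask; storage.mode(m) <- "integer"
  cpp_poisson_sor(rhs, p0, m, dx, tol, as.integer(max_iter), omega)
}

#' Pressure Poisson step for the projection method
#'
#' Forms the divergence of the intermediate velocity and solves
#' `laplacian(p) = rho * div(u*) / dt` so the corrected field is discretely
#' divergence-free. Non-convergence within the iteration cap is flagged (and
#' warned about), never silent.
#'
#' @param u_star,v_star intermediate velocity from [momentum_predictor()].
#' @param state a [flow_state()].
#' @param cfg a [wind_config()].
#' @return List `p`, `iters`, `converged`, `max_residual`.
#' @export
solve_pressure_poisson <- function(u_star, v_star, state, cfg = wind_config()) {
  dx <- state$grid$dx
  m <- storage_mask(state)
  div <- cpp_divergence(u_star, v_star, m, dx)
  rhs <- cfg$rho_air_dyn * div / cfg$dt_wind
  sol <- cpp_poisson_sor(rhs, state$p, m, dx,
                         cfg$ppe_tol * cfg$rho_air_dyn / cfg$dt_wind,
                         cfg$ppe_max_iter,
                         2 / (1 + sin(pi / max(dim(rhs)))))
  if (!sol$converged)
    warning("pressure Poisson solve hit the iteration cap (residual ",
            signif(sol$max_residual, 3), ")")
  sol
}

#' Project the intermediate velocity onto the divergence-free space
#'
#' @param u_star,v_star intermediate velocity.
#' @param p pressure from [solve_pressure_poisson()].
#' @param state a [flow_state()].
#' @param cfg a [wind_config()].
#' @return The updated `flow_state` with corrected velocity, stored pressure,
#'   and the post-projection `max_div` diagnostic.
#' @export
project_velocity <- function(u_star, v_star, p, state, cfg = wind_config()) {
  res <- cpp_project(u_star, v_star, p, storage_mask(state),
                     cfg$dt_wind, state$grid$dx, cfg$rho_air_dyn)
  state$u <- res$u
  state$v <- res$v
  state$p <- p
  state$max_div <- res$max_div
  state
}

#' Transport the temperature anomaly
#'
#' Deposits the supplied source anomaly (degC, already integrated over the
#' coupling interval) and advances `theta` over `interval` seconds by
#' dimensionally split, flux-form implicit upwind sweeps plus explicit
#' diffusion. The implicit formulation is unconditionally stable and
#' positivity-preserving, so the stair-step corner jets around the stamped
#' huddle do not force tiny substeps. The inflow carries zero anomaly, the
#' outflow loses anomaly, and masked faces carry no advective flux (huddle
#' interiors exchange heat only by diffusion). The anomaly is clipped at
#' zero from below: heat sources only warm, ambient is the floor.
#'
#' @param state a [flow_state()].
#' @param sources anomaly to deposit (matrix in the solver frame) or `NULL`.
#' @param cfg a [wind_config()].
#' @param interval transport time in seconds.
#' @return The `flow_state` with updated `theta`.
#' @export
advect_temperature <- function(state, sources = NULL, cfg = wind_config(),
                               interval = 30) {
  th <- state$theta
  if (!is.null(sources)) {
    stopifnot(all(dim(sources) == dim(th)))
    th <- th + sources
  }
  nsub <- max(1L, ceiling(interval / cfg$theta_dt))
  state$theta <- cpp_advect_theta(th, state$u, state$v, storage_mask(state),
                                  state$grid$dx, interval, cfg$theta_kappa,
                                  as.integer(nsub))
  state
}

#' Advance the wind field to a quasi-steady state
#'
#' Runs `quasi_steady_steps` momentum/PPE/projection cycles at `dt_wind`
#' after a mask update. The wind field is quasi-static relative to penguin
#' motion, so a fixed number of continuation substeps per coupling interval
#' replaces integrating every 0.02 s step over the whole run.
#'
#' @param state a [flow_state()] whose `mask` is current.
#' @param cfg a [wind_config()].
#' @param n_steps override for the number of substeps.
#' @return The advanced `flow_state` (with `max_div` and `ppe_converged`).
#' @export
step_to_quasi_steady <- function(state, cfg = wind_config(), n_steps = NULL) {
  if (is.null(n_steps)) n_steps <- cfg$quasi_steady_steps
  res <- cpp_wind_substeps(state$u, state$v, state$p, storage_mask(state),
                           cfg$dt_wind, state$grid$dx, cfg$nu,
                           cfg$rho_air_dyn, cfg$inflow_speed,
                           as.integer(n_steps), cfg$ppe_tol,
                           cfg$ppe_max_iter,
                           2 / (1 + sin(pi / max(dim(state$p)))))
  if (res$cfl >= 1)
    stop("advective CFL violated during quasi-steady stepping; reduce dt_wind")
  state$u <- res$u; state$v <- res$v; state$p <- res$p
  state$max_div <- res$max_div
  state$ppe_converged <- res$converged
  if (!res$converged)
    warning("pressure Poisson solve hit the iteration cap during ",
            "quasi-steady stepping")
  state
}

#' Cell-centre wind speed magnitude
#'
#' Averages the staggered face velocities to cell centres and returns the
#' speed, used for sampling wind at penguin positions and for diagnostics.
#'
#' @param state a [flow_state()].
#' @return Matrix of speeds (m/s) in the solver frame.
#' @export
cell_speed <- function(state) {
  nx <- nrow(state$p); ny <- ncol(state$p)
  uc <- 0.5 * (state$u[1:nx, , drop = FALSE] +
               state$u[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (state$v[, 1:ny, drop = FALSE] +
               state$v[, 2:(ny + 1), drop = FALSE])
  sqrt(uc^2 + vc^2)
}

#' Boundary mass fluxes
#'
#' Integrated volume flux through the inflow and outflow edges (m^2/s in 2D),
#' for conservation checks.
#'
#' @param state a [flow_state()].
#' @return List with `inflow` and `outflow`.
#' @export
boundary_fluxes <- function(state) {
  dx <- state$grid$dx
  ny <- ncol(state$p)
  list(inflow = sum(state$v[, 1]) * dx,
       outflow = sum(state$v[, ny + 1]) * dx)
}

#' Write a gridded field snapshot
#'
#' One delimited-text raster per field (cell-centred, x-fastest) plus a JSON
#' sidecar with the grid metadata.
#'
#' @param state a [flow_state()].
#' @param dir output directory (created if needed).
#' @param time_s simulation time stamp.
#' @param fields which fields to write.
#' @return Invisibly, the files written.
#' @export
write_grid_snapshot <- function(state, dir, time_s,
                                fields = c("theta", "speed", "p")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (f in fields) {
    mat <- switch(f, theta = state$theta, p = state$p,
                  speed = cell_speed(state),
                  stop("unknown field: ", f))
    path <- file.path(dir, sprintf("grid_%s_t%06d.csv", f, round(time_s)))
    con <- file(path, "w")
    writeLines(c("# cell-centred raster, rows = x index (1-based), cols = y index",
                 "# x-fastest ordering when read row-wise"), con)
    write.table(mat, con, sep = ",", row.names = FALSE, col.names = FALSE)
    close(con)
    written <- c(written, path)
  }
  meta <- list(dx = state$grid$dx, Lx = state$grid$Lx, Ly = state$grid$Ly,
               nx = state$grid$nx, ny = state$grid$ny, time_s = time_s,
               fields = fields)
  side <- file.path(dir, sprintf("grid_meta_t%06d.json", round(time_s)))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(written, side))
}
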