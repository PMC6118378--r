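#' Behaviour model parameters
#'
#' Two length scales enter the behaviour model. The interpolation smoothing
#' length `h` (10 m) governs how birds perceive and share warmth; the
#' repulsion smoothing length `repulsion_h` (0.5 m, one body diameter)
#' governs the excluded-crowding pressure that keeps bodies from
#' overlapping. A single 10 m kernel cannot do the latter: its gradient
#' vanishes toward the origin, so body-scale crowding would be unresisted.
#'
#' @param h SPH interpolation smoothing length (m, default 10).
#' @param repulsion_h smoothing length of the repulsion pressure kernel
#'   (m, default 0.5, one body diameter: an overlapping pair already raises
#'   the local density past the rest density).
#' @param body_radius penguin body radius (m, default 0.25); governs
#'   motion, wall clamping, and the drive tie-break.
#' @param blocking_radius effective aerodynamic radius used when stamping
#'   birds onto the wind-obstacle mask (m, default 0.35, about half the
#'   nearest-neighbour spacing in a packed huddle). Packed bodies block wind
#'   through sub-grid gaps (plumage, boundary layers), so the aerodynamic
#'   footprint is larger than the body itself.
#' @param max_speed walking speed cap (m/s, default 0.5, the observed land
#'   movement speed).
#' @param b_scale drive gain (m s^-2 per degC). The default 0.04 makes a bird
#'   at deep sub-TNZ wind chill (around -35 degC, i.e. 25 degC below the LCT)
#'   reach the speed cap within one behaviour step.
#' @param dt_behavior behaviour time step (s, default 0.5: half a body
#'   diameter of travel per step at the speed cap).
#' @param eos an [eos_params()] for the repulsion pressure.
#' @return An object of class `behavior_params`.
#' @export
behavior_params <- function(h = 10, repulsion_h = 0.5, body_radius = 0.25,
                            blocking_radius = 0.35, max_speed = 0.5,
                            b_scale = 0.04, dt_behavior = 0.5,
                            eos = eos_params()) {
  stopifnot(h > 0, repulsion_h > 0, body_radius > 0, blocking_radius > 0,
            max_speed > 0, b_scale > 0, dt_behavior > 0,
            inherits(eos, "eos_params"))
  if (dt_behavior * max_speed >= h)
    stop("dt_behavior * max_speed must stay below the smoothing length")
  structure(list(h = h, repulsion_h = repulsion_h, body_radius = body_radius,
                 blocking_radius = blocking_radius,
                 max_speed = max_speed, b_scale = b_scale,
                 dt_behavior = dt_behavior, eos = eos,
                 kernel = kernel_spec(h = h),
                 repulsion_kernel = kernel_spec(h = repulsion_h)),
            class = "behavior_params")
}

#' Sample the local environment at penguin positions
#'
#' Averages the four grid nodes (cell centres) surrounding each bird: wind
#' speed as the mean of node speed magnitudes, temperature as ambient plus
#' the mean temperature anomaly. Masked nodes are excluded from the wind
#' average. A bird whose four nodes are all masked is standing on its own
#' aerodynamic stamp; its surface wind is then taken from the open cells of
#' the surrounding 4 x 4 ring, and only a bird whose whole ring is masked
#' too (deep inside the packed huddle) is fully sheltered, `u_local = 0`.
#'
#' @param x,y penguin positions (physical coordinates, m).
#' @param state a [flow_state()].
#' @param ambient background ambient temperature (degC).
#' @param cfg a [wind_config()].
#' @return List with `Ta` (degC) and `u` (m/s), one entry per bird.
#' @export
sample_local_environment <- function(x, y, state, ambient,
                                     cfg = wind_config()) {
  grid <- state$grid
  if (any(x < 0 | x > grid$Lx | y < 0 | y > grid$Ly))
    stop("penguin position outside domain")
  s <- solver_xy(x, y, cfg)
  dx <- grid$dx
  nx <- nrow(state$p); ny <- ncol(state$p)
  speed <- cell_speed(state)
  n <- length(x)
  # the 2 x 2 block of cell centres around each point, as flat indices
  i0 <- pmin(pmax(floor(s$x / dx + 0.5), 1), nx - 1)
  j0 <- pmin(pmax(floor(s$y / dx + 0.5), 1), ny - 1)
  node <- cbind(i0 + nx * (j0 - 1), i0 + 1 + nx * (j0 - 1),
                i0 + nx * j0, i0 + 1 + nx * j0)
  th4 <- matrix(state$theta[node], n, 4)
  sp4 <- matrix(speed[node], n, 4)
  open4 <- matrix(!state$mask[node], n, 4)
  n_open <- rowSums(open4)
  u <- ifelse(n_open > 0, rowSums(sp4 * open4) / pmax(n_open, 1), 0)
  sealed <- which(n_open == 0L)
  if (length(sealed)) {
    # outer ring of the 4 x 4 block around the bird (4 x 4 minus inner 2 x 2)
    ring <- expand.grid(di = c(-1L, 0L, 1L, 2L), dj = c(-1L, 0L, 1L, 2L))
    ring <- ring[!(ring$di %in% c(0L, 1L) & ring$dj %in% c(0L, 1L)), ]
    for (k in sealed) {
      ii <- pmin(pmax(i0[k] + ring$di, 1L), nx)
      jj <- pmin(pmax(j0[k] + ring$dj, 1L), ny)
      idx <- ii + nx * (jj - 1L)
      open <- !state$mask[idx]
      u[k] <- if (any(open)) mean(speed[idx][open]) else 0
    }
  }
  list(Ta = ambient + rowMeans(th4), u = u)
}

#' Drive direction toward the colony centre of mass
#'
#' Unit vector from each bird toward the equal-weight centre of mass of the
#' whole colony; the zero vector for birds within one body radius of the
#' centre (tie-break: any direction there is arbitrary, repulsion resolves
#' crowding).
#'
#' @param x,y colony positions.
#' @param body_radius tie-break radius (m).
#' @return An n x 2 matrix of unit (or zero) vectors.
#' @export
drive_direction <- function(x, y, body_radius = 0.25) {
  n <- length(x)
  if (n == 0L) stop("colony must be non-empty")
  cx <- mean(x); cy <- mean(y)
  dxv <- cx - x; dyv <- cy - y
  d <- sqrt(dxv^2 + dyv^2)
  scale <- ifelse(d > body_radius, 1 / d, 0)
  cbind(dxv * scale, dyv * scale)
}

#' Overdamped velocity update
#'
#' The behaviour momentum balance has no friction term, so velocity is
#' treated kinematically: it is recomputed each step from the current forces
#' (`v = dt * (b * drive + repulsion)`) and capped at the walking speed by
#' rescaling. Comfortable (neutral) birds with no repulsion therefore stand
#' still.
#'
#' @param x,y colony positions.
#' @param b_signed per-bird signed drive accelerations from
#'   [behavior_accel()].
#' @param params a [behavior_params()].
#' @param mass particle masses (scalar recycled).
#' @return An n x 2 matrix of velocities (m/s).
#' @export
update_velocity <- function(x, y, b_signed, params = behavior_params(),
                            mass = 1) {
  n <- length(x)
  b_signed <- rep_len(b_signed, n)
  spec <- params$repulsion_kernel
  rho <- sph_density(x, y, mass, spec)
  P <- eos_pressure(rho, params$eos)
  arep <- sph_repulsion(x, y, mass, rho, P, spec)
  dir <- drive_direction(x, y, params$body_radius)
  acc <- arep + dir * b_signed
  v <- params$dt_behavior * acc
  sp <- sqrt(rowSums(v^2))
  over <- sp > params$max_speed
  v[over, ] <- v[over, , drop = FALSE] * (params$max_speed / sp[over])
  v
}

#' Explicit Euler position update with wall clamping
#'
#' `r <- r + dt * v`; positions are clamped one body radius inside the
#' domain and the wall-normal velocity component is zeroed on contact
#' (tangential motion preserved).
#'
#' @param x,y positions; `vx,vy` velocities.
#' @param params a [behavior_params()].
#' @param domain `c(Lx, Ly)` extent (m).
#' @return List `x`, `y`, `vx`, `vy` after the step.
#' @export
integrate_positions <- function(x, y, vx, vy, params = behavior_params(),
                                domain = c(50, 100)) {
  dt <- params$dt_behavior
  nx <- x + dt * vx; ny <- y + dt * vy
  if (any(!is.finite(nx)) || any(!is.finite(ny)))
    stop("non-finite position for agent ",
         which(!is.finite(nx) | !is.finite(ny))[1])
  lo <- params$body_radius
  hx <- domain[1] - lo; hy <- domain[2] - lo
  vx[nx < lo & vx < 0] <- 0; vx[nx > hx & vx > 0] <- 0
  vy[ny < lo & vy < 0] <- 0; vy[ny > hy & vy > 0] <- 0
  nx <- pmin(pmax(nx, lo), hx)
  ny <- pmin(pmax(ny, lo), hy)
  list(x = nx, y = ny, vx = vx, vy = vy)
}

#' Advance the colony through one coupling interval
#'
#' Runs `n_sub` behaviour substeps with the wind-chill drive frozen and the
#' SPH density, pressure, repulsion, and colony centre of mass refreshed
#' every substep (the compiled fast path; a single substep is identical to
#' [update_velocity()] followed by [integrate_positions()]).
#'
#' @param x,y colony positions.
#' @param b_signed per-bird signed drive accelerations.
#' @param params a [behavior_params()].
#' @param n_sub number of substeps.
#' @param domain `c(Lx, Ly)` extent (m).
#' @param mass particle masses (scalar recycled).
#' @return List `x`, `y`, `vx`, `vy` after the interval.
#' @export
behavior_interval <- function(x, y, b_signed, params = behavior_params(),
                              n_sub = 60, domain = c(50, 100), mass = 1) {
  n <- length(x)
  stopifnot(n >= 1L, length(y) == n)
  b_signed <- rep_len(b_signed, n)
  mass <- rep_len(mass, n)
  spec <- params$repulsion_kernel
  cpp_behavior_interval(as.numeric(x), as.numeric(y), as.numeric(b_signed),
                        mass, spec$h, spec$sigma, params$eos$k,
                        params$eos$rho0, params$dt_behavior,
                        as.integer(n_sub), params$max_speed,
                        domain[1], domain[2], params$body_radius)
}
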