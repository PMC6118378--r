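#' Full simulation configuration
#'
#' Bundles the grid, wind, thermoregulation, and behaviour settings with the
#' run schedule. Defaults reproduce the reference scenario: 200 birds on a
#' 50 m x 100 m plane at 0.25 m grid spacing, ambient -28 degC, 10 m/s
#' inflow along the long axis, 30 s coupling interval, 2 simulated hours,
#' snapshots at 0/30/60/75/90/120 minutes.
#'
#' @param n_penguins colony size (presets of interest: 100, 200, 800).
#' @param ambient_temperature background air temperature (degC).
#' @param total_time simulated duration (s); must be an integer multiple of
#'   `coupling_interval`.
#' @param coupling_interval wind/behaviour coupling interval (s); must be an
#'   integer multiple of the behaviour step.
#' @param snapshot_times times (s) at which colony/grid snapshots and
#'   summary rows are recorded.
#' @param seed master random seed (placement only; everything downstream is
#'   deterministic, so identical config + seed gives identical output).
#' @param output_dir optional directory for snapshot/summary files.
#' @param grid a [grid_spec()].
#' @param wind a [wind_config()].
#' @param thermo a [thermo_params()].
#' @param behavior a [behavior_params()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_penguins = 200, ambient_temperature = -28,
                       total_time = 7200, coupling_interval = 30,
                       snapshot_times = c(0, 30, 60, 75, 90, 120) * 60,
                       seed = 1, output_dir = NULL,
                       grid = grid_spec(), wind = wind_config(),
                       thermo = thermo_params(), behavior = behavior_params()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(wind, "wind_config"),
            inherits(thermo, "thermo_params"),
            inherits(behavior, "behavior_params"))
  if (n_penguins < 1) stop("n_penguins must be at least 1")
  if (total_time < 0) stop("total_time must be non-negative")
  n_sub <- coupling_interval / behavior$dt_behavior
  if (abs(n_sub - round(n_sub)) > 1e-9)
    stop("coupling_interval must be an integer multiple of dt_behavior")
  n_steps <- total_time / coupling_interval
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("total_time must be an integer multiple of coupling_interval")
  if (wind$inflow_speed * wind$dt_wind / grid$dx >= 1)
    stop("dt_wind violates the advective CFL condition for this grid")
  structure(list(
    n_penguins = as.integer(n_penguins),
    ambient_temperature = ambient_temperature,
    total_time = total_time,
    coupling_interval = coupling_interval,
    snapshot_times = snapshot_times,
    seed = as.integer(seed),
    output_dir = output_dir,
    grid = grid, wind = wind, thermo = thermo, behavior = behavior
  ), class = "sim_config")
}

#' Scenario presets
#'
#' Ready-made configurations for the three colony sizes of interest
#' (pairing ~200, chick rearing ~100, incubation ~800) under identical
#' ambient conditions. `dx` selects the grid resolution: 0.25 m matches the
#' body radius (the reference choice); 0.5 m is a coarser, faster setting
#' for exploratory work (`dt_wind` is rescaled to keep the same CFL number).
#'
#' @param n_penguins 100, 200, or 800 (other values are allowed).
#' @param dx grid spacing in metres.
#' @param seed master seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @export
preset_config <- function(n_penguins = 200, dx = 0.25, seed = 1, ...) {
  wind <- wind_config(dt_wind = 0.01 * dx / 0.25)
  sim_config(n_penguins = n_penguins, seed = seed,
             grid = grid_spec(dx = dx), wind = wind, ...)
}

#' Initialise the coupled simulation
#'
#' Places the colony uniformly at random (seeded) with rejection so no two
#' centres are closer than one body diameter, and initialises the flow to
#' the uniform inflow profile with zero pressure and temperature anomaly.
#'
#' @param config a [sim_config()].
#' @return List with `flow` (a [flow_state()]) and `colony` (data frame with
#'   id, position, velocity, and thermal state columns).
#' @export
initialize_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- with_seed(
    substream_seed(config$seed, "placement"),
    make_fixture_colony(config$n_penguins,
                        domain = c(config$grid$Lx, config$grid$Ly),
                        seed = config$seed, pattern = "random",
                        min_separation = 2 * config$behavior$body_radius)
  )
  colony <- data.frame(
    id = layout$id, x = layout$x, y = layout$y,
    vx = 0, vy = 0, MR = NA_real_, Texp = NA_real_, Twc = NA_real_,
    tnz = factor(rep("neutral", config$n_penguins),
                 levels = c("cold", "neutral", "hot")),
    sector = "unassigned", stringsAsFactors = FALSE
  )
  list(flow = flow_state(config$grid, config$wind), colony = colony)
}

# physical unit vector pointing the way the wind blows
wind_direction <- function(config) {
  if (config$wind$inflow_axis == "y") c(0, 1) else c(1, 0)
}

# steps 2-6 of the coupling procedure: refresh the wind for the current
# obstacle configuration and diagnose every bird's thermal state at time t.
# Returns the updated flow, the diagnosed colony, and the deposit field
# (still to be advected into theta).
diagnose_state <- function(flow, colony, config) {
  bp <- config$behavior; tp <- config$thermo; wc <- config$wind
  # a bird blocks wind over its aerodynamic footprint, and always at least
  # the cell containing it on grids coarser than that footprint
  stamp_radius <- max(bp$blocking_radius, config$grid$dx / sqrt(2))
  flow$mask <- rasterize_obstacles(colony$x, colony$y, stamp_radius,
                                   config$grid, wc)
  flow <- step_to_quasi_steady(flow, wc)
  env <- sample_local_environment(colony$x, colony$y, flow,
                                  config$ambient_temperature, wc)
  colony$MR <- metabolic_heat(env$Ta, tp)
  spec <- bp$kernel
  rho <- sph_density(colony$x, colony$y, 1, spec)
  deposit <- local_temperature_field(colony$x, colony$y, colony$MR,
                                     config$grid, wc,
                                     coupling_dt = config$coupling_interval,
                                     params = tp, spec = spec, rho = rho)
  dT <- local_temperature_increase(colony$x, colony$y, colony$MR,
                                   colony$x, colony$y,
                                   coupling_dt = config$coupling_interval,
                                   params = tp, spec = spec, rho = rho)
  colony$Texp <- exposed_temperature(env$Ta, dT)
  colony$Twc <- wind_chill(colony$Texp, env$u, tp)
  colony$tnz <- tnz_state(colony$Twc, tp)
  list(flow = flow, colony = colony, deposit = deposit)
}

#' One coupling step
#'
#' Executes the coupled update over one interval: (2) obstacle rasterisation
#' and quasi-steady wind update; (3) local environment sampling; (4)
#' metabolic heat; (5) kernel heat deposit and exposed temperature; (6) wind
#' chill; (7) TNZ state, drive accelerations, and repulsion pressures; (8-9)
#' behaviour substeps with the wind frozen, then temperature-anomaly
#' transport over the interval.
#'
#' @param flow a [flow_state()].
#' @param colony colony data frame.
#' @param config a [sim_config()].
#' @param t current simulation time (s), used only for error labelling.
#' @return List with advanced `flow`, `colony`, and the diagnosed colony at
#'   time `t` (`colony_at_t`).
#' @export
coupling_step <- function(flow, colony, config, t = 0) {
  d <- diagnose_state(flow, colony, config)
  flow <- d$flow
  diag_colony <- d$colony
  bp <- config$behavior
  b <- behavior_accel(diag_colony$Twc, config$thermo, bp$b_scale)
  n_sub <- round(config$coupling_interval / bp$dt_behavior)
  moved <- behavior_interval(diag_colony$x, diag_colony$y, b, bp,
                             n_sub = n_sub,
                             domain = c(config$grid$Lx, config$grid$Ly))
  colony <- diag_colony
  colony$x <- moved$x; colony$y <- moved$y
  colony$vx <- moved$vx; colony$vy <- moved$vy
  flow <- advect_temperature(flow, d$deposit, config$wind,
                             config$coupling_interval)
  list(flow = flow, colony = colony, colony_at_t = diag_colony)
}

#' Run the coupled huddle simulation
#'
#' Iterates [coupling_step()] from time 0 to `total_time`, recording colony
#' snapshots and huddle-summary rows at the configured snapshot times and a
#' per-interval log of solver diagnostics. With `total_time = 0` only the
#' initial snapshot is produced. Identical configuration and seed give
#' bit-identical trajectories.
#'
#' @param config a [sim_config()].
#' @param quiet suppress progress messages.
#' @return List with `summary` (one row per snapshot), `snapshots` (named
#'   list of colony data frames), `final_colony`, `final_flow`, `log`, and
#'   the echoed `config`.
#' @export
run_huddle_sim <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  st <- initialize_simulation(config)
  flow <- st$flow; colony <- st$colony
  snap_times <- sort(unique(round(config$snapshot_times)))
  n_steps <- round(config$total_time / config$coupling_interval)
  snapshots <- list(); summaries <- list(); logs <- list()
  domain <- c(config$grid$Lx, config$grid$Ly)

  record <- function(diag_colony, flow, t_now) {
    key <- sprintf("t%06d", t_now)
    diag_colony$time_s <- t_now
    h <- huddle_membership(diag_colony$x, diag_colony$y)
    diag_colony$sector <- classify_sectors(diag_colony$x, diag_colony$y, h,
                                           wind_direction(config))
    snapshots[[key]] <<- diag_colony
    summaries[[key]] <<- summarize_huddle(diag_colony, domain, config$thermo,
                                          time_min = t_now / 60)
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      write_colony(diag_colony,
                   file.path(config$output_dir,
                             sprintf("colony_%s.csv", key)),
                   comment = sprintf("snapshot at t = %d s", t_now))
      write_grid_snapshot(flow, config$output_dir, t_now)
    }
  }

  for (k in seq_len(n_steps)) {
    t_now <- (k - 1) * config$coupling_interval
    step <- coupling_step(flow, colony, config, t_now)
    if (t_now %in% snap_times) record(step$colony_at_t, step$flow, t_now)
    logs[[k]] <- data.frame(
      time_s = t_now, max_div = step$flow$max_div,
      ppe_converged = step$flow$ppe_converged,
      mean_Twc = mean(step$colony_at_t$Twc),
      pct_in_TNZ = 100 * mean(step$colony_at_t$tnz == "neutral")
    )
    flow <- step$flow; colony <- step$colony
    if (!quiet && (k %% 20 == 0))
      message(sprintf("t = %5d s  mean Twc = %6.2f", t_now,
                      logs[[k]]$mean_Twc))
  }
  # diagnose (without moving) the final state so total_time itself is
  # observable; for total_time = 0 this is the initial snapshot
  d <- diagnose_state(flow, colony, config)
  if (config$total_time %in% snap_times || n_steps == 0)
    record(d$colony, d$flow, config$total_time)
  final_colony <- d$colony
  final_colony$time_s <- config$total_time
  hfin <- huddle_membership(final_colony$x, final_colony$y)
  final_colony$sector <- classify_sectors(final_colony$x, final_colony$y,
                                          hfin, wind_direction(config))

  result <- list(
    summary = do.call(rbind, summaries),
    snapshots = snapshots,
    final_colony = final_colony,
    final_flow = d$flow,
    log = if (length(logs)) do.call(rbind, logs) else NULL,
    config = config
  )
  if (!is.null(config$output_dir)) {
    write.csv(result$summary,
              file.path(config$output_dir, "summary.csv"), row.names = FALSE)
    echo <- config_to_list(config)
    echo$huddlesim_version <-
      as.character(utils::packageVersion("huddlesim"))
    jsonlite::write_json(echo,
                         file.path(config$output_dir, "config_echo.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  result
}
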