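# Shared run configurations and a cache so expensive coupled runs are done
# once per test session and reused across test files.

# coarse but physically complete configuration used by the long-run checks:
# full 50 x 100 m domain, 0.5 m grid, full 2-hour schedule
desk_config <- function(n_penguins = 200, seed = 1, total_time = 7200,
                        snapshot_times = c(0, 30, 60, 75, 90, 120) * 60,
                        ...) {
  sim_config(n_penguins = n_penguins, seed = seed, total_time = total_time,
             snapshot_times = snapshot_times,
             grid = grid_spec(dx = 0.5),
             wind = wind_config(dt_wind = 0.01, quasi_steady_steps = 12),
             ...)
}

# small, fast configuration for smoke-level driver checks
mini_config <- function(n_penguins = 12, seed = 7, total_time = 120, ...) {
  sim_config(n_penguins = n_penguins, seed = seed, total_time = total_time,
             snapshot_times = c(0, total_time),
             grid = grid_spec(Lx = 20, Ly = 40, dx = 0.5),
             wind = wind_config(dt_wind = 0.01, quasi_steady_steps = 8),
             ...)
}

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(n_penguins, seed) {
  key <- sprintf("n%d_s%d", n_penguins, seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_huddle_sim(desk_config(n_penguins, seed))
  .run_cache[[key]]
}
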