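#' Thermoregulation parameters
#'
#' Physiological and air constants for the heat budget. Defaults follow the
#' published emperor-penguin values: whole-body thermal conductance
#' `C = 0.104` W/degC, body temperature `Tb = 37.7` degC, thermo-neutral zone
#' (TNZ) from `LCT = -10` to `UCT = 20` degC, and a wind-chill calm threshold
#' of 1.3 m/s. The specific heat of air defaults to 1000 J/kg/degC (the
#' standard value near -50 degC to three figures) and the air density to
#' 1.4224 kg/m^3 at -25 degC.
#'
#' `wind_unit_convention` selects how the wind-chill index treats the wind
#' speed: `"kmh"` converts to km/h inside the formula (the convention under
#' which the North American index is defined) while `"ms"` applies the
#' formula to the m/s value verbatim. The calm threshold is tested in m/s
#' under both conventions.
#'
#' `deposit_mode` selects how neighbour heat converts to a local temperature
#' rise: `"energy"` (default) spreads each bird's released energy
#' `MR * dt` over its kernel footprint against the heat capacity of a 1.2 m
#' air column, which conserves energy exactly up to kernel truncation;
#' `"shepard"` is the density-normalised kernel average divided by the
#' kernel-cylinder heat capacity `C_air * rho_air * V_air` (a diagnostic
#' variant; it averages rather than accumulates neighbour heat).
#'
#' @param C whole-body thermal conductance (W/degC).
#' @param Tb body temperature (degC).
#' @param A exposed-surface factor (dimensionless; unity in the main model).
#' @param C_air specific heat of air (J/kg/degC).
#' @param rho_air air density (kg/m^3).
#' @param penguin_height air-column height over which heat mixes (m); also
#'   the cylinder length defining `V_air`.
#' @param LCT,UCT lower/upper critical temperatures (degC).
#' @param calm_threshold wind speed below which wind chill has no effect (m/s).
#' @param wind_unit_convention `"ms"` or `"kmh"` (see Details).
#' @param deposit_mode `"energy"` or `"shepard"` (see Details).
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(C = 0.104, Tb = 37.7, A = 1.0, C_air = 1000,
                          rho_air = 1.4224, penguin_height = 1.2,
                          LCT = -10, UCT = 20, calm_threshold = 1.3,
                          wind_unit_convention = c("ms", "kmh"),
                          deposit_mode = c("energy", "shepard")) {
  wind_unit_convention <- match.arg(wind_unit_convention)
  deposit_mode <- match.arg(deposit_mode)
  if (LCT >= UCT) stop("LCT must be below UCT")
  stopifnot(C > 0, C_air > 0, rho_air > 0, penguin_height > 0, A > 0,
            calm_threshold >= 0)
  structure(list(C = C, Tb = Tb, A = A, C_air = C_air, rho_air = rho_air,
                 penguin_height = penguin_height, LCT = LCT, UCT = UCT,
                 calm_threshold = calm_threshold,
                 wind_unit_convention = wind_unit_convention,
                 deposit_mode = deposit_mode),
            class = "thermo_params")
}

#' Kernel-cylinder air volume
#'
#' Volume of a smooth cylinder with diameter equal to the smoothing length
#' and length equal to the penguin height; always derived from the current
#' kernel spec, never hard-coded.
#'
#' @param spec a [kernel_spec()].
#' @param params a [thermo_params()].
#' @return Volume in m^3.
#' @export
kernel_air_volume <- function(spec = kernel_spec(), params = thermo_params()) {
  pi * (spec$h / 2)^2 * params$penguin_height
}

#' Metabolic heat production (Fourier-law conductance model)
#'
#' `MR = C * A * (Tb - Ta)`, floored at zero when the local air is at or
#' above body temperature (no negative production).
#'
#' @param Ta_local local air temperature(s), degC.
#' @param params a [thermo_params()].
#' @return Metabolic rate(s) in watts.
#' @export
metabolic_heat <- function(Ta_local, params = thermo_params()) {
  pmax(params$C * params$A * (params$Tb - Ta_local), 0)
}

#' Huddle-size area-reduction reference curve
#'
#' The classic `A = n^(-1/4)` scaling of exposed surface with group size,
#' used only by the diagnostic comparison curve ([heatloss_comparison()]);
#' the main model keeps `A = 1` because proximity effects emerge dynamically
#' from wind sheltering and shared warmth.
#'
#' @param n number of aggregated animals (integer >= 1, vectorised).
#' @return `n^(-1/4)`.
#' @export
area_reduction_reference <- function(n) {
  if (any(n < 1)) stop("group size must be at least 1")
  n^(-1 / 4)
}

#' Local temperature increase from neighbour heat
#'
#' Kernel-weighted warming at query points from the metabolic heat released
#' over one coupling interval. In the default `"energy"` mode
#' `dT(r) = sum_i MR_i * dt * W(r - r_i, h) / (C_air * rho_air * H)` with
#' `H` the mixing-column height, so the column-integrated heat content equals
#' the energy released (up to kernel truncation at the domain edge). In
#' `"shepard"` mode the density-normalised form
#' `dT(r) = sum_i MR_i * dt * (m_i / rho_i) * W / (C_air * rho_air * V_air)`
#' is used instead.
#'
#' @param px,py penguin positions (m).
#' @param MR per-penguin metabolic rates (W).
#' @param qx,qy query point coordinates (m).
#' @param coupling_dt coupling interval (s).
#' @param params a [thermo_params()].
#' @param spec a [kernel_spec()].
#' @param mass particle masses (scalar recycled; `"shepard"` mode only).
#' @param rho SPH densities (computed if missing; `"shepard"` mode only).
#' @return Temperature increases (degC) at the query points, non-negative.
#' @export
local_temperature_increase <- function(px, py, MR, qx, qy, coupling_dt = 30,
                                       params = thermo_params(),
                                       spec = kernel_spec(), mass = 1,
                                       rho = NULL) {
  stopifnot(coupling_dt > 0)
  n <- length(px)
  if (n == 0L) return(numeric(length(qx)))
  w <- deposit_weights(px, py, MR, coupling_dt, params, spec, mass, rho)
  ks <- if (params$deposit_mode == "energy") heat_kernel_spec(spec) else spec
  cpp_kernel_sum_at(as.numeric(qx), as.numeric(qy),
                    as.numeric(px), as.numeric(py), w, ks$h, ks$sigma)
}

# per-penguin kernel weights for the heat deposit (degC per unit kernel value)
deposit_weights <- function(px, py, MR, coupling_dt, params, spec,
                            mass = 1, rho = NULL) {
  n <- length(px)
  energy <- MR * coupling_dt
  if (params$deposit_mode == "energy") {
    energy / (params$C_air * params$rho_air * params$penguin_height)
  } else {
    mass <- rep_len(mass, n)
    if (is.null(rho)) rho <- sph_density(px, py, mass, spec)
    V_air <- kernel_air_volume(spec, params)
    energy * (mass / rho) / (params$C_air * params$rho_air * V_air)
  }
}

#' Heat-spreading kernel
#'
#' The kernel over which released metabolic energy is diluted in the
#' `"energy"` deposit mode. Its smoothing length, `h * sqrt(10/28)` (about
#' 6 m for `h = 10`), is fixed by requiring the kernel's peak value to equal
#' `1 / (pi (h/2)^2)`, i.e. the dilution of the kernel-cylinder air volume
#' `V_air`: a lone bird then warms the air at its own position by exactly
#' `MR * dt / (C_air * rho_air * V_air)` while the column-integrated deposit
#' equals the energy released.
#'
#' @param spec the interpolation [kernel_spec()].
#' @return A [kernel_spec()] for the heat deposit.
#' @export
heat_kernel_spec <- function(spec = kernel_spec()) {
  kernel_spec(h = spec$h * sqrt(10 / 28), normalization = spec$normalization)
}

#' Gridded heat-deposit field
#'
#' The same deposit as [local_temperature_increase()] evaluated at every cell
#' centre of the flow grid (solver frame), ready to feed
#' [advect_temperature()].
#'
#' @param px,py penguin positions (physical coordinates).
#' @param MR metabolic rates (W).
#' @param grid a [grid_spec()].
#' @param cfg a [wind_config()] (sets the storage frame).
#' @inheritParams local_temperature_increase
#' @return Matrix of temperature increases (degC) in the solver frame.
#' @export
local_temperature_field <- function(px, py, MR, grid, cfg = wind_config(),
                                    coupling_dt = 30,
                                    params = thermo_params(),
                                    spec = kernel_spec(), mass = 1,
                                    rho = NULL) {
  d <- solver_dims(grid, cfg)
  if (length(px) == 0L) return(matrix(0, d[1], d[2]))
  w <- deposit_weights(px, py, MR, coupling_dt, params, spec, mass, rho)
  ks <- if (params$deposit_mode == "energy") heat_kernel_spec(spec) else spec
  s <- solver_xy(px, py, cfg)
  cpp_kernel_sum_grid(as.numeric(s$x), as.numeric(s$y), w, ks$h, ks$sigma,
                      d[1], d[2], grid$dx)
}

#' Exposed temperature
#'
#' `Texp = Ta + dT`: the ambient (plus accumulated anomaly) temperature at a
#' bird's position plus the warming contributed by its neighbours this
#' interval. No clipping.
#'
#' @param Ta ambient-plus-anomaly temperature(s), degC.
#' @param dT local temperature increase(s), degC.
#' @return `Ta + dT`.
#' @export
exposed_temperature <- function(Ta, dT) Ta + dT

#' Wind-chill temperature
#'
#' North American / UK wind chill index, applied piecewise: for local wind
#' `u <= calm_threshold` (1.3 m/s) the output equals the input exactly;
#' above it, `Twc = 13.12 + 0.6215 Texp - 11.37 u^0.16 +
#' 0.3965 Texp u^0.16`, with `u` in the configured unit convention. The index
#' can mildly warm at high `Texp`; the result is clamped to never exceed
#' `Texp` so wind never heats.
#'
#' @param Texp exposed temperature(s), degC.
#' @param u_local local wind speed(s), m/s, non-negative.
#' @param params a [thermo_params()].
#' @return Wind-chill temperature(s), degC.
#' @export
wind_chill <- function(Texp, u_local, params = thermo_params()) {
  if (any(u_local < 0)) stop("wind speed must be non-negative")
  u_f <- if (params$wind_unit_convention == "kmh") u_local * 3.6 else u_local
  windy <- u_local > params$calm_threshold
  out <- Texp
  if (any(windy)) {
    uw <- u_f[windy]^0.16
    raw <- 13.12 + 0.6215 * Texp[windy] - 11.37 * uw +
      0.3965 * Texp[windy] * uw
    out[windy] <- pmin(raw, Texp[windy])
  }
  out
}

#' Thermo-neutral-zone state
#'
#' `cold` below the LCT, `hot` above the UCT, `neutral` in between with both
#' boundaries inclusive to neutral.
#'
#' @param Twc wind-chill temperature(s), degC.
#' @param params a [thermo_params()].
#' @return Factor with levels `cold`, `neutral`, `hot`.
#' @export
tnz_state <- function(Twc, params = thermo_params()) {
  out <- rep("neutral", length(Twc))
  out[Twc < params$LCT] <- "cold"
  out[Twc > params$UCT] <- "hot"
  factor(out, levels = c("cold", "neutral", "hot"))
}

#' Behavioural drive acceleration magnitude
#'
#' Piecewise-linear relation between wind-chill temperature and the drive
#' acceleration `b`: zero inside the TNZ, `b_scale * (LCT - Twc)` (positive,
#' toward the huddle centre) below the LCT, and `b_scale * (UCT - Twc)`
#' (negative, away from the centre) above the UCT.
#'
#' @param Twc wind-chill temperature(s), degC.
#' @param params a [thermo_params()].
#' @param b_scale gain, m s^-2 per degC (positive).
#' @return Signed acceleration magnitude(s), m s^-2.
#' @export
behavior_accel <- function(Twc, params = thermo_params(), b_scale = 0.04) {
  if (b_scale <= 0) stop("b_scale must be positive")
  out <- numeric(length(Twc))
  cold <- Twc < params$LCT
  hot <- Twc > params$UCT
  out[cold] <- b_scale * (params$LCT - Twc[cold])
  out[hot] <- b_scale * (params$UCT - Twc[hot])
  out
}

#' Heat-loss versus group-size diagnostic
#'
#' Reproduces the comparison between the `n^(-1/4)` surface-reduction model
#' and this model's implicit proximity effect: for each group size `n`, a
#' packed disc of birds is built, the focal (central) bird's exposed and
#' wind-chill temperatures are computed from one coupling interval of
#' neighbour heat, and its metabolic loss is reported relative to a lone
#' bird. Never used by the main loop.
#'
#' @param n_values group sizes to evaluate.
#' @param Ta ambient temperature (degC).
#' @param u0 free-stream wind speed (m/s).
#' @param pack_density packing density of the synthetic disc (birds/m^2).
#' @param coupling_dt coupling interval (s).
#' @param params a [thermo_params()].
#' @param spec a [kernel_spec()].
#' @return Data frame with `n`, `relative_loss` (this model) and
#'   `area_reference` (`n^(-1/4)`).
#' @export
heatloss_comparison <- function(n_values = c(1, 2, 5, 10, 20, 50, 100),
                                Ta = -28, u0 = 10, pack_density = 3,
                                coupling_dt = 30,
                                params = thermo_params(),
                                spec = kernel_spec()) {
  loss_for <- function(n) {
    col <- make_fixture_colony(n, domain = c(60, 60), seed = 1,
                               pattern = "disc",
                               disc_radius = max(sqrt(n / pack_density / pi),
                                                 0.3),
                               center = c(30, 30))
    MR0 <- metabolic_heat(Ta, params)
    dT <- local_temperature_increase(col$x, col$y, rep(MR0, n),
                                     qx = 30, qy = 30,
                                     coupling_dt = coupling_dt,
                                     params = params, spec = spec)
    # neighbours shelter the focal bird in proportion to local crowding
    u <- u0 * max(0, 1 - n / 50)
    Twc <- wind_chill(exposed_temperature(Ta, dT), u, params)
    metabolic_heat(Twc, params)
  }
  rel <- vapply(n_values, loss_for, numeric(1))
  data.frame(n = n_values, relative_loss = rel / rel[1],
             area_reference = area_reduction_reference(n_values))
}
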