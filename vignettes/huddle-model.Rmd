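---
title: "The coupled wind-behaviour huddle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The coupled wind-behaviour huddle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huddlesim)
```

## The model

`huddlesim` simulates emperor-penguin huddle formation as a two-way coupled
system: an Eulerian finite-difference solver for the near-ground wind and
temperature field, and a Lagrangian agent model in which each penguin is a
smoothed-particle-hydrodynamics (SPH) particle. The coupling runs both ways:
birds obstruct and shelter the wind, deposit metabolic heat into the air,
and in turn sample the local wind and temperature to decide where to walk.

### Wind field

The wind obeys the 2D incompressible Navier-Stokes equations, discretised on
a staggered (MAC) grid and advanced with a projection method: an explicit
momentum predictor (conservative donor-cell advection plus viscous
diffusion), a pressure Poisson solve with red-black SOR, and a velocity
correction that renders the field discretely divergence-free to the
configured tolerance. The staggered arrangement prevents the checkerboard
pressure modes a collocated scheme would need special treatment for. At the
default grid spacing the cell Reynolds number is of order $10^5$, where a
central-difference advection operator oscillates without upwinding; the
donor-cell fluxes trade formal second-order accuracy for monotone, robust
wakes, which is the feature of the flow the behaviour model consumes.

Air enters through one short edge at `inflow_speed` (flowing along the
100 m axis by default), leaves through a zero-gradient outflow where the
pressure is pinned, and slips freely along the lateral walls. Birds are
stamped onto the grid as a stair-step obstacle mask; masked faces carry zero
velocity. Fluid pockets fully enclosed by the stamped huddle are frozen for
the wind update — they would otherwise form pure-Neumann islands for the
pressure solve and trap recirculating momentum that has no physical outlet.

Because the flow relaxes in seconds while the colony rearranges over
minutes, the wind is treated as quasi-steady: after each obstacle-mask
update the solver runs a fixed number of predictor/Poisson/projection
cycles (`quasi_steady_steps`, continuing from the previous state) rather
than integrating every 0.01 s step across the full two simulated hours. A
convergence property test checks that doubling the cycle count moves probe
wind speeds by less than 2%.

### Penguins as SPH particles

Field quantities are interpolated between birds with the classic 2D cubic
spline kernel $W(r,h)$ of compact support $2h$, $h = 10$ m, normalised by
$10/(7\pi h^2)$ so the kernel integrates to one over the plane (the other
normalisation sometimes printed for this kernel, $7\pi/10h^2$, does not,
and is kept only behind a compatibility flag). SPH density is the standard
summation $\rho_j = \sum_i m_i W_{ji}$ including the self term, so a lone
bird has density $m\,W(0,h)$ and density is always positive. Penguin "mass"
is a bookkeeping constant (1 per bird): only ratios $m/\rho$ enter the
interpolation, so density is effectively a smoothed local number density.

Two distinct length scales act on the colony:

* **Perception and warmth** use $h = 10$ m: how far a bird's released heat
  reaches and over what neighbourhood crowding is perceived.
* **Body exclusion** uses `repulsion_h = 0.5` m (one body diameter). The
  repulsive pressure force is the symmetric SPH momentum term
  $-\sum_i m_i (P_i/\rho_i^2 + P_j/\rho_j^2)\nabla_j W_{ji}$ evaluated with
  this short kernel. A single 10 m kernel cannot prevent body overlap: the
  spline gradient vanishes toward the origin, so sub-metre crowding would be
  unresisted and the colony would collapse to a point (we verified exactly
  that in early experiments). With the body-scale kernel an overlapping
  pair already raises the local density above the rest density and is
  pushed apart.

The pressure itself needs an equation of state, and there is no canonical
choice for behavioural particles; we close it with the simplest
compression-only law
$P = k\,\max(\rho - \rho_0, 0)$. The rest density $\rho_0 = 2.8$ birds
m$^{-2}$ is the typical observed winter huddle packing, so pressure engages
exactly when a huddle compresses beyond natural packing; the stiffness
$k = 10$ makes the resulting acceleration comparable to the strongest
thermal drive, so compression stalls just above $\rho_0$. Huddle density is
therefore an emergent balance, not a prescribed value, but its scale is
anchored to an observable.

### Thermoregulation

Each bird produces metabolic heat $MR = C\,A\,(T_b - T_a)$ with
conductance $C = 0.104$ W/°C, body temperature $T_b = 37.7$ °C and exposed
area factor $A = 1$ (the $A = n^{-1/4}$ group-size reduction is kept only
as a diagnostic reference curve: in this model proximity effects emerge
from sheltering and shared warmth instead of being imposed). The heat
released over a coupling interval is spread over a cubic-spline footprint
and converted to an air-temperature anomaly against the heat capacity of a
1.2 m air column ($C_{air} = 1000$ J kg$^{-1}$ °C$^{-1}$,
$\rho_{air} = 1.4224$ kg m$^{-3}$). The spreading kernel's smoothing
length, $h\sqrt{10/28} \approx 6$ m, is fixed by requiring its peak value
to equal the dilution of the kernel-cylinder volume
$V_{air} = \pi (h/2)^2 \times 1.2$ m$^3$: a lone bird then warms the air at
its own position by exactly $MR\,\Delta t / (C_{air}\rho_{air}V_{air})
\approx 1.5\times10^{-3}$ °C per 30 s interval, while the column-integrated
deposit equals the energy released. Deposits accumulate in a grid anomaly
field $\theta \ge 0$ that the wind transports, so warmth builds up over the
run wherever the colony blocks the flow. A density-normalised
(Shepard-average) variant of the deposit is available as
`deposit_mode = "shepard"` for comparison; it averages rather than sums
neighbour heat and cannot reproduce multi-degree huddle warming.

Anomaly transport uses dimensionally split, flux-form implicit
(backward-Euler) upwind sweeps — unconditionally stable, conservative up to
boundary fluxes, and positivity-preserving — because stair-step corner jets
around the huddle reach several times the free-stream speed and would force
thousands of explicit CFL substeps per interval. Anomaly diffusivity
defaults to the molecular value for air ($2\times10^{-5}$ m$^2$/s):
transport is advection-dominated, and in sensitivity runs any diffusivity
large enough to warm the huddle rim measurably ($\gtrsim 0.02$ m$^2$/s)
drained the interior faster than the colony could heat it.

A bird's exposed temperature is $T_{exp} = T_a + \Delta T$, with $T_a$ the
ambient temperature plus the anomaly sampled from the four grid nodes
around the bird (masked nodes are excluded from the wind average; a bird
whose whole neighbourhood is masked is fully sheltered). Wind chill follows
the North American index, piecewise: identity at or below the 1.3 m/s calm
threshold, and the standard polynomial in $T_{exp}$ and $u^{0.16}$ above
it. The formula is defined for wind speed in km/h; both that reading
(`wind_unit_convention = "kmh"`) and a literal m/s application (`"ms"`, the
reference-scenario default) are provided, and the result is clamped never
to exceed $T_{exp}$.

### Behaviour

The thermo-neutral zone (TNZ) spans $-10$ to $+20$ °C, boundaries
inclusive. The drive acceleration is piecewise linear in the wind-chill
temperature: zero inside the TNZ, `b_scale * (LCT - Twc)` toward the colony
centre of mass below it, and the mirrored law away from the centre above
it. `b_scale = 0.04` m s$^{-2}$ °C$^{-1}$ is set so a bird at the coldest
initial wind chills (roughly 25 °C below the lower critical temperature)
reaches the 0.5 m/s walking-speed cap within one behaviour step. The
momentum balance contains no friction, so an unopposed drive would
accelerate without bound; we integrate it in the overdamped (kinematic)
limit instead: each 0.5 s substep recomputes velocity from the current
forces, caps the speed, and steps positions with explicit Euler. Neutral,
uncrowded birds therefore stand still. Drive is frozen over each 30 s
coupling interval; repulsion and the centre of mass are refreshed every
substep. Positions are clamped one body radius inside the domain with the
wall-normal velocity zeroed.

### The coupling loop

Every 30 s interval: stamp the obstacle mask and relax the wind to
quasi-steady; sample each bird's local temperature and wind; compute
metabolic rates; deposit the interval's heat and form exposed temperatures;
apply wind chill; derive TNZ states, drive accelerations and repulsion
pressures; run the behaviour substeps with the wind frozen; transport the
anomaly field over the interval. All randomness enters through the seeded
initial placement (uniform with one-body-diameter rejection sampling), so a
configuration plus seed reproduces a run bit for bit.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `h` | 10 | m | perception/warmth smoothing length |
| `repulsion_h` | 0.5 | m | body-exclusion smoothing length |
| `body_radius` | 0.25 | m | body size: motion, walls, separation |
| `blocking_radius` | 0.35 | m | aerodynamic footprint stamped on the wind mask |
| `max_speed` | 0.5 | m/s | walking-speed cap |
| `b_scale` | 0.04 | m s^-2 / °C | thermal drive gain |
| `k`, `rho0` | 10, 2.8 | -, birds/m^2 | repulsion EOS stiffness and rest density |
| `ambient_temperature` | -28 | °C | background air temperature |
| `inflow_speed` | 10 | m/s | free-stream wind |
| `dx` | 0.25 | m | grid spacing (equals the body radius) |
| `dt_wind` | 0.01 | s | wind solver step (inflow CFL 0.4) |
| `coupling_interval` | 30 | s | wind/behaviour exchange period |
| `theta_kappa` | 2e-5 | m^2/s | anomaly diffusivity |

The `blocking_radius` deserves a note: stamping birds at their literal
0.25 m body radius leaves roughly half the huddle floor as open cells, and
the solver then blows unimpeded free-stream air through 0.3 m interstitial
channels — aerodynamic nonsense at sub-grid scale, and the huddle never
warms. Packed birds seal those gaps with plumage and body boundary layers,
so the stamped footprint uses half the nearest-neighbour spacing at
observed packing (0.35 m). The stamp also always covers at least the cell
containing the bird on grids coarser than the footprint.

Several quantities that no field measurement pins down for this idealised
scenario (ambient temperature, inflow speed, the EOS closure, `b_scale`,
`blocking_radius`) were fixed once during model design, each anchored to an observable or a
stated constraint as described above, and are configuration, not code.

## What the synthetic scenarios do and do not show

The scenario generator places colonies uniformly at random (with
rejection), or in packed discs and cluster pairs for metric tests. It
emulates the idealised study conditions: a flat, featureless fast-ice
plane, constant ambient temperature, steady unidirectional wind, identical
birds, and a single huddle nucleating at the colony centre of mass. It does
not emulate terrain, gusts or direction changes, solar radiation, humidity,
size- or state-structured colonies, or multiple huddle nucleation sites —
so passing tests support the mechanism (individual thermoregulation
suffices for huddle formation and its observed spatial structure), not
quantitative prediction for any real colony.

## Numerical choices and degenerate inputs

* Pressure solves warm-start from the previous interval; non-convergence
  within `ppe_max_iter` raises a warning and a flag, never a silent result.
* The advective CFL condition is enforced against the realised maximum
  speed, not just the inflow; violations abort with advice to reduce
  `dt_wind`. The default steps leave headroom for about 2.5x bluff-body
  speed-up.
* A bird exactly at the colony centre of mass gets zero drive (any
  direction is arbitrary; repulsion resolves crowding).
* Colonies too dense to place at one-body-diameter separation fail fast at
  initialisation; `n = 0` colonies and empty summaries are errors, and a
  single-bird summary reports SD 0 with a degeneracy flag.
* Huddle identification is single-linkage clustering at 1 m (twice the
  body diameter); size ties break toward the lower centroid-x cluster and
  are flagged; a largest cluster holding under half the colony sets the
  dispersed flag and density falls back to colony count over domain area.
  The huddle circle uses the 90th-percentile member radius — robust to
  stragglers, unlike a convex hull.
* Sector labels: interior inside 0.75 of the huddle radius, then
  windward/leeward/side by 45-degree cones about the upwind axis; these
  two thresholds are free parameters with stated defaults.

## Problem sizes used in the checks

The package's own test suite runs the full 50 m x 100 m domain and the full
two-hour schedule, but on a 0.5 m grid (with `dt_wind` rescaled to keep the
same CFL number) for the long statistical runs; the 0.25 m reference grid
is exercised on shorter horizons. The coarse grid runs the identical
physics about five times faster; its known cost is a thicker flushed rim
(one 0.5 m cell instead of one 0.25 m cell), which biases rim birds cold
and makes coarse-grid in-TNZ percentages mildly conservative.

## Known limitations

* The wind model is 2D and laminar-with-numerical-diffusion; there is no
  turbulence closure, so wake recovery lengths are indicative only.
* Heat transport ignores buoyant convection; warmth leaves the huddle only
  by advection and (weak) diffusion.
* The drive targets the global centre of mass, a deliberate simplification:
  one huddle forms at a prescribed location. Nearest-
  neighbour or perceived-group targeting, multiple huddles, and huddle
  breakup dynamics above the upper critical temperature are out of scope
  (the breakup drive exists but is untuned).
* First-order upwinding (momentum and anomaly) smears sharp fronts by
  design; quantities defined on scales near one cell (for example the rim
  temperature of the huddle) carry O(dx) bias.
* The windward/leeward temperature contrast comes out inverted relative to
  field observations: around a sealed 2D bluff huddle the windward
  stagnation region is becalmed and retains deposited warmth, while the
  wake continuously flushes the leeward rim, so the model's leeward birds
  are slightly the colder ones. Reproducing the observed windward
  disadvantage appears to need either three-dimensional over-body flow or
  a porous obstacle coupling — and a porous huddle loses its interior
  warming entirely in this model, so the sealed huddle is kept.
* The colony-wide in-TNZ fraction equilibrates near 60–65% under the
  default conditions: the flushed one-cell rim keeps the perimeter ring
  below its lower critical temperature regardless of how warm the interior
  becomes, and this fraction is insensitive to grid refinement from 0.5 m
  to 0.25 m.
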