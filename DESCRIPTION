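Package: huddlesim
Title: Coupled Fluid-Behaviour Simulation of Emperor Penguin Huddling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-way coupled simulation of emperor penguin huddle formation.
    A finite-difference incompressible Navier-Stokes solver computes the wind
    and near-ground temperature-anomaly fields on a fixed grid, while penguins
    are modelled as smoothed-particle-hydrodynamics (SPH) agents whose motion
    is driven by thermoregulation: metabolic heat release, kernel-weighted
    local warming, wind chill, and a thermo-neutral-zone behaviour rule.
    Penguins feed back on the flow as obstacles and as distributed heat
    sources. Includes huddle statistics (membership, density, windward and
    leeward sector classification, radial profiles) and deterministic, seeded
    scenario presets for colonies of 100, 200, and 800 birds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
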