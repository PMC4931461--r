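Package: drywet
Title: Reversible Polymerization Under Limited Diffusion and Wet-Dry Cycling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of reversible condensation polymerization on a lattice
    when diffusion is restricted and the environment alternates between wet
    and dry phases. Provides the exactly solvable mean-field theory of dimer
    formation (equilibrium with and without diffusion, and the wet-dry
    cycling map with its closed-form fixed point), the well-mixed polymer
    equilibrium theory (Flory-type exponential length distribution, strand
    concentration kinetics, Poisson site occupancy), a fixed-timestep
    stochastic lattice simulator of polymerization with hopping, scrambling,
    wet-phase hydrolysis and monomer influx, and scenario presets that
    reproduce the canonical diffusion, no-diffusion, cycling and influx
    experiments together with their analytic overlays.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
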