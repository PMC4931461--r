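# drywet

Models of reversible condensation polymerization when diffusion is
limited and the environment cycles between wet and dry phases — the
setting usually invoked for prebiotic synthesis of RNA-like polymers.
Bond formation releases water, so it is favourable only in the dry
phase; the wet phase hydrolyzes bonds but redistributes molecules and
can deliver fresh monomers. The package quantifies when cycling helps,
by how much, and what bounds it can never beat.

It is aimed at people building or checking origin-of-life polymerization
models: every analytic limit is implemented in closed form, every
simulated scenario is reproducible from a single seed, and simulation
and theory cross-validate each other in the test suite.

## What is implemented

**Dimer mean-field model.** Sites hold 0–2 monomers or a dimer;
monomers condense at rate *k⁺*, dimers break at *k⁻* (*K = k⁺/k⁻*),
monomers hop at rate *h*. Closed forms for the equilibrium with
diffusion, the local equilibrium without diffusion
(*P_D = Kφ²/(1+K)*), and the wet–dry cycling map

> P_D(dry) = K/(1+K) · (P_D + (φ−P_D)²/(1−P_D)),  P_D(wet) = P_D(dry)·e^(−w·t_wet)

whose fixed point is the quadratic root returned by
`dimer_cycling_limit()`. The ordering
*no-diffusion < cycling < diffusion* is the model's central claim.

**Well-mixed polymer theory.** Flory-type geometric equilibrium
C_m = a·x^(m−1) with (1−x)² = x/(Kμ), mean length m̄ = 1/(1−x), strand
concentration λ solving Kλ² = μ−λ, Poisson site occupancy, and the
strand-count kinetics dC_tot/dt = −k⁺C_tot² + k⁻(μ−C_tot).

**Stochastic lattice simulator.** Fixed-timestep Monte Carlo on an
L×L torus (C++ core, R's RNG): per-site bond formation at
k⁺n(n−1)δt, per-strand hydrolysis at k⁻(m−1)δt, Moore-neighbourhood
hopping, global scrambling (the well-mixed limit), wet phases with
hydrolysis rate *w*, and Poisson monomer influx with mean
Nb(1−μ/μ_max)δt.

**Scenario presets.** `run_scenario()` reproduces the canonical
experiments — diffusion, no diffusion, cycling with and without wet
hydrolysis, and influx — with theory overlays, plus deterministic CSV/JSON
output (`write_run_outputs()`), YAML configs (`load_config()`), and a
thin CLI at `inst/cli/polysim.R`.

## Worked example

```r
library(drywet)

# analytic dimer limits at phi = 0.2, K = exp(2), w = 1, t_wet = 0.5
dimer_cycling_limit(0.2, exp(2), w = 1, t_wet = 0.5)
#>     PD_wet     PD_dry
#> 0.03305866 0.05450451

# equilibrium mean polymer length at K = exp(4), mu = 2
mean_length_equilibrium(exp(4), 2)
#> [1] 10.96166

# cycling with repositioning but no wet hydrolysis reaches that equilibrium
set.seed(42)
run <- run_scenario("polymer-cycling-nohydrolysis", L = 50, n_cycles = 50,
                    record_every = 25L)
run
#> drywet run: scenario 'polymer-cycling-nohydrolysis'
#>   series: 3200 rows
#>   final mean length: 10.64 (theory equilibrium 10.96)
long_run_mean(run)
#> [1] 10.58383
```

The dimer numbers say: under cycling the dimer fraction oscillates
between 0.033 (end of wet phase) and 0.055 (end of dry phase) — well
above the 0.035 a single dry phase without diffusion can ever reach, and
below the 0.093 diffusive ceiling. The lattice run shows a single seed
of the no-hydrolysis cycling scenario settling around the well-mixed
equilibrium mean length of ~11 monomers (individual seeds fluctuate by a
few tenths; replicate means agree with theory within standard errors).

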