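---
title: "Reversible polymerization under limited diffusion and wet-dry cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversible polymerization under limited diffusion and wet-dry cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drywet)
set.seed(1)
```

## The question the models address

Condensation polymerization — the chemistry that builds nucleic-acid and
peptide backbones — releases a water molecule per bond, so it is
thermodynamically uphill in bulk water and downhill only at low water
activity. A recurring proposal for prebiotic polymer synthesis is an
environment that alternates between dry phases (bonds can form, but
molecules barely move) and wet phases (bonds hydrolyze, but molecules are
redistributed and fresh monomers can arrive). `drywet` implements the
minimal models that make this intuition quantitative: an exactly solvable
dimerization model, the well-mixed theory of reversible polymerization,
and a stochastic lattice simulator with cycling protocols and monomer
influx.

The central result the models exhibit is kinetic, not thermodynamic: if
diffusion were possible in the dry phase, a single dry phase would reach
the best achievable equilibrium, and any wet interlude could only lose
bonds. Cycling matters because dry-phase diffusion is *not* possible:
repeated redistribution lets the system escape the poor local equilibrium
of isolated sites and climb toward — but never beyond — the diffusive
equilibrium.

## Dimer model

Sites of a lattice hold 0, 1 or 2 monomers or 1 dimer, with fractions
$P_0, P_1, P_2, P_D$. Two monomers on a site condense at rate $k^+$,
dimers break at rate $k^-$, $K = k^+/k^-$, and monomers hop at rate $h$.
In the mean-field rate equations (`dimer_meanfield()`) the only hopping
process that changes site counts is $2 + 0 \leftrightarrow 1 + 1$, which
is why the dimer hopping rate drops out of the theory entirely and has no
slot in `dimer_params()`. Two quantities are conserved: the vacancy
fraction $P_0 + P_1/2$ and the occupied fraction $P_1/2 + P_2 + P_D$.
These conservation laws are the main correctness surface for the
integrator, so the default relative tolerance is tight (`1e-9`).

Three regimes have closed forms:

* **diffusion permitted** — `dimer_equilibrium_diffusion()` solves the
  simultaneous balance conditions (dimer balance $P_D = K P_2$, diffusion
  balance $4 P_0 P_2 = P_1^2$);
* **no diffusion** — the reactive pool is frozen at $P_2 + P_D = \phi^2$
  and `dimer_local_equilibrium()` gives $P_D = K\phi^2/(1+K)$;
* **cycling** — each cycle redistributes molecules
  (`dimer_cycle_start()`), relaxes the dry phase, and applies wet decay
  $e^{-w t_{wet}}$; the fixed point of the map has the closed form in
  `dimer_cycling_limit()`.

```{r dimer}
dimer_equilibrium_diffusion(0.2, exp(2))[["PD"]]
dimer_local_equilibrium(0.2, exp(2))
dimer_cycling_limit(0.2, exp(2), w = 1, t_wet = 0.5)
```

The ordering *local equilibrium < cycling limit < diffusive equilibrium*
holds for every $\phi \in (0,1)$, $K > 0$, $w\,t_{wet} > 0$, and the
cycling limit collapses onto the diffusive equilibrium as
$w\,t_{wet} \to 0$. Both properties are asserted numerically over
parameter grids in the test suite.

All three quadratics in the package (diffusive equilibrium, cycling
limit, and the polymer decay ratio below) are evaluated in the conjugate
("multiply by the conjugate root") form. The naive root
$\tfrac12(B - \sqrt{B^2 - 4c})$ loses precision exactly in the
interesting regimes (large $K$, small $w\,t_{wet}$), where the
discriminant approaches $B^2$; the conjugate form $2c/(B + \sqrt{B^2 -
4c})$ is stable there and makes the $K \to 0$ and $K \to \infty$ limits
exact. Degenerate $k^- = 0$ is treated as $K = \infty$ and dispatched to
the stated limits rather than evaluated as an indeterminate expression.

The cycling map runs in two modes. The default `"local-equilibrium"`
mode assumes the dry phase is long enough to complete its first-order
relaxation, which is the regime where the closed-form limit applies; the
`"finite"` mode uses the exact relaxation `dimer_relax()` for a dry
phase of duration $t_{dry}$. The two agree to $10^{-6}$ once
$t_{dry} \gtrsim 20/(k^+ + k^-)$, which is also tested. Iteration stops
when the relative change in the wet-phase value drops below $10^{-12}$
or the cycle budget is exhausted, and the flag is reported on the result.

## Well-mixed polymer theory

For strands of identical monomers joining at $k^+$ and hydrolyzing at
$k^-$ per bond, the equilibrium length distribution is geometric
(Flory's most probable distribution), $C_m = a x^{m-1}$ with $a = x/K$,
because that form satisfies detailed balance for every split
$k^+ C_n C_m = k^- C_{n+m}$. Fixing the monomer concentration
$\sum_m m C_m = \mu$ gives $(1-x)^2 = x/(K\mu)$, solved by
`equilibrium_x()`. The mean length is $\bar m = 1/(1-x) = \mu/\lambda$,
with $\lambda$ the total strand concentration solving
$K\lambda^2 = \mu - \lambda$. The kinetics of the strand count obeys the
single closed equation implemented in `integrate_ctot()`:
$\dot C_{tot} = -k^+ C_{tot}^2 + k^-(\mu - C_{tot})$. The package does
not implement the full per-length kinetic hierarchy $C_m(t)$: it is only
valid in the well-mixed limit, which is exactly the regime where the
single $C_{tot}$ equation already answers the question.

```{r wellmixed}
equilibrium_x(exp(4), 2)
mean_length_equilibrium(exp(4), 2)
mean_length_equilibrium(exp(4), 20)
```

The default length cutoff of `equilibrium_length_distribution()` is the
smallest $m_{max}$ retaining $1 - 10^{-9}$ of the monomer mass; the
excluded tail is computed in closed form and attached to the result, so
truncation error is always reportable rather than silent.

## Lattice simulator

`lattice_init()` scatters $M_{tot}$ monomers over an $L \times L$ torus
(sites have no occupancy cap). Each fixed timestep $\delta t$,
`dry_run()` performs, in order: one bond-formation pass over sites
(probability $k^+ n(n-1)\delta t$ on a site with $n$ strands, joining
two distinct uniformly chosen strands), one hydrolysis pass over strands
(probability $k^-(m-1)\delta t$, uniform break point, fragments staying
on the parent site and not re-broken within the step), and one hopping
pass (probability $h\,\delta t$, uniform Moore neighbour, always
accepted). `wet_phase()` applies hydrolysis at rate $w$ with no bond
formation, then moves every strand to a random site; `scramble()` after
every step realizes the well-mixed limit. The inner sweeps are C++
(via Rcpp) drawing from R's RNG, so a single `set.seed()` makes an
entire run, including its CSV outputs, bit-reproducible.

Numerical choices worth stating explicitly:

* *At most one bond per site and one break per strand per step.* This is
  the discretization that defines the model; probabilities are clamped
  at 1 and every clamp is counted in `clamp_count`, so discretization
  stress is visible in run metadata instead of silently biasing rates.
  With the default $\delta t = 0.01$ and the canonical parameter sets,
  clamps occur only in deliberately extreme test states.
* *Periodic boundaries.* Edge effects would otherwise contaminate the
  comparison with the spatially homogeneous mean-field theory.
* *Strands are lengths.* With a single monomer type, concatenation
  order is meaningless, so a strand is represented by its length only.
* *Influx is Poisson.* `apply_influx()` adds a Poisson-distributed
  number of monomers with mean $N b (1 - \mu/\mu_{max})\delta t$ —
  independent arrivals with the prescribed mean; the ensemble density
  follows $\dot\mu = b(1 - \mu/\mu_{max})$. In cycling scenarios the
  influx operates during wet steps; in the diffusive scenario during dry
  steps. Newly added monomers count toward the mean length immediately,
  which is why the mean length dips during influx wet phases even when
  $w = 0$.

The well-mixed equivalence of the simulator is checked two independent
ways: the scrambling run tracks the $C_{tot}$ kinetics within replicate
standard errors, and a one-site three-monomer system (built as an
`lattice_state_from()` configuration with hopping disabled, so the site
is exactly an isolated reactor) matches the stationary distribution of
the corresponding three-state continuous-time Markov chain computed by
linear algebra.

## Scenarios and what the experiments show

`run_scenario()` names the five canonical experiments, with presets
pinning the standard parameters ($k^+ = 1$, $K = e^4$, $\mu = 2$,
$w = 0.2$, $t_{dry} = 8$, $t_{wet} = 0.5$, $b = 5$, $\mu_{max} = 20$;
$K = e^2$, $\phi = 0.2$, $w = 1$ for the dimer map). Long-run values are
taken as the average of the recorded mean length over the final quarter
of a run — a deliberately simple equilibration convention, paired with
run lengths of roughly ten times the relaxation time of the
corresponding well-mixed kinetics.

```{r scenarios}
run <- run_scenario("polymer-cycling", L = 25, n_cycles = 20, seed = 1,
                    record_every = 25L)
run
long_run_mean(run)
```

At matched parameters the long-run mean lengths order as: no diffusion
< cycling with hydrolysis < cycling without hydrolysis ≈ diffusive
equilibrium; and wet-phase influx cycling far exceeds fixed-$\mu$
cycling because the higher monomer density shifts the equilibrium toward
longer chains.

Problem sizes: the package's own validation suite runs the lattice at
$L = 50$ ($N = 2500$ sites, 5000 monomers at $\mu = 2$) with 10
replicate seeds and horizons of 400 time units (50 cycles for cycling
runs). These sizes put replicate standard errors of the long-run mean
length near 0.05 monomers, tight enough to resolve every ordering and
equivalence claim above; the canonical $L = 100$ lattice is the preset
default for interactive use.

## What the generator does and does not emulate

The synthetic lattice runs emulate: random initial placement, reversible
single-monomer-type chemistry with a uniform bond free energy,
length-independent hopping, instantaneous wet/dry switching, and
monomer influx with a density ceiling. They deliberately do not emulate
sequence-dependent rates, template-directed synthesis,
structure-dependent hydrolysis, gradual drying, or length-dependent
diffusion. Passing tests therefore demonstrate the internal consistency
of this idealized model and its analytic limits — they do not by
themselves predict yields for any real nucleotide chemistry, where all
of the omitted effects are known to matter.

## Known limitations

* The mean-field dimer theory ignores spatial correlations between
  neighbouring sites; it is exact only in the fast- or global-hopping
  limit. No stochastic realization of the dimer model is provided.
* The fixed-timestep scheme has $O(\delta t)$ bias; the suite checks
  that halving $\delta t$ leaves ensemble means unchanged within
  sampling error at the default settings, but very large $k^+ n(n-1)$
  or $w(m-1)$ products require a smaller $\delta t$ (watch
  `clamp_count`).
* Long-run averages use a fixed final-quarter window rather than a
  formal equilibration diagnostic; for slow-diffusion runs ($h \ll
  0.1$) the window must be checked against the trajectory by eye.
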