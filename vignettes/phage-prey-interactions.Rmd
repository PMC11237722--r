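---
title: "Generalist and specialist phage on interacting bacterial prey: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalist and specialist phage on interacting bacterial prey: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagetrade)
```

## The question

Lytic bacteriophage range from strict specialists, able to infect a single
bacterial species, to generalists with broad host range. Whether ecology
favors one strategy over the other should depend not only on trade-offs
internal to the phage (the "jack of all trades, master of none" penalty) but
on the ecology of the prey themselves. `phagetrade` implements a
phenomenological model built to ask exactly this: two bacterial prey that
either compete for resources or feed each other obligately, attacked by one
generalist phage (both hosts) and one specialist phage (one host), all under
chemostat-like dilution.

## The model

Dimensionless biomasses $E$ and $S$ (the two prey), $G$ (generalist phage)
and $P$ (specialist phage, infecting only $S$) evolve as

$$\frac{dE}{dt} = \mu_E E \frac{\alpha_{ES} S}{\alpha_{ES} S + \kappa_E}
  \left(R - E - \beta_{ES} S\right) - \varsigma_{EG} G E - \delta_E E$$

$$\frac{dS}{dt} = \mu_S S \frac{\alpha_{SE} E}{\alpha_{SE} E + \kappa_S}
  \left(R - S - \beta_{SE} E\right) - \varsigma_{SP} P S
  - \varsigma_{SG} G S - \delta_S S$$

$$\frac{dG}{dt} = \gamma_{SG} \varsigma_{SG} G S
  + \gamma_{EG} \varsigma_{EG} G E - \delta_G G, \qquad
\frac{dP}{dt} = \gamma_{SP} \varsigma_{SP} P S - \delta_P P$$

Prey grow logistically toward a shared carrying capacity $R$; the saturating
bracket encodes obligate cross-feeding (each prey needs its partner's
metabolite; half-saturation $\kappa$). Phage convert adsorption (attachment
rate $\varsigma$, per biomass per time) into progeny (burst size $\gamma$)
and die or wash out at rate $\delta$.

Two *pure* interaction presets span the ecology
(`preset_params()`):

* **competition** — $\kappa = 0$ (bracket $\equiv 1$, including the $0/0$
  point when the partner is absent), $\beta = 1$, $R = 2$;
* **mutualism** — $\kappa = 1$, $\beta = 0$, $R = 1$.

All other defaults are shared: $\mu = 0.5$, $\gamma = 20$,
$\varsigma = 10^{-3}$, $\delta = 0.03$, $\alpha = 1$. The competition
carrying capacity is doubled because obligate mutualism inflates equilibrium
biomass above $R$; the two presets then settle at the same total prey
biomass. The parameter table also stores a specialist burst size and
attachment rate on prey $E$; these fields are deliberately inert — the
specialist's dynamics contain only the $S$ terms — and exist so that every
tabulated symbol has a home.

A *cost of generalism* (`apply_cost()`) gives the specialist an advantage
along one of three channels: a larger burst size
($\gamma_{SP} = r\,\gamma_{SG}$), a larger attachment rate
($\varsigma_{SP} = r\,\varsigma_{SG}$), or a survival advantage (death
rates re-based to $0.0067$ for prey and specialist, with
$\delta_G = r \times 0.0067$). Because the first two scale one factor of the
product $\gamma_{SP}\varsigma_{SP}$, both act on the same product scale, and
every threshold we locate agrees between them (this is tested).

## Numerical choices

**Integration.** LSODA (via `deSolve`), relative tolerance $10^{-8}$,
absolute tolerance $10^{-12}$. The tight absolute tolerance is not
gratuitous: the extinction floor sits at $10^{-12}$, and the solver must
resolve densities near the floor for clamping to behave deterministically.

**Extinction clamping.** Any species below $10^{-12}$ at an output sample is
set to exactly 0 and the integration restarts from that sample
(`integrate_community()`). Since every per-capita rate is proportional to
the species' own biomass, a clamped species stays at zero; this prevents
populations at physically meaningless densities (e.g. $10^{-80}$) from
resurging when conditions improve. Clamping therefore acts at the sampling
resolution (default: 1 time unit); dips below the floor shorter than one
sample are not registered. We chose sample-level clamping over event/root
detection after finding root location at the floor numerically fragile in
oscillatory regimes whose troughs skim the floor tangentially.

**Steady state.** `run_to_steady_state()` integrates in growing chunks and
declares convergence when every species' excursion over a trailing window
(default 100 time units) drops below $10^{-9}$, capped at
$t_{\max} = 10^5$. Limit-cycle regimes — the competition preset with the
generalist is one — never converge pointwise; they are summarized by the
trailing-window time average and flagged `converged = FALSE` so sweeps can
mark those cells. The convergence tolerance and window are package
conventions: the underlying protocol ("integrate until abundances no longer
change") names no tolerance.

**Fixed points.** `enumerate_fixed_points()` solves the algebraic system
per presence/absence subset of the four species (absent species pinned to
zero), by damped Newton iteration from a deterministic lattice of starting
points, using the hand-derived Jacobian (`community_jacobian()`, verified
against central finite differences in the tests). Solving per subset rather
than on the full 4-D system avoids spurious roots with tiny negative
components. Stability is read from the full $4 \times 4$ Jacobian — the
rows of absent species are their invasion growth rates — with a marginality
band of $10^{-7}$ on eigenvalue real parts. Two degeneracies deserve note:

* under symmetric competition ($\beta = 1$) the prey equations pin only
  $E + S$, so prey-pair and prey-generalist equilibria form *lines* of
  fixed points; points on them are classified `marginal` (a zero eigenvalue
  along the line). This is why the competition preset with phage has no
  stable fixed point at all, only a neutrally stable family orbited by the
  transient dynamics;
* under obligate mutualism the origin is *always* stable: as both prey
  vanish the growth bracket shuts off and every per-capita rate tends to
  $-\delta$. Total extinction is a genuine attractor of the mutualistic
  community (the low-density prey root is the Allee-type saddle separating
  it from coexistence).

## Thresholds for the cost of generalism

`find_cost_threshold()` bisects the cost ratio (to $5 \times 10^{-3}$) on
one of two indicators:

* `density_crossing` — forward simulation from the study's standard initial
  condition (every species at 0.1): does the specialist's long-run density
  exceed the generalist's? At mutualism defaults with a burst-size cost the
  crossing sits at a ratio of about **2.09**.
* `only_stable_is_ESP` — the fixed-point battery: no stable fixed point
  contains the generalist, while the prey-pair + specialist coexistence
  point is stable. Because the origin is unconditionally stable under
  mutualism (above), trivial extinction states with both prey absent are
  disregarded by this indicator; demanding literally that *every* stable
  point be the E–S–P state would be unsatisfiable. At mutualism defaults
  this threshold computes to about **2.30**, identically for burst-size and
  attachment-rate costs (the product scale), and it is reproducible by hand:
  the specialist pins $S^\ast = \delta / (\gamma_{SP}\varsigma_{SP})$, the
  prey-$E$ equation then fixes $E$, and the generalist's invasion rate
  $\gamma_G \varsigma_G (E + S) - \delta$ changes sign where
  $S^2 - 0.56\,S - 0.06 = 0$, i.e. $S = 0.652$, ratio $= 1.5/S = 2.30$.
  Above it, forward simulation from strongly generalist-favoring initial
  conditions confirms the generalist is lost regardless of starting point.

Between the two thresholds (2.09–2.30) the four-species interior equilibrium
carries both phage with the specialist already in the majority; at 2.30 it
exchanges stability with the E–S–P point and the generalist's equilibrium
density passes through zero.

The analytic counterpart is the $S^\ast$ (R-star) criterion
(`sstar_criterion()`): treating the shared prey as the resource,
$S_P^\ast = \delta/(\gamma_P \varsigma_P)$ and
$S_G^\ast = \delta/(\gamma_G \varsigma_G) - E$, the specialist excludes the
generalist when $S_P^\ast < S_G^\ast$, equivalently
$\gamma_G\varsigma_G / \gamma_P\varsigma_P <
1 - \gamma_G \varsigma_G E / \delta$. The criterion can never hold without a
cost of generalism, and the threshold ratio it implies depends strongly on
the $E$ level assumed — from 2.0 at the generalist-held level $E = 0.75$ to
about 2.8 near $E = 0.97$ — which is why we treat the self-consistent
fixed-point battery, not the analytic inequality at a chosen $E$, as the
package's definitive threshold.

## Sweeps and the scenario battery

`scenario_battery()` reruns the four phage treatments (none / specialist /
generalist / both) from the standard initial condition. `sweep_cost()` and
`sweep_cost_by_asymmetry()` grid the cost ratio, alone or against a prey
asymmetry (growth rate of $E$ relative to $\mu_S = 0.5$, or the interaction
coefficient of $E$ relative to its partner's 1). Default grids are 30
log-spaced cost ratios in $[1, 10]$ and 30 asymmetry points in
$[0.25, 4]$ — wide enough to bracket every threshold above — and every cell
records final densities, the specialist's relative abundance
$P/(P+G)$, a convergence flag, and prey-exclusion flags; mutualism cells
whose prey pair collapses entirely are flagged infeasible. Cells are
computed independently, so grid order is irrelevant (tested bit-for-bit).

Headline patterns (all asserted in the acceptance tests): prey split 50:50
without phage and under the generalist alone in both modes; the generalist
wins whenever the phage are parametrically identical; under competition the
generalist keeps winning at any burst-cost ratio we probe (to 20 and
beyond) except in cells where prey $E$ is itself competitively excluded;
under mutualism a modest cost flips the community to the specialist, with
the generalist driven below the extinction floor. With the mortality-channel
cost (baseline $\delta = 0.0067$), the generalist persists on competing
prey across a band of mortality ratios in which it is already extinct on
mutualistic prey (ratios 1.5 and 5 bracket the band in the tests; a narrow
window near ratio 3 lets the generalist linger under mutualism before it is
lost again) — and at very low shared mortality the mutualistic community
can even collapse entirely under double predation, another face of its
obligate coupling.

## Global sensitivity analysis

`morris_screen()` and `sobol_indices()` quantify how the two phages' final
biomasses respond to the parameters. Both act on a named range
specification; the default is $\pm 50\%$ around each preset default,
sampled log-uniformly (every varied parameter is a positive rate or scale),
with the four death/dilution rates tied into a single chemostat parameter
`delta` and the two half-saturations tied into `kappa`. These ranges are a
package convention, chosen in the absence of a published specification, and
are fully overridable.

Both methods evaluate the model at a fixed horizon of 2000 time units from
the standard initial condition rather than running the full steady-state
search — a deliberate divergence that keeps thousands of evaluations at
desk scale. The implementations are self-contained: Morris uses the
standard one-at-a-time elementary-effects design on a level grid
($\mu^\ast$ = mean |effect|, $\sigma$ = their SD); Sobol uses the
Saltelli A/B/AB radial design with the Saltelli-2010 first-order and Jansen
total-order estimators and percentile-bootstrap intervals. Samples whose
integration fails or does not complete are dropped and logged (a fraction
of a percent at the default ranges). A custom `model_fn` hook substitutes
any function for the ODE — the tests use an additive toy model with known
variance shares to validate the estimators independently.

Two practical notes. First, elementary effects on the *oscillatory*
competition endpoint are dominated by phase shifts, so Morris rankings
there converge slowly in the trajectory count $r$; we use $r = 48$ for the
13-parameter default screen and treat the top group, not individual ranks,
as the meaningful output (the rank-stability check in the test suite uses
the smooth mutualism endpoint and the toy model). Second, across methods
and modes the common death/dilution rate lands in the top group for the
persisting phage's final biomass, alongside the burst/attachment products
and the prey interaction parameters — dilution is what both phage must
outrun, so this is the expected chemostat signature.

## Synthetic plate and plaque observables

`simulate_readout()` emulates the measurement layer of an in vitro phage
competition assay: species-resolved OD-like prey signals every 20 minutes
over 48 hours (145 points), and endpoint phage titers (PFU/mL) with a lower
limit of detection of 500 PFU/mL. Noise is multiplicative lognormal with
configurable CV (default 0.1) — a stand-in with the right positive support;
no noise model is prescribed by the assay description. Censored titers are
reported as below-LOD, never as zero or a fabricated value;
`ln_fold_change()` turns a censored final titer into the upper bound
$\ln(\mathrm{LOD}/\mathrm{initial})$ with a flag, and `classify_winner()`
compares mean endpoint titers with censored replicates contributing
$[0, \mathrm{LOD}]$ intervals (overlap = tie). The mapping of one model
time unit to one hour is a declared readout-layer scale and never touches
the dynamics. What passing these tests shows is that the *classification
and censoring logic* is sound on model-generated data; the generator does
not emulate fluorescence spectral unmixing, physiology-dependent
infectivity, or plating error structure, so it cannot validate inferences
about those aspects of real plate data.

## Problem sizes

The shipped tests and the acceptance script run entirely at desk scale:
bisections need ~11 fixed-point enumerations or steady-state runs each;
sweeps in the tests use grids of 3–20 cells with $t_{\max}$ of
$2$–$5 \times 10^4$; the sensitivity screen uses $r = 48$ Morris
trajectories and a Sobol base sample of 128 (about 2000 ODE evaluations per
mode). All seeds are explicit arguments with fixed defaults; rerunning any
analysis with the same resolved configuration reproduces its outputs
bit-for-bit.

## Known limitations

* No spatial structure, phage latent period, resistance evolution, or
  multi-strain diversity; the model is deliberately phenomenological.
* "Final density" of a non-converged (oscillatory) run is a trailing-window
  time average — a convention, flagged in every output that uses it.
* The bistable band between the simulated dominance crossing (~2.09) and
  the stability threshold (~2.30) is initial-condition dependent; we locate
  its edges but do not characterize its interior.
* Morris rankings on oscillatory endpoints are intrinsically noisy; treat
  them as screening, and prefer the Sobol total-order indices where the
  distinction matters.
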