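---
title: "Modelling capping-protein-regulated branched actin growth at membranes"
author: "actocap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling capping-protein-regulated branched actin growth at membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actocap)
```

## The problem

When a minimal actin machinery — G-actin, profilin, the Arp2/3 complex, a
membrane-anchored VCA activator and capping protein (CP) — is encapsulated in
a cell-sized lipid vesicle, the branched network that assembles at the
membrane can either push the membrane outward (a protrusion), pull it into a
concave dimple, or coat it without deforming it. Which outcome occurs is set
almost entirely by the CP concentration, in the tens-of-nanomolar range.
`actocap` implements a kinetic model of this switch: well-mixed reaction
kinetics of the branching/capping network under finite, depleting protein
pools; an effective-2D radial simulation of a single domain spreading along
the membrane; a Brownian-ratchet mapping from barbed-end density profiles to
membrane deformation modes; a solution-mode emulator of bulk (pyrene-type)
polymerization curves; and a synthetic vesicle-ensemble generator.

## The reaction network

The model tracks densities only — no filament lengths, orientations or branch
angles. Species are split between bulk concentrations (µM) and membrane areal
densities (µm⁻²):

* bulk: polymerization-competent profilin–actin `G`, polymerized actin `P`,
  inactive Arp2/3 `Arp`, free capping protein `CPf`;
* membrane: free / G-loaded / spent VCA (`VCAf`, `VCAg`, `VCAs`), activated
  Arp2/3\* (`Astar`), free and capped barbed ends (`B`, `Bcap`).

Seven reactions connect them:

| reaction | rate law | meaning |
|---|---|---|
| VCA + G → VCA·G | `k_bind_VG · G · VCAf` | activator loads a monomer |
| VCA·G + Arp → Arp\* + VCA_spent | `k_act · Arp · VCAg` | activation; the loaded monomer seeds the nascent nucleus |
| Arp\* → B | `k_seed · Astar` | rare de novo nucleation |
| Arp\* + B → 2B | `k_branch · (G − c_crit) · Astar · B` | autocatalytic branching |
| elongation | `k_elong · (G − c_crit) · B` | monomer consumption into `P` |
| B + CP → B_capped | `k_cap · CPf · B` | irreversible capping |
| VCA_spent → VCA | `k_regen · VCAs` | slow activator regeneration |

Branching carries a monomer factor `(G − c_crit)` because branch formation,
like elongation, draws on the available monomer pool: when `G` reaches the
critical concentration both stop together. This is what bounds the barbed-end
density under finite pools — without it, pool exhaustion would leave the
entire activated Arp2/3 reservoir converted into free ends.

Bulk and membrane species couple through the vesicle's area-to-volume ratio:
one µm⁻² of a membrane species corresponds to `(3/R)/602.214` µM for a sphere
of radius `R` µm. Bulk (3D) mixing is treated as instantaneous; at patch
scales of a few µm and cytosolic diffusivities of tens of µm²/s the bulk
homogenizes in well under a second, so no gradient could persist there.

Three reservoir modes share this network: `finite` (all pools deplete),
`infinite` (bulk `G`, `CPf`, `Arp` held constant; used for steady states),
and `solution` (the bulk-assay mode, where VCA is volumetric).

Conservation of the four moieties (actin, CP, VCA, Arp2/3) is checked after
every integration: the content-weighted stoichiometry of every reaction is
exactly zero, and trajectories must close the totals to 1e−6 relative
(well-mixed) or 1e−5 (spatial).

## Steady states and growth phases

In infinite-reservoir mode the VCA cycle carries a stationary flux
`phi = VCA_tot / (1/(k_bind_VG·G) + 1/(k_act·Arp) + 1/k_regen)`, and the
fixed point follows in closed form:

* `B_ss = phi / (k_cap · CP)` — the steady barbed-end density falls as CP
  rises;
* `Astar_ss = phi / (k_seed + k_branch·(G − c_crit)·B_ss)` — the standing
  Arp2/3\* pool rises with CP, because fewer free ends consume it.

`steady_state()` returns this fixed point (the accumulators `P` and `Bcap`
grow without bound in infinite mode and are not part of it); the test suite
verifies it independently against long-time integration. `detect_phases()`
segments a barbed-end time course into seeding (below 1% of the maximum),
rapid growth (up to the peak growth rate), and transient (until |dB/dt| falls
below 1% of its peak); the thresholds are scale-free fractions.

## The spreading domain

`integrate_spatial()` solves the same kinetics on a radially symmetric
membrane patch (finite-volume annular cells, method of lines, sparse stiff
integrator, no-flux boundaries), with the bulk pools global and finite.
Growth starts from a seeded disc (radius 0.2 µm, 40 ends/µm²) that stands for
a completed nucleation event; the de novo seeding channel is switched off in
the field (its job is done by the seed). Membrane species diffuse laterally:
VCA states and Arp2/3\* with ordinary membrane-protein mobilities
(0.05 µm²/s), and barbed ends with the polymerization-scaled diffusivity
`D_B = alpha_spread · v_pol · delta`, so spreading stops when the monomer
pool is spent. Multiple domains in one vesicle compete for the pools by
volume partition: `domain_competition()` divides the reservoir volume (hence
every molecular amount) by the domain count while leaving concentrations
unchanged.

The CP dependence plays out as follows with the calibrated defaults:

* **40 nM** — branching beats capping early; a fast wave converts the
  standing Arp2/3\* as it sweeps outward, but the dense network behind it
  consumes the monomer pool within tens of seconds, so the wave's transient
  peak shrinks as it travels and the profile is radially flat (coefficient of
  variation < 0.10 over the occupied region, outermost 10% of radius
  excluded) by under 40 s.
* **80 nM** — capping carves the wake down to a low quasi-steady level while
  the slower-moving front keeps bursting through the Arp2/3\* excess it finds
  in virgin membrane: a propagating high-density rim over a low centre — a
  double-peaked radial distribution.
* **120 nM** — nucleation at many sites (10 pool-sharing domains by default)
  leaves each domain a sliver of the reservoir; growth is quenched before any
  structure can establish, and the profile stays flat and low.

### Classifying the pattern

`classify_profile()` calls a single profile double-peaked when the mean
density over the outer rim band (0.7–1.0 of the occupied radius) exceeds the
central-band mean (0–0.3) by more than 1.5×. For a whole growth episode,
`classify_pattern()` asks whether a double-peaked distribution *occurs*: it
takes the maximum rim/centre ratio over output times, restricted to times at
which the field is mechanically relevant — its maximum above
`mechanical_floor()`, the density (~66 µm⁻²) at which the ratchet velocity
reaches 10% of the unloaded speed. Two reasons for this design: the rim pulse
sweeps through any single fixed read-time within a few seconds, so an
instantaneous call is fragile against the output grid, whereas the episode
maximum is stable (unchanged across 96–192 cells, 1–2 s output steps and
160–200 s horizons); and after the pools are spent the *relative* shape of
the decaying field is frozen, so without an amplitude floor a dead residue
could masquerade as structure.

## From density to morphology

With VCA surface densities in the hundreds per µm², barbed-end densities stay
below ~450 µm⁻², and in that sparse regime protrusion speed is limited by
membrane load rather than by monomer supply. The membrane load per unit area
`F_mem` is shared equally across the local ends, giving the load-sharing
ratchet law

`v(B) = v_free · exp(−F_mem · delta / (B · kBT))`,

with `v_free = k_elong·(G − c_crit)·delta` ≈ 91 nm/s at 3 µM actin. The
default `F_mem = 230 pN/µm²` makes `v` sweep essentially 0–65 nm/s over
`B ∈ (0, 450]` µm⁻². `classify_morphology()` then reads a velocity profile
as: *flat* if the mean speed is at or below 10% of `v_free` (a network too
slow to push cannot deform the membrane, whatever its shape); otherwise
*concave* if the rim outruns the centre by more than 1.5×; otherwise a
*protrusion*. The amplitude test comes first deliberately: a depleted
multi-domain run can retain a faint rim-shaped residue that no membrane would
ever feel. With the calibrated defaults the three CP conditions map to
protrusion (40 nM; mean speed 0.60 `v_free`, velocity ratio 1.13), concave
(80 nM; ratio 1.87) and flat (120 nM; mean speed 0.08 `v_free`).

```{r morphology, eval = FALSE}
dm <- domain_morphology(80)
dm$pattern              # "double_peaked"
dm$morphology$label     # "concave"
```

## Bulk polymerization curves

`simulate_bulk()` runs the network in solution mode and reports the
pyrene-like signal `f_poly = (P − Astar)/A_tot`: monomers held in
not-yet-branched Arp2/3\* nuclei are not stacked F-actin and do not
contribute. Two solution-specific choices matter:

* **Branching is mother-filament-proportional** in solution:
  `k_branch_bulk · (G − c_crit) · Astar · (P − Astar)`. In a solution assay
  the mothers that Arp2/3\* branches from are the bulk F-actin, not the
  barbed ends. This form is also structurally necessary: with barbed-end-
  proportional branching and irreversible capping, the net growth rate is
  `const − k_cap·CP`, which goes negative above ~40 nM CP — no sigmoidal
  polymerization at high CP, contrary to bench behaviour. With mothers
  proportional to F-actin the growth exponent `mu` solves
  `mu (mu + k_cap·CP) = c`, finite and CP-stretched at every CP. On the
  membrane the barbed-end-proportional law is kept: there the nascent mothers
  concentrate exactly where the barbed ends are.
* **Lag extraction** uses the classic tangent construction
  (`extract_lag()`): the lag is where the tangent at the point of maximal
  slope meets the baseline, and the maximal rate is that slope. On an
  analytic logistic `1/(1+e^{−k(t−t0)})` this gives exactly `t0 − 2/k`, which
  the tests exploit as a closed-form oracle. For noisy curves a centred
  moving average (window ~21 points at 1 Hz sampling and 1% noise) keeps the
  recovered lag within 10% of the noise-free value.

At the study concentrations (3 µM actin, 0.3 µM VCA, 0.3 µM Arp2/3, 13.5 µM
profilin) the defaults give a lag of 1.49 min at 20 nM CP, with the lag
rising (to ~3.8 min at 120 nM) and the peak rate falling monotonically across
the CP sweep. Profilin itself is not an explicit species: its documented
roles — suppressing spontaneous nucleation and pointed-end growth — are
embodied by the absence of both processes from the network.

## Synthetic vesicle ensembles

`sample_vesicles()` draws the population structure the experiments describe:
radii uniform over 10–25 µm, per-vesicle CP with multiplicative lognormal
noise (sdlog 0.15; encapsulation variability is described but unquantified),
and Poisson seed counts with a CP-increasing mean (`lambda_seeds()`: ~1.5
expected seeds at 40 nM, ~10 at 120 nM, matching the default domain counts).
`run_ensemble()` gives each vesicle exactly one label: volume-spanning
network above 150 nM actual CP (between the studied 120 and 180 nM
extremes), cortex at ≥ 12 seeds (domains packed shoulder to shoulder), flat
for seedless vesicles, and otherwise the single-domain pipeline with the
pools shared across the vesicle's seeds — either one full spatial run per
vesicle or a nearest-neighbour lookup in a precomputed (CP × seed-count)
label table (`build_surrogate()`; radius variability is collapsed onto the
reference geometry in surrogate mode). With these rules protrusions dominate
at 40 nM (~85% of vesicles), concave domains at 60 nM, and flat/cortex
outcomes at 120 nM, and protrusion-labelled vesicles carry fewer seeds than
concave- or flat-labelled ones — the qualitative orderings the study reports.
The generator emulates population variability only; it does not model
encapsulation artifacts, myosin-driven contraction or membrane mechanics, so
quantitative vesicle percentages are out of its scope on purpose.

## Parameters

Only four constants are standard literature values: `k_elong = 11.6`
µM⁻¹s⁻¹, `k_cap = 3` µM⁻¹s⁻¹, `c_crit = 0.1` µM, `delta = 2.7` nm. No other
rate constant of this system is published for this geometry, so the rest are
free parameters of the model, calibrated once against four quantitative
anchors — the 1.5 ± 0.3 min bulk lag at 20 nM CP, the ≤ 450 µm⁻² barbed-end
density bound, the flat / double-peaked / flat radial patterns at 40/80/120
nM, and radial flatness within 40 s at 40 nM — and then frozen:

| parameter | default | units | role |
|---|---|---|---|
| `k_bind_VG` | 5 | µM⁻¹s⁻¹ | fast G-loading of VCA |
| `k_act` | 0.3 | µM⁻¹s⁻¹ | activation (first VCA pass ~30 s) |
| `k_seed` | 3e−6 | s⁻¹ | rare de novo nucleation |
| `k_branch` | 6e−4 | µM⁻¹µm²s⁻¹ | membrane branching |
| `k_branch_bulk` | 4e−4 | µM⁻²s⁻¹ | solution branching |
| `k_regen` | 0.04 | s⁻¹ | slow VCA regeneration |
| `alpha_spread` | 48 | – | barbed-end mobility coupling |
| `D_VCA`, `D_Arp_star` | 0.05 | µm²/s | membrane diffusivities |
| `F_mem` | 230 | pN/µm² | membrane load |
| `R_vesicle` | 10 | µm | reference vesicle (range 10–25) |
| `N_domains` | 1 (<100 nM CP), 10 (≥100) | – | pool-sharing domains |

The reference vesicle sits at the small end of the encapsulation range
deliberately: the pool-to-membrane ratio it sets is what lets the 40 nM
domain exhaust its monomer during spreading, which is the mechanism behind
the early flattening.

## Numerical choices

* Well-mixed integration: `lsoda`, rtol 1e−8, atol 1e−10. Spatial: `lsodes`
  (sparse Jacobian), rtol 1e−6, atol 1e−8, 128 annular cells over a 2.9 µm
  patch, 200 s horizon with 2 s output. Refinement to 192 cells changes the
  area-integrated barbed-end count by < 1%.
* Solver-scale negative excursions are clamped to zero; anything beyond
  1e4 × atol aborts the run. Conservation is enforced post hoc as described
  above.
* Below the critical concentration the net elongation law would depolymerize;
  this is allowed only while polymer exists (no negative `P`), and the
  spatial model omits the depolymerization branch entirely (its bulk `G`
  never falls below `c_crit` during growth).
* Ties in phase detection and classification resolve to the earliest time
  (`which.max` semantics), and half-open cells `[r_i, r_{i+1})` fix the grid
  convention.
* The stochastic oracle (`ssa_wellmixed()`, exact Gillespie direct method in
  C++) is compared to the deterministic solution on a ~1000-molecule instance
  over the pre-explosion window, where the linear-noise regime holds and the
  rate equations describe the ensemble mean; after the autocatalytic
  explosion the mean of a discrete birth process genuinely lags the ODE, and
  no agreement should be expected or enforced there.

## Open choices made here

* Whether activator recycling consumes the VCA·G complex on branching is not
  determined by the biochemistry this model coarse-grains; the implemented
  cycle (VCA → spent → free, with `k_regen` slow) makes activation, not
  regeneration, the early bottleneck.
* The pattern call uses the episode-maximum statistic, and the morphology
  call tests amplitude before shape (both argued above).
* `domain_competition()` divides the reservoir *volume*, not the
  concentrations: each domain starts at the encapsulated concentrations but
  owns a 1/N share of the molecules.

## Limitations

* The rate constants are a calibrated reconstruction, not a fit to raw data;
  only the qualitative regime structure and the four anchors above are
  constrained. Conclusions about absolute timescales other than those anchors
  should not be drawn.
* Membrane mechanics is out of scope: the ratchet map translates density
  profiles into velocity profiles and class labels, not into curvatures or
  shapes. Myosin-driven contraction and fission are likewise not modelled.
* The spatial model is radially symmetric and its bulk is well-stirred;
  azimuthal structure and local monomer boundary layers are absent.
* The infinite-reservoir 40 nM transient peaks at ~445 ends/µm², about 1%
  under the 450 µm⁻² bound — a thin (though deterministic) margin.
* The synthetic ensemble reproduces orderings, not percentages; its surrogate
  mode additionally collapses vesicle-radius variability.
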