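---
title: "Methods: imposed-flux heat transport in a coarse-grained bilayer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imposed-flux heat transport in a coarse-grained bilayer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lipidheat)
```

## What the package computes

`lipidheat` studies steady-state heat conduction across a hydrated lipid
bilayer with a desk-scale molecular dynamics engine. A fixed amount of
kinetic energy `dE` is moved every `interval` steps from a "cold" slab layer
to a "hot" one by momentum-conserving velocity rescaling; once the
temperature field is stationary, the imposed flux is

$$J = \frac{\sum \Delta E}{2\,A\,t},$$

where `A` is the cross-section perpendicular to the flux axis and the
factor 2 accounts for the two periodic heat paths (half of the exchanged
energy leaves the hot layer through each side of the periodic cell). The
downstream analysis turns per-layer temperatures into

* segment thermal conductivities, `K = J / |dT/dz|`,
* segment thermal resistances, `R = dT_segment / J`,
* interfacial (Kapitza) resistances, `R_int = dT_jump / J`, where
  `dT_jump` is the discontinuity between two fitted segments extrapolated
  to their shared boundary. The equivalent route
  `R_int = R_total(i,j) - R_i - R_j` is implemented independently and
  cross-checked; both are reported.

A gel/fluid transition temperature is estimated from a specific-volume
versus temperature curve as the break point of a continuous two-segment
piecewise-linear fit, and adhesion energies between molecular groups are
computed as `E_adh = E_tot - (E_1 + E_2)` with an independent cross-group
pair sum as a check.

## The engine

Internal units are MD "real" units (Å, fs, amu, kcal/mol, K, e). The
integrator is velocity Verlet; pair interactions are truncated
Lennard-Jones (optionally energy-shifted to zero at the cutoff) plus cutoff
Coulomb. Two Coulomb modes exist: plain `1/r` truncation (exact closed forms
inside the cutoff; the default for single-configuration energetics) and a
force-shifted form whose energy and force both vanish at the cutoff (the
default in the dynamics presets, so that pairs crossing the cutoff do not
inject energy). Bonds and angles are harmonic with the half-k convention
`E = k/2 (r - r0)^2`. Nonbonded exclusions follow the bond graph: 1-2
partners and all 1-3 pairs sharing a bonded neighbour are excluded, whether
or not an angle term is defined between them.

Temperature control is a single Nosé–Hoover chain with
`Q = N_f k_B T \tau_T^2`; pressure control is a Berendsen barostat that can
couple isotropically or to the z axis only. Slab simulations use z-only
coupling so the flux cross-section `A` stays fixed during a run. The
whole-system temperature uses `3N - 3` degrees of freedom (centre-of-mass
momentum removed); per-layer temperatures use `3n` per layer without a
per-layer COM correction — the bias is below one percent at the layer
occupancies used here (tens of particles per layer) and this matches common
slab-analysis practice.

Defaults: `dt = 2 fs` (bilayer runs; a heavy argon-like fluid tolerates
8 fs), pair cutoff 12 Å (8.5 Å for the argon-like test fluids), Verlet
neighbour list with a 2 Å skin rebuilt on a half-skin displacement trigger.
During flux sampling no thermostat runs: a global thermostat would be an
unaccounted heat sink in the flux bookkeeping, so NEMD integrates NVE
between exchanges, and pre-equilibration alone sets the temperature.

Exchanges rescale velocities about each layer's centre-of-mass velocity,
`v' = v_com + α (v - v_com)` with `α = sqrt(1 ∓ dE/K_rel)`; this is the
unique linear rescaling that changes the layer's energy by exactly `∓dE`
while leaving its momentum untouched. If a layer holds fewer than two
particles or the cold layer's relative kinetic energy does not exceed
`dE`, the exchange is skipped and logged; the skip count is a quality
metric, not an error.

## The surrogate bilayer

The builder produces a two-leaflet membrane of coarse-grained lipids (a
2-bead zwitterionic head carrying a ±q dipole, default q = 0.25 e, and two
4-bead apolar tails) in a single-bead solvent, 1 bead ≈ 1 water (18 amu).
Amphiphilicity is encoded in the nonbonded table: solvent–head attraction
(ε = 1.2 kcal/mol) far exceeds solvent–tail (ε = 0.08), solvent coheres
with itself (ε = 0.70, σ = 2.9 Å — the σ that puts 1 g/cm³ of beads at the
reduced density of a Lennard-Jones liquid), and tails cohere through
moderate dispersion (ε = 0.65, σ = 5.2 Å — the bead volume that lets a
4-bead chain fill its share of a 62.5 Å² per-lipid column at the built
leaflet thickness). Gel-like versus fluid-like behaviour is a chain angle
stiffness preset (25 vs 3 kcal/mol/rad²) — two bonded parameter sets, not a
claim about the real transition temperature.

Tails are laid down pre-coiled (a zigzag at the bond length) so the built
leaflet starts near the thickness the chains relax to; the equilibration
protocol opens with a short, strongly-coupled z-barostat "settle" run that
removes the residual excess height of the lattice-built slab before the
canonical three-stage schedule (NVT at 300 K, NPT at 400 K and 1 atm, NPT
cooling to the working temperature). Without the settle the fixed-box NVT
stage runs under z tension and the membrane can cavitate at its weakest
plane, the tail–tail midplane. Stage durations are 0.3 ns at full scale and
are multiplied by a `scale` factor for desk-scale work; the package's own
tests use `scale = 0.05` (7 500 steps per stage).

Imposed-flux runs on a membrane use a doubled cell (`replicate_z()`): two
bilayers at one and three quarters of the box, so that each of the two
periodic heat paths crosses exactly one membrane and the half-path profile
reads water | leaflet A | leaflet B | water. The hot layer defaults to slab
bin 1 and the cold layer to the bin half a box away.

## Analysis choices

* Region boundaries come from per-layer composition: the lipid block is
  where the head+tail fraction exceeds one half, and the leaflet A/B
  boundary sits at the tail-leaflet midplane (where the leaflet-0 tail
  fraction crosses 0.5). Fewer than four identifiable regions falls back to
  a user-supplied region specification with a warning.
* Segment fits exclude the 2 layers nearest each interior boundary
  (interfacial discontinuities contaminate adjacent bins) and need at least
  3 surviving layers.
* Steady state: the default averaging window is the second half of the
  sampled series; a run is flagged steady when, comparing the third and
  fourth quarters, at least 90 % of layers agree within twice their
  combined block standard errors. Layer standard errors use 5-block
  averaging.
* Uncertainties propagate first order: `se(K) = K · se(slope)/|slope|`; the
  jump uncertainty combines both fits' endpoint standard errors.
* Reporting units: K in W m⁻¹ K⁻¹, R in m² K W⁻¹ (printed ×10⁻⁹), J in
  W m⁻².

## Transition detection

`detect_transition()` minimises the SSE of a continuous two-segment
piecewise-linear model over a dense grid of candidate breaks (restricted so
at least 3 points lie on each side), refined by golden-section search. The
two-segment model must beat a single line by AIC, and a numerically perfect
line short-circuits to "no transition". The confidence interval is a
percentile bootstrap over points (default 1000 seeded resamples), widened
if necessary to contain the point estimate; a bootstrap was preferred over
profile likelihood because the 23-point, heteroscedastic setting makes the
quadratic approximation unreliable. The cooling-scan driver exposes two
sampling modes, since protocols differ on whether structures are taken
on-the-fly from the ramp (`"onfly"`) or re-equilibrated briefly at each
sampled temperature (`"requench"`); both are supported and the choice is
the user's.

## Synthetic fixtures and what the tests show

`make_profile_fixture()` generates piecewise-linear temperature profiles
with known slopes and interfacial jumps. Defaults encode the canonical
membrane analysis: water/lipid segment thicknesses 11.31/25.25 Å, flux
9.04 × 10⁸ W m⁻², water and lipid conductivities 0.60 and 0.39 W m⁻¹ K⁻¹,
interface resistances {0.40, 2.11, 0.40} × 10⁻⁹ m² K W⁻¹. The `noise`
argument is, by default, a fraction of the mean per-layer temperature
increment (≈ 0.28 K here), so `noise = 0.02` means ≈ 0.006 K of layer
noise — the scale at which recovering a 0.36 K interfacial jump to a few
percent is a meaningful statistical test rather than an impossibility.

`make_vt_fixture()` generates v(T) curves with a single kink. Defaults — a
break at 318 K inside a 280–360 K window, gel-side slope 1.2 × 10⁻³ and
fluid-side slope 3 × 10⁻⁴ cm³ g⁻¹ K⁻¹, 23 points, noise 2 % of the volume
range — depict a strongly first-order-like kink, consistent with the steep
volume change real phosphatidylcholines show at their main transition; the
gel-side slope exceeds the fluid-side slope by construction and the
generator rejects the opposite ordering.

Passing these tests shows the analysis machinery is correct and well
calibrated on data of known structure. It does not show that the
coarse-grained surrogate reproduces any real membrane's conductivity or
transition temperature — absolute numbers from the surrogate are
qualitative by design.

## Statistical conventions in the acceptance checks

Two conductivity estimates are called compatible when they differ by less
than twice their combined standard error (`|K₁ − K₂| ≤ 2√(se₁² + se₂²)`),
the usual 2σ compatibility reading. Standard errors for slab conductivities
are taken across quasi-independent estimates — three time blocks of the
steady window times the two periodic heat paths — because slow conduction
modes correlate neighbouring layers and make per-layer OLS errors
optimistic. The linear-response check uses exchange energies of 0.8 and
0.4 kcal/mol on the argon-like slab (temperature differences of roughly 45
and 25 K): small enough that the response stays linear within the
measurement's resolution, large enough that the signal dominates the slow
hydrodynamic fluctuations. The bilayer phenomenology run uses 32 lipids and
576 solvent beads (doubled to ≈ 1 800 particles), 80 000 steps of 2 fs with
`dE = 0.15` every 20 steps, giving a ≈ 60 K drop across the half cell — the
"high gradient" regime. These problem sizes are the package's documented
desk-scale conditions.

## Known limitations

* Electrostatics are cutoff-based (plain or force-shifted); no Ewald
  summation. Head-group polarity is qualitative.
* The Berendsen barostat produces correct means but not a rigorous NPT
  ensemble; it is used for relaxation and ramps, not for fluctuation
  analysis.
* The surrogate's gel/fluid presets change chain stiffness only; its v(T)
  slope change under a cooling scan is weak at desk scale, so transition
  detection is validated on synthetic curves with known truth.
* Imposed-flux NEMD measures an effective conductivity at a finite
  gradient; at the largest exchange energies the effective K of the
  surrogate visibly grows with the imposed gradient, so comparisons are
  made between runs of comparable gradient.
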