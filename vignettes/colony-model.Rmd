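---
title: "A multi-scale model of cell colonies with compartmentalized adhesion dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-scale model of cell colonies with compartmentalized adhesion dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(colonysim)
```

`colonysim` simulates two-dimensional colonies of cells that each carry an
explicit E-cadherin/β-catenin adhesion pathway. This vignette is the
package's account of the model: the equations it integrates, the
parameters and their units, the numerical choices, the design decisions
taken where the model statement left room, and the known limitations —
in particular, which published colony-scale observations this
implementation reproduces and which it demonstrably cannot.

## 1. The pathway: compartments and fluxes

A cell's adhesion machinery is described by four kinds of pools, all in
percent of the maximum number of E-cadherin/β-catenin complexes the cell
could form (100% = every molecule complexed):

* `E` — free E-cadherin in the cytosol. Its total content is the cell's
  *expression level* `E_t` (usually 100%).
* `B` — free β-catenin (total fixed at 100%).
* `EB` — complexes in the cytosol or at non-contact membrane positions.
* `EBc_i` — complexes in the compartment of contact site `i`, one
  compartment per neighbour, created and destroyed dynamically.

Binding and dissociation are mass action: `dE/dt = dB/dt =
−ν_p·E·B + ν_n·EB`. Each contact site receives an exocytosis flux

```
c_i = (ρ_c · a_c,i  +  ρ_u · A_i / (4πr²)) · EB · sat
```

with `A_i` the contact area, `a_c,i` the relative contact-area *gain*
since the previous bookkeeping step, and `sat` the variant's saturation
factor. Junction disassembly returns complexes through
`d_i = ρ_d · a_d,i · EBc_i`, where `a_d,i` is the relative area *loss*
(`a_d,i = 1` on full detachment, after which the orphaned compartment
drains at rate `ρ_d` and is deleted when it falls below 10⁻⁶). Only
complexes freed by disassembly are endocytosed; intact junctions are not
turned over.

The two exocytosis hypotheses differ only in `sat`:

* **Model 1 (static adhesion)**: each site is individually capped at
  `τ_E = E_t/6` — six saturated neighbours exhaust the cell. With the
  force anchor below, a single site can never greatly exceed the
  two-cell separation force.
* **Model 2 (dynamic adhesion)**: the cap is global —
  `sat = max(0, 1 − ΣEBc/(0.8·E_t))` — so a lone contact can recruit
  almost the whole complement, and sites additionally exchange complexes
  ("redistribution") at rate γ, each pair of sites transferring
  `γ·(EBc_rich − EBc_poor)` from richer to poorer.

Two reconstruction decisions are worth recording. First, the saturation
factor is shared by the directed and the undirected term (the model
statement specifies it for the directed one; an unsaturated undirected
term would overshoot every cap). Second, redistribution operates among
*attached* sites only: a fully detached, draining compartment no longer
takes part, otherwise it would be refilled indefinitely and could never
meet its own deletion rule.

`a_c`/`a_d` are per-bookkeeping-step relative changes clamped to [0, 1],
normalized by the larger of the two areas. They are dimensionless
multipliers on per-minute rates; the bookkeeping interval is the engine
step `dt` (0.01 min by default and throughout all shipped analyses), so
the directed/disassembly terms are defined relative to that interval.

Conservation — `E + EB + ΣEBc = E_t` and `B + EB + ΣEBc = 100` — holds
exactly by construction and is enforced numerically by flux limiting
(section 5).

## 2. Forces

**Repulsion.** Hertz contact of two compressed spheres. With overlap
`h = R_i + R_j − d`,

```
F_rep = h^{3/2} · sqrt(R_i R_j / (R_i + R_j)) /
        ((3/4)·((1−σ_i²)/E_i + (1−σ_j²)/E_j)) ,
```

which is the negative distance-derivative of the Hertz potential. In the
package's unit system (µm, min, pN; note 1 Pa ≡ 1 pN/µm²) the default
parameters (R = 5 µm, σ = 1/3, E = 1 kPa) give ≈2 178 pN at 8.5 µm
centre distance; six such neighbours sum to ≈13 071 pN — within 1% of the
13 000 pN contact-inhibition threshold, which is how that threshold was
chosen. The same sum of repulsive magnitudes is the "pressure" used by
the cycle gate (a symmetric hexagon has zero *net* force, so the scalar
sum, not the resultant, is the meaningful load measure).

**Adhesion.** The smaller of the two facing compartments limits the
number of trans bonds: `m = min(EBc_self, EBc_partner)`. The
bond-to-force map is linear and anchored at the dual-pipette separation
force: `F = m/15 · 210 nN` (Model 1) and `F = m/80 · 210 nN`
(Models 2/3). The anchors encode the assumption that in the measured
two-cell experiments 15% (static hypothesis) or 80% (dynamic hypothesis)
of the possible complexes carried the 210 nN. The map is deliberately
uncapped above the anchor.

**Model 3 — the separation-force framework.** Dual-pipette experiments
measure forces *during separation*; Model 3 therefore reinterprets bonds
as resisting separation rather than actively pulling. Cells at or inside
their *natural state* — contact-circle diameter equal to one sixth of the
circumference, i.e. centre distance `d* = 2·sqrt(R² − (πR/6)²) ≈ 8.52 µm`
for equal 5 µm cells (generalized to unequal radii through the mean
radius) — experience no adhesive force at all. Beyond `d*`, this
implementation realizes "bonds merely prevent separation" literally: at
each motion substep, an equal-and-opposite centre-line force cancels the
*separating* component of a bonded pair's relative velocity, capped at
the bond force `m/80 · 210 nN` (a few Gauss–Seidel sweeps resolve chains
of coupled pairs). Bonds never compress.

This is the one place where the package knowingly departs from the most
literal force-map reading, under which a bonded pair beyond `d*` would
feel the full active bond force. That reading is untenable in colonies:
a saturated pair pulls with up to 210 nN ≈ 210 000 pN while the largest
possible Hertz repulsion of a fully overlapped default pair is ≈37 500 pN,
so one bonded pair shoves third cells through their neighbours and every
colony run collapses within hours of the first division — contradicting
the separation-force variant's entire purpose (enabling colony growth
across the whole endocytosis-rate range). The velocity-cancelling
constraint preserves the intended semantics (pairs cannot separate unless
driven harder than their bond force; no force inside the natural state)
while keeping bonds from acting as compressive slingshots. Models 1 and 2
retain their constantly active adhesive pull.

**Motion.** Overdamped: `dx/dt = (ΣF + f)/(6πηR)` with Stokes drag
6πηR ≈ 15.71 pN·min/µm at the default viscosity (10 Pa·s), so 942.5 pN
moves a default cell at 1 µm/s. The noise force `f` is isotropic,
zero-mean Gaussian per component with amplitude `noise_amp` (default 0 —
all shipped analyses are deterministic; the term exists because motility
noise is part of the model family, but no amplitude is calibrated).

## 3. Cell cycle

G1 (fixed 7 h): the radius grows linearly from `R/2^{1/3}` to `R`.
Rest (G0/S/G2, uniform 8–18 h): idle at full size. M (fixed 2 h): the
cell is a dumb-bell of two daughter lobes. Generation times are thus
uniform on 17–27 h, mean 22 h. Divisions happen at the rest→M boundary:
the mother is replaced by two daughters of radius `R/2^{1/3}` (volume is
conserved exactly) placed at ±R/2 along the division axis — the
eigenvector of the largest eigenvalue of the compression tensor
`Σ |F_rep,j| û_j ûᵀ_j` over the mother's compressed contacts ("axis of
highest pressure"; isotropic or contact-free cells draw a random axis).
During M the lobes ignore each other mechanically and chemically; the
package additionally keeps the dumb-bell *rigid* (lobe separation fixed
at R), because lobes with no mutual repulsion would otherwise be squeezed
into each other by the neighbourhood and emerge deeply interpenetrated at
M exit, spuriously triggering the collapse detector. With contact
inhibition enabled, a mother whose pressure exceeds 13 000 pN at the
boundary holds in rest and re-checks every step, dividing as soon as the
load drops.

Division folds the mother's contact-bound complexes back into her
cytosolic pool before concentrations are copied to both daughters:
concentrations are intensive, and the fold-back is what keeps
`E + EB + ΣEBc = E_t` true in each daughter (daughters start with no
contacts; bookkeeping re-forms them).

The initial cell of a colony run starts at a uniformly random point of
its G1+rest interval (a lone cell cannot be half of a dumb-bell).

## 4. The engine

Operator splitting per step `dt` (default 0.01 min): (1) contact
bookkeeping — every overlapping non-sibling pair carries a site on both
cells with the sphere–sphere intersection-disc area (`a² = (4d²R_i² −
(d²−R_j²+R_i²)²)/(4d²)`, the lens formula; `prev_area` retains the last
value; detached sites persist at zero area while draining); (2) pathway
integration for every cell; (3) mechanics sub-stepping — forces are
recomputed on substeps chosen so no cell moves more than 0.05 µm each, at
most 50 per step, and sub-stepping ends early once a substep moves
nothing (statically pinned or equilibrated configurations); (4) cycle
advance and divisions; (5) collapse check — the run halts when any
non-sibling pair is closer than 0.2·(R_i+R_j), the "cells can no longer
be identified individually" failure of over-adhesive regimes. Identical
configuration and seed give bit-identical trajectories; all randomness
(cycle draws, division axes, noise) flows from the single seed.

Neighbour search is grid-binned (bin = 2R), so steps are O(N); a 7-day
headline colony (~190 cells at the end, ~10⁶ steps) runs in ≈3 minutes.

## 5. Numerical choices

* **Integrator**: forward Euler for the pathway, with two safeguards:
  sub-stepping (halving until no pool would lose more than half its
  content per substep, at most 16) and exact-conservation flux limiting —
  all outflows of a pool are scaled so it cannot undershoot zero, with
  inter-site transfers limited pairwise. Conservation therefore holds to
  round-off (the test suite checks 10⁻⁶ across dividing colony runs).
* **Step size**: `dt = 0.01 min`. Halving it changes the 100-min
  two-cell force trajectory by well under 1%. Steps above ~0.02 min are
  *not* safe for the two-cell scenario: its initial condition (contact
  area 1 µm², no complexes anywhere) sits on a knife edge where the small
  Hertz repulsion fully separates the pair within the first step, before
  any complex has formed; the drained empty site is then deleted and the
  cells never re-engage. Calibration utilities default to 0.02 min and
  refuse nothing — but the shipped analyses use 0.01–0.02 only.
* **Mechanics cap**: 0.05 µm per substep. Overlap relaxation times are
  seconds (stiffness/drag ≈ hundreds per minute), far below `dt`, so
  position updates are effectively quasi-static; the cap bounds the error
  during fast transients (post-division rearrangements, Model 1/2
  adhesive collapse).
* **Minimum distance**: scenarios that disable collapse detection (the
  pipette fits, where Model 1/2 pairs legitimately crush) keep pair
  centres at least 0.1·(R_i+R_j) apart so centre-line directions stay
  defined.
* **Tie-breaks**: isotropic compression tensors draw a random division
  axis; equalization times are read off force series sampled every
  0.5–1 min.

## 6. Calibration

`fit_kinetics()` reproduces the two-cell fitting procedure: multi-start
Nelder–Mead (starts log-uniform in [10⁻⁶, 10⁶]) over the four rates a
two-cell experiment can constrain (ρ_u, ν_n, ν_p, ρ_c), minimizing the
summed squared force residuals against a force-versus-time series (5, 10,
30, 60 min at 100% expression) plus a force-versus-expression series
(100, 58, 41, 38, 14, 2% at 30 min). The shipped fixture
(`inst/extdata/pipette_force_*_synthetic.csv`) is generated by the model
itself at the published rates (ρ_u = 8.2, ν_n = 0.6, ν_p = 0.02,
ρ_c = 0.6 min⁻¹) — the underlying experimental force values at early
times and reduced expression are not tabulated anywhere, only the 210 nN
maturation anchor is. A caveat the package is explicit about: this
objective is *nearly degenerate*. Several rate combinations far from the
generating values reproduce the ten data points to within a fraction of a
nN², because the observable dynamics are dominated by the saturation cap
and the transport bottleneck ρ_u·EB. The fit therefore polishes the
leading multi-start candidates at high precision, but recovering all four
rates to within 10% from random starts is at the edge of what the data
identify; the acceptance suite runs this experiment honestly rather than
seeding the optimizer with the answer.

`fit_redistribution_rate()` fits γ against the three-cell criteria: with
simultaneous contacts each per-site force must settle at half the
two-cell force (the min() in the force map plus the shared 80% cap make
the 80 split into 40+40); with a second neighbour arriving at 20 min the
two forces must equalize (1% relative) about 30 min later. The
equalization *time* identifies γ cleanly (a two-stage deterministic grid
search handles the piecewise-constant readout); at γ = 0 the late site
starves — the global cap is already exhausted by the first site — and the
forces never meet; at γ = 0.16 min⁻¹ equalization lands at ≈36.5 min of
total time, matching the published "completely the same after 40 min".

## 7. What the synthetic scenarios do and do not show

The generator-side scenarios (`make_scenario()`) emulate the study
conditions: two/three cells placed at a 1 µm² initial contact, colonies
grown from a single cell for 3–7 days, a hexagon defining the pressure
threshold. They are deterministic (noise off), monolayer-planar with
spherical-cap geometry, and contain no E-cadherin production/degradation,
no substrate interaction beyond Stokes drag, and no deformable shapes.
Passing tests on them validates the kinetics, mechanics, conservation
laws and calibration machinery — not agreement with any particular cell
line.

Colony-scale comparisons deserve a frank statement. With the published
kinetic rates and the reconstructed fluxes, the undirected exocytosis
into a colony-sized contact (≈20 µm² at the natural state, i.e.
ρ_u·EB·A/S ≈ 20%/min per site) saturates every contact compartment within
minutes. Consequences in this implementation, all verified numerically:

* Model 2 colonies collapse shortly after the first division for *every*
  endocytosis rate — a lone post-mitotic pair saturates to 80% bound,
  whose 210 nN pull has no Hertz balance — whereas the published sweeps
  report completed Model 2 runs at ρ_d = 500 and 50 min⁻¹ (with mean
  contact forces of only ~4.5 nN, i.e. bound fractions of ~2%, which no
  admissible disassembly drain can sustain against that influx). The
  collapse of the slow-endocytosis regimes (ρ_d ≤ 0.05) is reproduced.
* Model 3 + contact inhibition completes the whole ρ_d sweep and grows
  near-circular, contiguous colonies exponentially (doubling time ≈22 h
  against the intrinsic 22 h mean generation time; the published fit is
  ≈20 h), with the neighbour-number histogram peaking at 5–6; but the
  mean per-contact separation force sits at 15–30 nN, not under 6 nN,
  again because compartments run near their caps.

The package reports these quantities as computed; the gap between the
printed colony-scale force levels and anything reachable from the printed
rates plus the reconstructed flux terms is documented here deliberately,
as it is the main open reconciliation question of this re-implementation.

## 8. Problem sizes of the shipped analyses

Unit and property tests run seconds-scale scenarios (two/three cells for
20–100 min; colonies for 1–3 days). The regime sweep is run in reduced
form (three ρ_d values per variant, 3 days); the headline colony run is
the full 7 days from a single cell. The acceptance script's quantities
are all desk-scale (two- and three-cell scenarios and closed-form
geometry).
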