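---
title: "An agent-based model of posterior body-axis elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of posterior body-axis elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(axisim)
```

## The system and the model

During vertebrate body-axis formation the posterior presomitic mesoderm
(pPSM) — a pair of loose, mesenchymal tissues flanking the axial midline
(notochord and neural tube) — expands and, confined between stiffer
anterior structures and rigid lateral boundaries, drives the posterior
elongation of the whole axis.  New cells continuously enter the pPSM from a
progenitor domain (PD) on the posterior midline, so the pPSM's cell density
is set by two opposing processes: expansion (density down) and progenitor
influx (density up).  Density, in turn, controls how much pushing force the
pPSM exerts, making it a natural node for negative feedback on elongation
speed.

`axisim` implements this system as an overdamped, center-based agent model.
Each cell `i` is a disc (2D) or sphere (3D) with position `x_i`, radius
`R_i` and maximum adhesion distance `A_i`.  Its velocity is the sum of
pairwise interactions, rigid-wall repulsion, and — for PSM cells only — an
active motility term:

* repulsion, for center distance `d < R_i + R_j`:
  magnitude `sqrt(c_r^i c_r^j) (1 - d/(R_i+R_j))^2`, directed apart;
* adhesion, for `R_i + R_j <= d < A_i + A_j`:
  magnitude `sqrt(c_a^i c_a^j) (1 - d/(A_i+A_j))^2`, directed together;
* wall repulsion with the same quadratic falloff over one radius;
* motility: magnitude 1.2 along a direction redrawn uniformly each
  iteration ("directionless" active noise).

Positions are advanced by explicit Euler, `x <- x + v dt`.  There is no
cell cycle, no apoptosis, and no chemical field; posterior and axial cells
are passive (zero motility) and move only because other cells push or pull
them.

The three tissue types use the reference coefficient table: repulsion
10/10/10 (axial / PSM / posterior), adhesion 2.5/0.05/1, motility 0/1.2/0,
and maximum adhesion distance 1.1, 1.25 and 1.1 times the radius.
Heterotypic coefficients default to geometric means, with two deliberate
exceptions described below.

## The initial construct

`build_construct()` generates the multi-tissue initial condition: an axial
column along the midline (AP from 0 to 11.6 length units), bilaterally
mirrored PSM blocks flanking both the column and the PD strip (AP 11.6 to
13.6, |ML| below 1.25), and a full-width passive posterior cap (AP 13.6 to
15).  Rigid walls close the anterior and lateral (and in 3D, dorsal and
ventral) sides; the posterior is never walled.  The starting field is 15
units long; the 2D default has ~340 cells and the 3D default exactly 7920.

Several geometric choices could not be carried over literally from the
usual sketch of this system and were fixed as follows:

* **Cell radius 0.36.**  The 2D model must hold 300–800 cells in the
  15-unit field.  With radius 0.5 that count forces ~50% lattice overlap,
  and the resulting relaxation burst drives an indiscriminate posterior
  flow that swamps every regime distinction.  Radius 0.36 makes ~2 cells
  per square unit a near-contact packing.
* **Full-width posterior cap.**  If the cap flanks the PD strip instead,
  influx cells are injected into a closed pocket between the axial tip and
  the cap and mechanically compress the tip.
* **Per-tissue initial packing.**  The anterior PSM is laid down ~14%
  below contact distance (compressed — the expansion reservoir), while the
  posterior ~4 units of the PSM and the PD flanks are ~10% above contact
  (sparse).  This encodes the anterior-to-posterior density gradient
  measured in the embryonic PSM (roughly 10.2k/mm^2 anteriorly versus
  6.5k/mm^2 posteriorly).  The axial column is placed at its force-balance
  spacing, where its adhesion and repulsion cancel, so it neither
  contracts nor explodes at rest.
* **Interface repulsion.**  The PSM–axial and PSM–posterior repulsions
  default to 50 and 35, the midpoints of their explored ranges, rather
  than the ~10 geometric mean.  With ~10 the tissues intermix and the
  axial column loses integrity within a few thousand iterations; the
  strong interfacial repulsion keeps the tissues segregated, which is a
  prerequisite for every readout tied to "the posterior-most axial cells".

```{r construct}
tc <- build_construct(2, seed = 1)
tc
plot(tc)
```

## Integration settings

The integration step is `dt = 0.01` time units per iteration with motility
direction redrawn every iteration.  At this step the per-iteration motility
displacement is 3% of a cell diameter and contact forces at typical
overlaps move cells by well under 10% of a radius per iteration; a
per-step displacement clamp (0.3 units) guards the stiffest transient
contacts in sweep corners.  Runs of 2,000–6,000 iterations (the scales
used throughout) integrate 20–60 time units.  Net cell displacements over
such windows mix a collective (pressure-driven) drift with motility noise
whose per-cell standard deviation is `1.2 dt sqrt(N/2)`; the regime
classification below is read against this noise floor.

## Simulated readouts

All readouts of `measure` operate on recorded trajectories
(`run_simulation()` stores snapshots, a per-iteration axis length and
axial-force series, and a wall-collision impulse tally):

* `axis_length()` — mean AP position of the 4 posterior-most axial cells.
* `density_profile()` — PSM counts in unit grids, banded by distance to
  the posterior axis end; bands within 5 units are labeled pPSM.
* `boundary_pressure()` — summed wall-collision impulses of PSM cells per
  AP unit per iteration.
* `axial_push_force()` — the summed AP component of cell–cell interaction
  forces on the 4 posterior-most axial cells (in an overdamped model these
  are velocity contributions; they are reported as forces), binned per 200
  iterations.
* `pd_lateral_flux()` — ML speeds of PD cells (PSM cells posterior to the
  axial tip within a midline half-width), binned per 200 iterations.
  Absolute speeds by default; `signed = TRUE` gives the
  medial-to-lateral signed rate, which is the readout to use for
  direction-of-effect comparisons because absolute speeds are dominated
  by the isotropic motility noise.
* `classify_regime()` — per-cell net displacement decomposed into an
  ML-inward (convergence) and an AP-posterior (elongation) component;
  the run is labeled by whichever summed magnitude dominates (ratio
  threshold 1), and the continuous ratio is kept for transition detection.

## Perturbations

`perturbation()` specifies in-silico analogues of the embryo
manipulations, applied instantaneously between iterations (viscoelastic
recoil is not simulated):

* global strain: every AP coordinate rescaled by `1 + strain` about the
  anterior wall;
* graded strain: the posterior 75% of cells (by AP rank) displaced by
  `A exp((a - a_max)/lambda)`, amplitude `A` chosen so the whole-axis
  strain equals the request; the default decay length is one third of the
  affected zone (the exponential constant is otherwise unconstrained) and
  the map is monotone for strains in the ±10–15% range used;
* pPSM deletion: a uniform fraction of PSM cells within 5 units of the
  axial tip removed;
* influx change: the Poisson insertion rate switched mid-run.

The strong pull/compression conditions carry a bookkeeping
`magnitude_parameter` of 80; the physical strain is the controlling input.

## Progenitor influx

With `influx_rate > 0`, each iteration inserts `Poisson(rate)` new PSM
cells into the current PD window: the posterior half of the AP span
between the axial tip and the posterior cap front, across the full
mediolateral band up to half a unit short of the lateral walls.  A birth
position must be at least 1.3 radii from every existing cell (up to 10
draws, skipped insertions are logged): cells are born into loose space,
mimicking arrival of ingressing progenitors, rather than materializing at
deep overlap and injecting pressure spikes.  The default recipe rate of
0.3 attempted insertions per iteration yields ~50–90 accepted births per
6,000 iterations at these densities — comparable to the cell number the
growing posterior region can absorb.

Influx reliably sustains pPSM density (influx-off runs thin out; this is
the density half of the feedback loop).  A known limitation of this
re-implementation: the elongation-speed benefit of influx does not
reproduce — added posterior mass loads the axial tip slightly more than it
boosts the flank squeeze, so influx-on runs elongate marginally *less*
than influx-off runs at these scales.  The corresponding acceptance check
is therefore expected to fail on its elongation half, and the package does
not hide that.  The perturbation responses (pressure, extent ordering,
length recovery) do not depend on this and reproduce cleanly.

## The repulsion sweep and the transition

`run_sweep()` explores the five repulsion coefficients over their stated
ranges (PSM–PSM 5–45, axial 1–16, posterior 0.1–1.1, PSM–axial 20–80,
PSM–posterior 10–60), min–max scaled to [0, 1].  Sweeps run the
*simplified* 2D configuration — no influx, uniformly compressed PSM
blocks (spacing 0.64) and a slightly slack axial column (0.78) whose
cohesion can drive convergence — for 4,000 iterations, and record the
axial bounding-box length and width plus the regime classification.  The
default slice varies PSM–PSM repulsion over 17 points with 5 replicate
seeds each; `find_transition()` majority-votes the labels per point and
returns the midpoint between the last convergence-dominated and first
elongation-dominated points.  Replicate noise near the boundary can make
the voted sequence non-monotone; in that case the assumed monotonicity is
enforced instead, by an isotonic (pool-adjacent-violators) fit of the
per-point elongation-vote share whose 1/2-crossing is reported (the slice
is flagged via the `monotone` attribute).  At these settings the
transition falls at ~0.5–0.6 scaled units, against ~0.5 in the reference
description.

`fit_surrogate()` trains a one-hidden-layer feed-forward regressor (10
units by default; "shallow" is the only architectural constraint
available) from the five scaled inputs to the min–max scaled axial length
and width, on a 70/15/15 train/validation/test split; the validation set
picks the weight decay and the held-out R² is reported.

## What the generator does and does not emulate

The synthetic constructs reproduce the tissue topology, confinement,
relative densities and coefficient table of the reference system; they do
not model somite formation, axial-cell intercalation, FGF signaling or any
chemical gradient, cell division or death, or the viscoelastic recoil of
real tissue.  Passing tests therefore demonstrate the mechanical
sufficiency arguments (confined active expansion driving elongation;
density as the pressure-setting variable; length recovery through
density-dependent speed), not any molecular mechanism.

## Scales used by tests and recipes

Unit tests run seconds-scale simulations; the canned experiments
(`run_recipe()`) default to the reference scales — 6,000 iterations, 20–40
replicate seeds per condition for the feedback and recovery experiments,
17 × 5 runs of 4,000 iterations for the sweep — chosen so a full recipe
completes in minutes on one CPU.  All randomness flows from one root seed
through fixed per-run derivations, so every table is bit-reproducible from
its manifest.
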