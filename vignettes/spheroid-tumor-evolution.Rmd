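---
title: "Modeling spheroid tumor evolution in an adhesion-motility phenotype space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling spheroid tumor evolution in an adhesion-motility phenotype space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidevo)
```

## The model

`spheroidevo` simulates an avascular spheroid tumor embedded in healthy
tissue with a three-dimensional cellular Potts model (CPM).  Every voxel of
a periodic $L^3$ lattice (1 voxel $\approx$ 1 µm³) carries the integer id of
the cell occupying it; a biological cell is the set of voxels sharing an id.
Dynamics are voxel-copy attempts: a uniformly random site proposes to adopt
the id of a uniformly random lattice neighbor, and the proposal is accepted
with the Metropolis probability $\min(1, e^{-\Delta H/T_{MC}})$ at
temperature $T_{MC} = 55$.  One Monte Carlo sweep (MCS) performs $L^3$
attempts and is the unit of simulated time; 1 kMCS = 1000 MCS.

The Hamiltonian is

$$
H = \sum_c \lambda_V (v_c - V_0)^2
  + \sum_c \lambda_S (s_c - S_0)^2
  - \sum_{\langle i j \rangle} k(c_i, c_j)
  - \sum_c m_c\, \hat e_c \cdot \mathbf r_c
  + \sum_{c \in \text{cancer}} |\lambda_c|\, \lVert \mathbf r_c -
    \mathbf r_{\text{ctr}} \rVert ,
$$

with, per cell $c$: volume $v_c$ (target $V_0 = 500$ voxels, coupling
$\lambda_V = 8$), surface $s_c$ counted as unlike-neighbor faces (target
$S_0 = 400$, coupling $\lambda_S = 6$), and center of mass $\mathbf r_c$.
The third sum runs over unordered neighboring voxel pairs belonging to
different cells.

**Adhesion convention.**  The adhesion parameter is a *bond strength*:
shared contact area between two cells lowers the energy by the pair's
strength per face, so nonnegative parameters mean adhesion is never
repulsive.  Between two cancer cells the strength is the arithmetic mean of
their phenotype adhesion values; any contact involving healthy tissue uses
a fixed reference strength (default 50, the mid-range value).  This sign
convention is load-bearing: writing the same parameters as a positive
contact penalty would give the interfacial tension between a cancer
phenotype with adhesion $p$ and healthy tissue the form $25 - p/2$, making
*strongly* adhesive cells sort to the spheroid rim.  With the bond-strength
form the tension is $p/2 - 25$: weakly adhesive cells preferentially wet
the healthy interface, sort to the nutrient-rich rim, divide more, and are
selected — the differential-adhesion mechanism the model is built to
express.  The healthy reference strength and the mixing rule are
configurable.

**Motility** is a constant force of strength $m_c$ (the second phenotype
axis; healthy cells default to 0) along a per-cell preferred direction
$\hat e_c$, redrawn uniformly on the sphere every
`motility_recalc_interval` = 100 MCS, which makes undisturbed cells perform
an unbiased random walk.  **The central potential** applies a constant
force of magnitude $|\lambda_c| = 70$ pulling every cancer cell toward the
box center, preventing the tumor from drifting and healthy tissue from
being enclosed.

**Periodic boundaries and centers of mass.**  Center-of-mass sums are kept
in unwrapped coordinates: each voxel enters as the periodic image nearest
the cell's current center of mass.  This is exact for compact cells whose
extent stays well below $L/2$ — true for $V_0 = 500$ cells on every
supported lattice — and both the motility and central terms as well as the
nutrient field read these unwrapped positions relative to the fixed box
center.  A brute-force rebuild (`sim_check_consistency()`) recomputes
volume, surface, and center of mass from the spin array after any number
of sweeps; the test suite requires exact agreement.

**Neighborhood.**  Flip candidates, surface faces, and adhesion contacts
all use the same lattice neighborhood, 6 (von Neumann, default) or 26
(Moore).  The 6-neighborhood gives the simplest consistent contact-area
definition on a cubic lattice; $S_0 = 400$ is calibrated to it.

**No connectivity constraint** is enforced: cells may fragment.
`sim_fragments()` reports connected components per cell so users can audit
fragmentation; in the default configurations fragmented cells are a small
minority and fragments are transient.

## Phenotype space and mutation

Cancer cells carry one of $12 \times 12 = 144$ phenotypes: all combinations
of adhesion and motility over $\{0, 10, \dots, 110\}$ (the range is twice
the Metropolis temperature).  At every division there is a 4% chance that
one uniformly chosen daughter changes one uniformly chosen parameter by one
grid step of $\pm 10$ (uniform sign).  A step that would leave the grid is
*aborted* — both daughters keep the parent phenotype and the division
counts as unmutated.  Clipping would inflate edge occupancy and reflection
would invent dynamics; aborting is the most conservative reading of an
incremental step on a bounded grid, and `mutation_boundary = "reflect"` is
available for comparison.  Because of aborts, the realized mutation
frequency equals 4% only for interior phenotypes and is lower at grid
edges.

The seed phenotype defaults to (50, 50).  The exact center of the range,
55, is not a grid point; we take the lower neighbor on both axes, and both
coordinates are configurable.

## Nutrient environment

Availability is a dimensionless scalar in $[0, 1]$: zero at a *sink*,
rising linearly with distance, saturating at 1 at `decay_radius` $R_n$
(default $L/2$, so the tumor rim sits near maximal availability).  The sink
either rests at the box center (constant environment) or orbits it on a
circle in the $xy$ plane with amplitude $A = 50$ voxels and period $T$
(fluctuating environment); the orbit starts on the $+x$ axis at $t = 0$, an
arbitrary phase fixed for reproducibility.  A cell's availability is
evaluated at its center of mass.  Because the profile $\lVert \mathbf r -
\mathbf r_{\text{sink}}\rVert / R_n$ has a kink at the sink, the
center-of-mass value tracks the voxel-averaged availability of a compact
500-voxel cell to within 0.05 only away from the sink; directly on the sink
the voxel average exceeds it by $\approx 3R_{\text{cell}}/(4R_n)$.  The
threshold-style dependency variant is deliberately out of scope; only
`"none"` and `"linear"` dependency modes are implemented.

## Division and death

A cancer cell may divide once its age strictly exceeds 2 kMCS *and* its
volume strictly exceeds $0.9\,V_0 = 450$ voxels; it may die once its age
exceeds 4 kMCS.  (The source description of the death gate reads "divide"
in one sentence where "die" is clearly meant — two division gates and no
death gate would leave death impossible; we implement 4 kMCS as the death
age gate and flag the reading here.)  Every MCS, each live cancer cell
draws division with probability $n \cdot 0.005$ and death with probability
$(1 - n) \cdot 0.001$ at its local availability $n$ (linear mode).  In
`"none"` mode both rates are constant at their maxima, so the two modes
agree at the $n = 1$ / $n = 0$ endpoints; the constant-mode values are
configurable.  Rates are per-MCS Bernoulli draws, not a Gillespie scheme:
the printed rates are per-MCS probabilities and events are rare.

Division splits the cell's voxels by a plane of uniform random orientation
through its center of mass; the smaller side becomes a new cell id, both
daughters restart their age, and a degenerate plane (an empty side) is
resampled up to ten times before the division is skipped.  Death is
gradual: the dying cell's volume and surface targets drop to zero and the
ordinary Potts dynamics shrink it until its last voxel is copied away;
dying cells neither divide nor die again.  A cell that loses its last voxel
*without* having been marked (squeezed out mechanically) is retired and
logged as a `mechanical_death`, distinct from rate-based death.  Healthy
cells take no part in division or death; they act as a pressure-bearing
medium.

## Initialization and scheduling

The box is tiled with cubic healthy cells (side 8, 512 voxels $\approx
V_0$); a sphere of `seed_radius` at the center is carved into cancer cells
by a nearest-seed (Voronoi) partition with $K = \lceil \text{sphere
voxels}/V_0 \rfloor$ uniformly sampled seed points, so initial cancer cells
are compact, connected, and $\approx V_0$-sized.  A short burn-in
(`relax_mcs`, default 50 sweeps with the lifecycle off and the clock
frozen) rounds the cubic tiling before the run loop starts.  Each MCS then
performs: motility redraw (every 100 MCS), one sweep, one lifecycle pass,
clock increment, and composition sampling every `composition_cadence` MCS.
If the cancer population reaches zero the run terminates early with an
`extinct` status — the evolutionary trajectory is lost.

All engine randomness comes from a self-contained xoshiro256++ generator
seeded by `rng_seed` (the R-side initialization also seeds R's RNG from
it), so a run is bit-reproducible from its manifest.  Period sweeps derive
per-run seeds deterministically from a master seed, the condition, and the
replicate index.

## Trajectory analysis

The tumor state at a sample time is its *composition*: counts of live,
non-dying cancer cells per phenotype.  From the composition series we
compute:

* **Centroid**: count-weighted mean (adhesion, motility) — the tumor's
  position in phenotype space; invariant under uniform count scaling.
* **MSD**: squared displacement of the centroid from its first sample.
* **Evolution speed**: the centroid trajectory is smoothed component-wise
  by a centered moving average (default window 10 kMCS) and differentiated
  by centered finite differences, in parameter units per kMCS.  Smoothing
  *before* taking the displacement modulus matters: the modulus of a noisy
  difference is biased upward, and smoothing first removes most of that
  bias, which is how the estimator recovers prescribed fixture drifts
  within 5%.  The raw unsmoothed speed and the time derivative of the MSD
  are emitted alongside; run means use the smoothed centroid speed.
* **Spread**: the number of phenotypes occupied by *strictly* more than 10
  cells, a heterogeneity measure ("more than 10" is read as a strict
  inequality).
* **Radial event histograms**: division/death counts binned by distance
  from the box center, with per-kind mean radii.

Run means of speed and spread exclude a burn-in of the first 10% of
samples (index-based): the initial expansion phase is not the evolutionary
steady state.  Period sweeps are compared against the constant-environment
control with Welch's unequal-variance two-sample t-test (the variant is a
deliberate choice; only "a t-test" is specified by the protocol), flagging
p < 0.04; degenerate groups (no variance or fewer than two runs) warn and
report NA rather than significance.

## Synthetic fixtures

`generate_drifting_composition()` draws, at each sample time, a population
from a bivariate Gaussian whose center drifts at a prescribed velocity,
snapped to the nearest grid phenotype (off-grid mass goes to the boundary).
It emulates the *statistical* shape of a drifting composition — multinomial
sampling noise around a moving center — and deliberately none of the CPM's
spatial dynamics: no spatial correlation between samples, no
clone structure, no selection.  Passing estimator tests on fixtures
therefore validates the analysis layer's arithmetic and bias, not the
simulator's biology; the simulator itself is validated by the oracle,
conservation, and calibration tests plus the qualitative spheroid checks.
`generate_event_log()` plays the same role for the radial histograms.

## Numerical choices

* Incremental $\Delta H$ updates are validated against a brute-force
  voxel-enumeration Hamiltonian (pure R) to a relative tolerance of 1e-9
  over chained random flips, including the 26-neighborhood.
* A flip that removes a cell's last voxel is allowed and retires the cell;
  forbidding it would bias the dynamics and dying cells must be removable.
* Division uses the cached center of mass and the nearest periodic images
  of the cell's voxels; daughter surfaces are recomputed exactly from the
  relabeled lattice.
* Composition samples store all 144 phenotype rows per time, so row sums
  equal the live cancer count and downstream pivoting is trivial.
* The moving-average window is rounded to an odd number of samples; a
  window longer than the series is an error, and speeds at the series
  edges are NA rather than one-sided estimates (this keeps the speed of a
  time-reversed trajectory identical to the original).

## Scale profiles

The production configuration (200³ voxels, 580 kMCS, 21 replicates per
condition, periods up to 400 kMCS) is cluster work: at the engine's
~4 MCS/s on a 200³ lattice a single 580-kMCS run is on the order of two
CPU-days, and the full sweep (7 conditions × 21 replicates) roughly a
CPU-year.  The
package's own validation uses a desk profile chosen to keep the full test
suite in tens of minutes: a 48³ box, seed radius 16 (the spheroid spans a
third of the box with a healthy rim of ~8 voxels), 14 kMCS, 10 replicates,
linear dependency, static sink.  At this scale the spheroid reaches its
population plateau, division localizes to the rim and death to the center,
and the full analysis pipeline runs end to end.

What the desk scale does *not* provide is the mutation supply that makes
directional selection statistically visible run by run.  Turnover is
death-limited: with a generation time of several kMCS, a ~40-cell tumor
produces on the order of a hundred divisions — only a handful of mutation
events, some of which never touch the adhesion axis — in 14 kMCS, versus
on the order of a million divisions in a production run.  Aggregated over
replicates the adhesion centroid should drift toward low adhesion, but a
per-replicate strict decrease cannot be guaranteed at this scale; the
acceptance suite therefore reports the replicate count for this check at
desk scale, and the `scripts/experiments/` scripts document the larger
budgets (longer runs, larger boxes, more replicates) at which the
directional and period-dependence results are expected to resolve.

## Known limitations

* Nutrient transport is geometric (distance to a sink), not
  reaction-diffusion; moving nutrient *sources* are out of scope.
* No persistent random walks, polarization memory, or adhesion-motility
  trade-offs; phenotype axes are independent and discrete.
* Healthy tissue is immortal and non-dividing by construction.
* The threshold nutrient-dependency variant is exposed only as the
  `dependency_mode` hook ("none"/"linear"); it is not implemented.
* No MPI or multi-threaded sweeps; the engine is single-core.
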