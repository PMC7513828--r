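---
title: "A growth-factor feedback model of lineage proportioning in the blastocyst ICM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A growth-factor feedback model of lineage proportioning in the blastocyst ICM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The inner cell mass (ICM) of the mouse blastocyst allocates its cells to two
lineages — pluripotent epiblast (EPI, high NANOG) and primitive endoderm
(PrE, high GATA6) — in reproducible proportions within a narrow time window,
and it does so robustly: embryos tolerate cell loss, absorb foreign cells,
and scale their lineages with embryo size. `icmfate` implements a minimal
dynamical explanation of that robustness: a fate decision coordinated purely
by intercellular growth-factor signalling, with no direct intracellular
mutual repression required.

## The circuit

Each cell carries one dimensionless state variable, its NANOG level
$x_i \ge 0$. NANOG is produced under cooperative self-activation and
repressed by the average NANOG level of the cell's signalling neighbourhood
(which stands in for the local FGF4 concentration, since NANOG drives FGF4
secretion and FGF4/ERK signalling suppresses NANOG in the receivers):

$$\frac{dx_i}{dt} =
  \alpha\,\frac{(1+x_i^n)^m}{(1+x_i^n)^m+\left(\langle x\rangle_i/K\right)^{2m}}
  - x_i,$$

where $\langle x\rangle_i$ averages $x$ over cell $i$'s neighbours
*including itself*, $\alpha$ is the maximal production rate, $K$ the
repression threshold, and $n, m$ Hill/cooperativity exponents. This is
lateral inhibition through a secreted signal: high-NANOG cells push their
neighbours low.

For a perfectly mixed population split into two internally uniform clusters
(levels $x_a$, $x_b$), both clusters see the common field $(x_a+x_b)/2$ and
the system reduces to a plane. `two_cluster_rhs()`, `nullclines()` and
`find_equilibria()` analyse this reduction; at the package defaults the
portrait has two stable mirror equilibria (one cluster high, the other low)
and one unstable symmetric state on the diagonal — the geometric statement
that a split population is an attractor while an undecided, homogeneous
population is not.

### Default parameters

The exponents are fixed at $n = m = 2$ (the lowest cooperativity that
produces a robust double-well structure). $\alpha$ and $K$ are the model's
two free constants and were calibrated in two stages, mirroring how the
model is meant to be used: first a coarse numerical scan for the region
where the two-cluster reduction is bistable with well-separated states
(high:low ratio at least 5); then, within that region, selection of the pair
whose full agent-based wild-type simulations split into balanced epiblast
and PrE compartments on average. The shipped defaults are $\alpha = 4.5$,
$K = 0.9$, giving stable states at $x \approx 0.147$ and $x \approx 4.099$
(ratio $\approx 28$) and a saddle at $x \approx 2.199$.

```{r}
library(icmfate)
find_equilibria(circuit_params())
plot_phase_plane()
```

## The agent-based embryo

`grow_embryo()` embeds the circuit in a growing three-dimensional aggregate:

* **Mechanics.** Cells are overdamped soft spheres (radius 1, the model
  length unit): linear-spring repulsion proportional to overlap, a weak
  tent-shaped adhesion out to 1.5 summed radii, and a weak central spring
  standing in for the confinement the ICM experiences inside the
  blastocyst. The exact potential constants are implementation-level
  choices (stiffness 5, adhesion 0.5, drag 1, confinement 0.2); the
  sensitivity sweep shows the fate outcome does not depend on them.
* **Division.** Cell cycles last `mean_cycle = 10` h on average, jittered
  uniformly by ±30% per daughter; this asynchrony, plus a small
  multiplicative jitter ($e^{N(0,0.05^2)}$) on the inherited NANOG level,
  seeds the symmetry breaking. Time units: one circuit time unit is one
  hour (the NANOG turnover timescale).
* **Signalling graph.** Neighbours are cells within 1.5 summed radii
  (`signaling_range = "global"` gives the all-to-all limit). Each cell's
  repression field is the neighbourhood mean of $x$, self included.
* **Schedule.** A run starts from 2 progenitors at the unstable symmetric
  NANOG level (s.d. 0.1), switches the circuit on once the aggregate has 8
  cells, and stops the first time the live cell count reaches the target
  (27 by default) — the simulated embryo develops up to a fixed cell
  number and no further, with no post-growth settling phase. That stopping
  rule is load-bearing: it is what limits the dynamical time available to
  recover from late perturbations.
* **Commitment.** Identity thresholds bracket the saddle midway towards
  each stable state ($x < 1.17$: PrE; $x > 3.15$: EPI; in between:
  uncommitted progenitor, DP). A cell whose level stays beyond a threshold
  for `commit_persistence_hr = 6` h locks its fate irreversibly (its level
  can no longer cross back), matching the asynchronous and irreversible
  commitment observed in vivo. Recovery from perturbations therefore flows
  through uncommitted progenitors. Six hours (a few NANOG turnover times,
  below one cell cycle) was chosen so that wild-type progenitors are
  depleted by the 27-cell stage while perturbation responses remain
  possible as long as uncommitted cells exist; with commitment disabled
  (`irreversible = FALSE`) a fully committed population can collectively
  destabilise and re-split, which erases the stage dependence of ablation
  recovery.
* **ESCs.** Embryonic stem cells added by `run_chimera()` are frozen at the
  high-NANOG stable level: they secrete like epiblast (raising their
  neighbours' repression field) but never change fate; they divide like
  host cells, and the host grows to its normal target on top of them.

## The in-silico experiment suite

* `run_wildtype()` — growth to the target ICM; progenitors deplete and the
  population splits close to 50:50 on average.
* `run_scaling(factor)` — target size × 0.5 or × 2; fractional composition
  is preserved while absolute counts scale.
* `run_chimera(n_esc)` — ESC aggregation before circuit activation; host
  epiblast contribution decreases monotonically with the load until the
  epiblast is entirely ESC-derived, while total composition (ESCs counted
  as epiblast) is maintained for loads up to about twice the control
  epiblast.
* `ablate()` / `run_ablation_series()` — staged removal: growth pauses the
  first time the live count reaches the trigger stage, the chosen fraction
  of the target lineage is removed (rounding half away from zero, at least
  one cell), and growth resumes to the target. Uniform removal across
  lineages leaves composition unchanged at every stage; partial (30%)
  single-lineage removal is compensated while progenitors remain; total
  removal of a lineage recovers progressively worse at later stages because
  the uncommitted pool is spent. Division parameters are never modified, so
  there is no compensatory proliferation — only re-routed fate choice.
* `sensitivity_sweep()` — batches over parameter grids (±50% around the
  defaults); wherever bistability survives, mean epiblast fraction stays in
  a balanced band, and the global-coupling limit behaves like
  nearest-neighbour coupling.

## The classification pipeline

The measurement side of the package mirrors how segmented-fluorescence
tables and time-lapse GFP tracks are processed:

1. `zdecay_correct()` — per embryo and channel, log intensity is regressed
   on imaging depth and the slope component removed; `mode = "eb"` first
   shrinks per-embryo slopes towards the litter mean with normal-normal
   precision weights, with the between-embryo variance estimated by the
   method of moments (zero truncation gives full pooling). The exact
   shrinkage form is a package choice; the published description names the
   step but not its formula.
2. `harmonize_antibody()` — affine mapping between antibody scales, fitted
   on double-stained cells by least squares.
3. `rescale_by_litter()` — channels divided by their per-litter maxima
   (litters are the experimental unit).
4. `classify_icm()` — agglomerative UPGMA (average-linkage) clustering on
   the rescaled (NANOG, GATA6) plane with Euclidean distance, tree cut at
   `k = 4`; clusters are named from their centroids relative to the
   highest centroid per channel (both high → DP; high NANOG only → EPI;
   high GATA6 only → PrE; both low with NANOG dominant → NANOG-lo).
   Cells with both channels below 0.1 are set aside as double negative
   before clustering. Rows are sorted by `cell_id` first, so the result is
   invariant to input row order.
5. `smooth_gfp()` / `classify_track()` — tracks are smoothed with a
   4-frame (1 h) centred moving average (window shrinking at the edges),
   then classified by two rules: committed identities are permanent, and a
   progenitor switches at the first frame of the earliest run of at least
   2 h (8 frames at 15-min spacing) spent continuously beyond the
   per-frame linearly interpolated threshold. A cell qualifying for both
   fates on the same frame is flagged ambiguous rather than guessed.
   Assigning the switch at the *start* of the qualifying run (not its end)
   is a documented, configurable choice.
6. `survival_curve()` — product-limit (Kaplan–Meier) estimates per group
   from death/censoring times; the half-life is the first time survival
   reaches 0.5, undefined if it never does. Death is timed at the first
   frame at which a cell is observed dead, so times are ceiling-discretised
   to the 15-min frame grid.

## Synthetic data

The generators produce the two data products the pipeline consumes, with
known truth:

* `synth_embryo_table()` / `synth_litter()` — per-cell tables with uniform
  depth positions, identity-specific log-normal channel intensities
  (locations separated by ~5 noise s.d., so clustering is solvable but not
  trivial), a configurable log-linear depth decay, and a shared log-normal
  intensity factor per litter. The default composition is the late-stage
  wild type: 60% PrE, 40% epiblast, no remaining progenitors.
* `synth_timelapse()` — 15-min-frame tracks over an 18 h movie (within the
  16–20 h range of real movies): PrE drifts upward on a normalised GFP
  scale, epiblast sits on a low plateau, progenitors start intermediate and
  drift towards a fate after an exponential waiting time; targeted cells
  die with memoryless (exponential) timing at half-life 3.4 h, censored at
  the movie end. The exponential form is the simplest model consistent
  with a single reported half-life.

What the generators deliberately do not emulate: segmentation errors,
mitotic intensity artefacts, spatial intensity correlations, or non-normal
noise. Passing the recovery tests therefore demonstrates that the pipeline
is correct and well-calibrated on clean tabular data of the right shape,
not that it is robust to every artefact of real microscopy.

## Numerical choices

* Equilibria: sign-change scan on a 200×200 grid with Newton refinement
  (residual tolerance 1e-9); eigenvalue real parts within 1e-8 of zero are
  labelled "marginal" rather than silently classified.
* Integration: explicit Euler with a shared `dt = 0.01` h step for
  mechanics, circuit and division scheduling; the integrator is validated
  against an adaptive solver, and trajectories leaving
  $[0, 1.05\,\alpha]$ raise a step-size error rather than continuing.
* Mechanics displacement is capped at 0.1 radius per step (velocity
  clamping) inside the growth loop; the exposed `step_positions()` errors
  instead by default.
* Degenerate inputs (empty ablation targets, coincident cell centres,
  too-few cells for a depth fit, `k` larger than the table) raise errors;
  nothing is silently imputed.

## Problem sizes used by the checks

The test suite runs the wild-type batch at 60 seeds, scaling at 40 seeds
per size, ablation arms at 20 seeds, and chimera loads at 12 seeds; the
acceptance script runs 100 wild-type seeds, 50 synthetic embryos and 200
death tracks. These sizes keep the sampling error of each batch mean well
inside the tolerance it is compared against, since the per-run spread of
final lineage fractions is a few percentage points.

## Known limitations

* The reduced one-variable circuit cannot represent cell-autonomous
  bistability; irreversible commitment is therefore imposed by the
  persistence ratchet rather than emerging from the molecular network.
* Simulation time is reported in model hours and developmental stage as
  live ICM cell count; no mapping to hours post-fertilisation is attempted.
* The ICM is modelled in isolation (no trophectoderm, cavity or lumen
  mechanics, no wild-type apoptosis programme).
* The two-cluster analysis assumes perfect mixing; on sparse neighbour
  graphs the realised split ratio fluctuates seed to seed even though the
  batch mean is balanced.
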