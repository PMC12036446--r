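---
title: "Beam-angle optimization by ADMM with a QUBO selection subproblem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-angle optimization by ADMM with a QUBO selection subproblem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Proton therapy plans deliver dose from a handful of beam directions; each
beam is a lattice of pencil-beam "spots" whose intensities are optimized so
the summed dose covers the target and spares organs at risk (OARs).
Choosing which `N` directions to use out of `B` candidates — beam-angle
optimization (BAO) — is a mixed-integer program:

$$
\min_{x, y} \; f\!\Big(\sum_{i \in B} y_i A_i x_i\Big)
\quad \text{s.t.} \quad
x_i \in \{0\} \cup [G, \infty),\;
\sum_i y_i = N,\; y_i \in \{0,1\},
$$

where `A_i` is beam *i*'s dose-influence matrix (spot intensities to voxel
dose), `y_i` selects beams, and `G` is the minimum monitor unit (MMU): a
deliverable spot is either off or at least `G`.

`qcbao` solves this by operator splitting.  An auxiliary copy `z_i = x_i`
carries the MMU constraint, giving the augmented Lagrangian

$$
f\Big(\sum_i y_i A_i x_i\Big)
+ \frac{\mu_1}{2}\sum_i \lVert x_i - z_i - \lambda_{1i}\rVert^2
+ \frac{\mu_2}{2}\Big(\sum_i y_i - N + \lambda_2\Big)^2 ,
$$

minimized by sequential block updates with dual ascent
(`lambda1 += z - x`, `lambda2 += sum(y) - N`).

A note on the dual sign: with the proximal step written on `v = x - lambda1`
and the dual ascent written as `lambda1 += z - x`, the only self-consistent
scaled-ADMM bookkeeping stores the *negated* scaled dual, which makes the
x-step's consensus anchor `z + lambda1`.  All three formulas in the code
follow that single convention.

## The objective and iterative convex relaxation

`f(d)` is a weighted sum of per-structure terms
(see `prescription_term()`):

* **target least squares** — two-sided pull of target dose to the
  prescription `b`;
* **OAR least squares** — one-sided penalty on dose above `b` (a config
  flag makes it two-sided; pulling cold OAR voxels *up* to `b` is never
  useful);
* **DVH-max** — at most a fraction `p` of the structure may exceed `b`:
  when the dose at rank `ceil(p n)` of the descending sort violates the
  bound, the violating tail enters the active set;
* **DVH-min** — at least a fraction `p` of the target must reach `b`; cold
  voxels within the top `ceil(p n)` ranks activate.

Each outer iteration re-identifies these active sets from the current dose
(iterative convex relaxation), after which the objective is a plain
weighted least squares on the active voxels,
`sum_k alpha_k (d_k - beta_k)^2 + const` (`voxel_quadratic()`).  Voxels in
several terms get summed coefficients and a weighted-mean level, with the
constant tracked so totals are preserved exactly.  Active sets are frozen
for the whole iteration and shared by the x-, z- and y-updates; that
freezing is precisely what makes the y-subproblem a QUBO.

Rank ties are broken by stable sort on voxel index; DVH active sets are
intersected with the actually violating voxels so satisfied voxels are
never dragged toward the bound.

## Block updates

* **x** (intensities): for a selected beam, the subproblem is unconstrained
  weighted least squares; we solve the normal equations
  `(2 A' D_alpha A + mu1 I) x = 2 A' D_alpha r + mu1 (z + lambda1)`
  directly (spot counts are small; `mu1 > 0` guarantees nonsingularity).
  A deselected beam keeps only the consensus term, minimized at
  `z + lambda1`.  Beams are swept Gauss–Seidel style in a seeded random
  order each sweep: with a fixed order, the first-updated beams absorb
  most of the prescription sweep after sweep and the selection step
  inherits that bias.
* **z** (MMU prox): componentwise on `v = x - lambda1`,
  `z = max(G, v)` if `v >= G/2`, else `0` — the exact projection onto
  `{0} ∪ [G, ∞)`, with the tie at `v = G/2` rounded up to `G`.
* **y** (selection): with everything else frozen the objective restricted
  to `y` expands exactly (using `y^2 = y`) into a QUBO over `{0,1}^B`
  (`assemble_qubo()`), solved by one of three backends: exhaustive
  enumeration (`B <= 20`; the ground-truth oracle), best-of-reads
  simulated annealing (default; 32 reads, 1000 sweeps on a geometric
  inverse-temperature schedule scaled to the coefficient magnitudes), or a
  bitstring genetic algorithm (tournament selection, uniform crossover,
  elitism 1) mirroring a classical mixed-integer baseline.

## Two-step pipeline

**Step 1** alternates [active-set refresh → x → z → y → duals] for
`T_outer` (default 10) iterations.  **Projection** then restores exact
cardinality if the soft penalty left `sum(y) != N`, greedily toggling the
beam whose flip least increases the restricted objective.  **Step 2**
re-runs the iteration with `y` frozen (`T_refine` up to 500 iterations,
early stop at relative objective change `1e-6`), warm-started from the
Step-1 state.  Final intensities are the consensus copies `z` of the
selected beams — MMU-feasible by construction of the proximal step.

The reported plan objective is the objective at the final `z`-dose with
freshly identified active sets.

### Initialization policy

Two choices here are deliberate and worth recording:

* **Start with every candidate on** (`init_y = "full"`).  The OAR terms
  are one-sided: a beam that delivers no dose produces no active OAR
  voxels, so its OAR cost is invisible to the frozen-set QUBO.  Starting
  from an exactly-`N` random subset is in fact a fixed point of the
  alternation whenever the binary subproblem is solved well — the first
  x-update fits the incumbent subset to the prescription, after which no
  swap can look attractive.  Starting all-on at delivery scale exposes
  every candidate's footprint to the first refresh, and the cardinality
  penalty prunes the set informedly.  `init_y = "subset"` retains the
  random-subset start for study.
* **Delivery-scale intensities.** Spots start near `s_i/2` with
  `s_i = 2 D_p / (N \cdot \bar{t}_i)`, where `\bar{t}_i` is beam *i*'s mean
  target dose at unit intensities, randomized per spot by `U[0.4, 1.6]`.
  At this scale OAR and DVH terms activate from the first iteration; the
  randomization gives independent restarts genuinely different
  trajectories.

### Penalty parameters

`mu1` auto-scales to the mean diagonal of the per-beam Hessians
`2 A' D_alpha A` at initialization — the natural curvature scale of the
dose term.  Step 1 uses factor 1.0 (intensities adapt gradually while the
selection settles); Step 2 uses 0.1 (fast refinement of a frozen
selection).  Setting `mu1` orders of magnitude above this scale freezes
the intensity update; far below it, the consensus copies decouple.

`mu2` governs pruning pressure and is the one hyperparameter tuned:
`qcbao_tune()` crosses the grid `{0.01, 0.1, 1, 10, 50}` with `n_runs = 5`
independent seeded restarts, reports mean ± sd per grid point, and returns
the best run (lowest objective) as the headline plan.  Headline results
should always come from this protocol: a single alternation run is a local
method and its quality varies with the restart.

## Synthetic phantoms

The generator replaces clinical CT + dose-engine input so the pipeline is
testable end to end.  Grids are 2D (couch angles are carried as candidate
labels and do not change 2D geometry); the dose model is an analytic
pristine Bragg peak — entrance plateau with a logistic roll-off at the
range plus a Gaussian peak — times a depth-growing Gaussian lateral kernel,
deposited only inside the body, with spots on a lateral-offset × range-layer
lattice covering the target's beam's-eye view.  This is the minimal model
in which the *choice of angle* changes OAR dose, which is all the optimizer
sees.  It does not emulate tissue heterogeneity, range straggling,
scattering tails, or 3D couch geometry, so passing tests say nothing about
dosimetric accuracy on real CT data — they validate the optimization
machinery.

Presets: `centered-target` (mirror-symmetric; used for geometric
consistency checks), `offset-target-with-oar`, and `planted-corridor` — an
annular OAR around a central target with a seeded angular gap, so beams
entering through the gap are geometrically right *by construction*; with 8
candidates this is small enough that all 56 three-beam subsets can be
refined and ranked exhaustively, giving a recovery oracle.

The default phantom objective uses weight 10 for the target, OAR and
DVH terms and adds a weight-0.25 one-sided body term at 10% of the
prescription.  The body term plays two roles: it is the standard
integral-dose (mean body dose) sparing objective, and it keeps the optimal
objective value of order 10 rather than near zero — on the corridor
phantom the best subset would otherwise refine to ~1e-3, at which point
*relative* plan comparisons measure convergence noise instead of plan
quality.

## Numerical choices

* Sparsity floor: dose-influence entries below `1e-6` of their column
  maximum are dropped.
* Normal-equation solves are direct (dense Cholesky via `solve`); spot
  counts per beam are tens, not thousands.
* QUBO assembly uses a zero diagonal with `y^2 = y` folded into the linear
  part; exhaustive enumeration breaks ties toward the lexicographically
  smallest vector; SA is deterministic per seed (its own RNG stream,
  independent of R's).
* D95 normalization (scale so 95% of the target receives the prescription;
  `D95` is the `ceil(0.95 V)`-th largest target dose) is recorded as a
  scale factor and applied to reported *metrics*; intensities are reported
  raw so the MMU guarantee is never silently broken by scaling.
* Degenerate inputs: empty active sets make the x-update consensus-only;
  `mu2 = 0` removes cardinality pressure (the projection step still
  enforces feasibility); a target with zero dose makes D95 normalization
  an error rather than a division by zero.

## Problem sizes in the test suite

Unit and acceptance tests run on 21×21 to 31×31 grids (3 mm spacing,
441–961 voxels), 4–8 candidate beams for solver tests and the 72-candidate
(24 gantry × 3 couch) grid for feasibility tests, with 2–3 range layers
and ~9–27 spots per beam.  The corridor-recovery check enumerates all 56
subsets as its oracle and runs five independent tuning protocols.  These
sizes keep every property checkable by brute force while exercising the
same code paths a clinical-scale instance would.

## Limitations

* Couch angles are labels in 2D; non-coplanar geometry is not modeled.
* The annealer is a classical sampler; the backend interface is pluggable
  but no quantum-hardware client is included.
* ADMM on this nonconvex problem has no monotonicity guarantee; consensus
  residuals are reported in the trace rather than asserted.
* Deliverability beyond the MMU rule (collision, arc constraints) is out
  of scope.
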