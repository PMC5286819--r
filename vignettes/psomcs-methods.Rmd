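---
title: "psomcs: methods, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{psomcs: methods, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psomcs)
```

## The model

A metabolic network is a stoichiometric matrix $N$ (m metabolites ×
n reactions) with steady-state constraint $Nr = 0$, sign constraints
$r_i \ge 0$ for irreversible reactions, and flux bounds.  A strain
design is a threshold vector $x$ over yield-ratio objectives at unit
reference uptake.  It induces two polyhedra over flux space:

* the **target (undesired) region**: unit reference uptake and product
  yield *strictly below* $x_1$;
* the **desired region**: unit reference uptake, product yield
  $\ge x_1$, and one existence row per further objective (e.g. growth
  yield $\ge x_2$).

A knockout set $S$ realizes the design when the target region becomes
infeasible under $r_i = 0\ (i \in S)$ while the desired region stays
feasible.  Minimal such sets (cMCS) are found from the dual system: by
Farkas' lemma the knocked-out target region is empty exactly when
multipliers $u$ (free), $w \ge 0$ (target rows) and a free vector
supported on $S$ (split as $vp - vn$, $vp, vn \ge 0$) combine to a
componentwise-valid certificate.  Binary indicators $zp, zn$ linked to
$vp, vn$ make "smallest cut set" a MILP objective
$\min \sum_i (zp_i + zn_i)$ with the exclusivity row $zp_i + zn_i \le 1$,
a cardinality cap, and an embedded primal block ($Nr = 0$, $Dr \le d$,
$r_i = 0$ whenever $zp_i \lor zn_i$) that keeps the desired region
alive.  One MILP solve yields one optimal cMCS; no-good cuts
$\sum_{i \in S}(zp_i + zn_i) \le |S| - 1$ enumerate the minimum
stratum.

The outer search over $x$ is a constriction-coefficient particle swarm
with the fitness $F(x) = (1 - |cMCS|/n)\,\prod_i x_i / x_i^{max}$; an
infeasible MILP (no cut set within the cap, or an empty desired region)
scores 0.

## Strictness of the target region

The dual constraint $t^T w \le -c$ with any $c > 0$ certifies
infeasibility of the *closed* region $\{Tr \le t\}$.  That is the wrong
region at the boundary: when $x_1$ equals the strain's maximal yield the
closed region $\{yield \le x_1\}$ contains the desired flux itself, so
no certificate can exist — yet "eliminate every state with yield
*strictly below* $x_1$" is exactly achievable there, and the
worked-example optimum (threshold 1, cut set {R2, R9}) lives on that
boundary.  The package therefore implements the full transposition
disjunction for strict rows, selected by one auxiliary binary:

* branch 1: $t^T w \le -c$ (the closed-region certificate);
* branch 2: $t^T w \le 0$ and total weight $\ge c$ on the strict rows.

Branch 2 is sound (a positive strict-row weight turns the combined
inequality strict) and is what makes boundary thresholds solvable.
$c$ is fixed to 1: the certificate cone is homogeneous, so any positive
value gives the same supports.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `chi` | 0.7298 | constriction coefficient; the standard value from the PSO literature |
| `phi1`, `phi2` | 2, 2 | cognitive/social acceleration constants, the common choice |
| `n_particles` | 10 | default swarm size for medium/genome-scale models; the worked example uses 4 |
| `max_iterations` | 40 | iteration cap (worked example: 2 suffice to see convergence begin) |
| `stagnation_window` | 10 | stop after this many iterations without global-best improvement; the stopping rule names the criterion, not the number |
| `max_cardinality` | 5 | cut-set size cap; MILP cost grows quickly beyond it |
| `M` (big-M) | 1e3 | indicator linking and dual bounds; matches the flux-bound scale.  Too small an M can silently drop cut sets whose certificates need large weights |
| LP tolerances | 1e-9 pivot, 1e-7 feasibility | standard numeric floors for a double-precision simplex |
| blocked-reaction tolerance | 1e-9 | FVA range below this counts as blocked |
| subset tolerance | 1e-8 | relative tolerance for null-space proportionality in compression |
| essentiality threshold | 1e-6 | a knockout forcing a protected reaction's maximum below this marks the reaction essential |

## Design choices where the design was open

* **Neighborhood vs global best.**  The velocity update uses the best
  position among a particle's informants — itself, four fixed ring
  neighbours (±1, ±2 modulo swarm size), and one random informant
  redrawn each iteration — while the overall global best is tracked for
  reporting and stopping.  The limited topology matches the stated
  four-connections design; ring is the canonical shape when none is
  given.
* **Velocity initialization** is uniform in ±(yield range width) per
  dimension; unspecified in the source material, standard practice.
* **Synchronous iterations**: all particles are evaluated, then all
  personal bests update, then all moves happen.  Particle evaluations
  are independent (results are memoized per position in a cache, the
  only shared state).
* **Position clamping** to the FBA yield bounds with velocity zeroing:
  outside the bounds the region pair is meaningless.
* **Desired region contains the product-yield row** by default (so the
  surviving mode itself meets the design), switchable via
  `include_product_in_desired`.
* **β ∈ (0,1]** is drawn as `1 - runif()` since `runif()` samples
  `[0,1)`.
* **Tie-breaking among equal-cardinality optima** is whatever the
  (deterministic, single-threaded) branch-and-bound finds first;
  reproducibility comes from the seed and the fixed variable order.
* **Solver**: no LP/MILP library exists in the target R environment, so
  the package carries a dense two-phase simplex (Dantzig pivoting with
  most-stable-pivot tie-breaking, Bland fallback during degenerate
  stalls, row equilibration) and a depth-first branch-and-bound with
  ceiling-rounded bounds for the integer-valued cardinality objective.
  The test suite cross-validates it against an independent solver
  (scipy's HiGHS) on random LPs and against exhaustive enumeration on
  binary programs.

## What the synthetic generator emulates — and what it does not

`generate_random_network()` builds a guaranteed-consistent spine
(uptake → chain through all metabolites → secretion), extra secretions,
and random conversions, condensations and cleavages.  Every metabolite
carries an integer weight (a stand-in for carbon count, non-increasing
along the spine) and every reaction conserves or loses weight,
reversible reactions conserving it exactly.  Weighted mass balance then
bounds every yield per unit uptake — no amplifying cycles — and
cleavages ($a \to b + c$) provide the obligatory-byproduct structure
that makes growth-coupled designs possible at all: without them, any
"growth" sink can be fed without co-producing anything, and no knockout
couples product to growth.

The generator does *not* emulate: cofactor/redox balancing, reaction
reversibility patterns of real metabolism, gene–protein–reaction
structure, or realistic degree distributions.  A green test on these
networks establishes the correctness of the LP/MILP/search machinery,
not biological realism of designs.

## Attainment of optima by a continuous swarm

The fitness surface is piecewise smooth: within a region of constant
optimal cut set, $F$ grows with $x$ up to the strain's FVA-minimal
yield (a breakpoint), then drops.  Two cases matter:

* the breakpoint coincides with a clamped bound of the search box (the
  worked example: threshold 1 = maximal yield).  Clamping puts particles
  exactly on it; the optimum is attained exactly, and the acceptance
  tests require exact attainment there.
* the breakpoint is interior to the box.  A continuous swarm approaches
  it geometrically (velocities contract at rate χ) but hits it exactly
  only with probability zero, while a grid oracle "attains" it whenever
  rational yields land on grid nodes.  The supplementary swarm test
  therefore asserts ≥ 99% of the grid optimum on such instances, a
  convergence statement, not an optimality gap.

## Degenerate inputs and edge cases

* Threshold $x_1 = 0$ (or below the wild-type minimum): the strict
  target region is empty, the empty cut set is optimal and the MILP
  returns cardinality 0.
* An empty desired region at a given $x$ makes the MILP infeasible;
  the particle scores 0 and the swarm moves on.
* Exchange reactions are auto-detected as single-entry columns;
  spontaneous reactions have no standard SBML flag and are supplied as
  an annotation list.
* Unbounded FVA directions are serialized as ±1e3, never infinity.
* Compression of a network whose kernel is one-dimensional (a single
  pathway) would merge everything into an all-zero column; compression
  is intended after reduction, on networks with genuine branching.
* Knockout exclusions come *after* compression in the pipeline; a
  merged subset is knockable if any member is, and decompression picks
  the first knockout-allowed member (any member silences the subset).

## Known limitations

* Big-M indicator linking can, in principle, exclude cut sets whose
  dual certificates need weights above M = 1e3; solver-native indicator
  constraints would remove the caveat but require an external MILP
  solver.
* The dual encodes sign constraints and target rows only; finite flux
  bounds are assumed non-binding inside the unit-uptake yield space
  (true for the default ±1000 bounds, and validation always re-checks
  candidate cut sets with bounded LPs).
* One strict (product-yield) row per design: multiple simultaneous
  guaranteed-yield objectives would need a union of target regions,
  i.e. several MILPs.
* The dense tableau simplex is built for desk-scale networks (hundreds
  of rows); genome-scale models would need a sparse factorized solver
  behind the same `solve_lp()` contract.
* Knockouts are at reaction level; no gene–protein–reaction rules, no
  regulatory (up/down-regulation) interventions, no thermodynamic
  constraints.
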