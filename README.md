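# psomcs

Growth-coupled strain design for constraint-based metabolic models, by
particle swarm optimization over design thresholds coupled with direct
MILP enumeration of constrained minimal cut sets (cMCS).

## The problem

A metabolic engineer wants a knockout strain whose *guaranteed minimal*
product yield is as high as possible — not just the optimistic FBA
optimum — while growth remains possible and the number of knockouts stays
small.  For a stoichiometric network `N` (m metabolites × n reactions) a
steady-state flux vector `r` satisfies

    N r = 0,   r_i >= 0  for irreversible i.

A design is stated as a pair of linear flux regions at unit reference
uptake: an **undesired (target) region** `T r <= t` — e.g. all states
with product yield strictly below a threshold `x₁` — which the knockouts
must render infeasible, and a **desired region** `D r <= d` — e.g. a
state with growth yield at least `x₂` — which must survive.  A
**constrained minimal cut set** is an inclusion-minimal reaction set
whose removal achieves both.

cMCS are computed directly from a Farkas-type dual of the target system:
a certificate `(u, vp, vn, w ≥ 0)` with

    Nᵀu + vp − vn + Tᵀw  = 0  (reversible rows)   ≥ 0  (irreversible rows)

and a strictness condition on `tᵀw` proves the knocked-out target region
empty, where the support of `vp, vn` *is* the cut set.  Minimizing
`Σ(zpᵢ + znᵢ)` over binary indicators linked to `vp, vn` — with an
embedded primal block `N r = 0, D r ≤ d, rᵢ = 0` on knocked-out
reactions — yields one smallest cMCS per MILP solve.

The threshold vector `x` is not known in advance: the best achievable
design is found by a particle swarm with constriction dynamics

    vᵢ ← χ { vᵢ + φ₁β₁ (pᵢ − xᵢ) + φ₂β₂ (gᵢ − xᵢ) },   xᵢ ← xᵢ + vᵢ

(χ = 0.7298, φ₁ = φ₂ = 2, ring-plus-random informant topology) maximizing
the fitness

    F(x) = (1 − |cMCS|/n) · Πᵢ xᵢ / xᵢ(max).

The package ships its own exact dense-simplex LP solver and
branch-and-bound MILP (no external solver needed), network reduction and
subset compression, FVA production envelopes, brute-force oracles used
to verify the MILP on small networks, and a CLI.

## Worked example

The bundled 9-reaction network has three substrate inputs (R1–R3) and
three secretions; the design objective is the guaranteed yield of R4 per
unit total uptake:

```r
library(psomcs)
net  <- toy_network()
spec <- toy_design()
res  <- run_pso(net, spec, pso_config(n_particles = 4,
                                      max_iterations = 30, seed = 1))
print(res)
#> design result: best fitness 0.777778 at x = ( 1 )
#> cut set {R2, R9} cardinality 2 valid=TRUE minimal=NA
#> iterations: 11  MILP calls: 48

production_envelope(net, "R4", knockouts = res$best_cutset$reactions,
                    reference = c("R1", "R2", "R3"))
#>   growth product_min product_max
#> 1     NA           1           1
```

The swarm converges to threshold x = 1: knocking out {R2, R9} blocks all
flux through R5 and R6, so every surviving steady state converts all
substrate to R4 — the guaranteed minimal yield is 1 (the envelope's min
and max coincide), achieved with 2 of 9 knockouts, hence fitness
(1 − 2/9)·1 ≈ 0.778.

The same run from the command line:

```sh
Rscript -e 'psomcs::psomcs_main()' run \
  --config inst/extdata/toy_design.json --out toy_out --seed 1
# toy_out/: result.json cutsets.tsv trace.csv envelope.csv milp_log.csv config.json
```

## Layout

- `R/network.R`, `R/reduce.R` — model I/O (SBML L3+FBC, tabular),
  validation, medium reduction, subset compression, knockout exclusions
- `R/lp.R`, `src/simplex.cpp` — LP/MILP solver
- `R/fba.R` — FBA, FVA, yield bounds, flux regions, envelopes
- `R/design.R`, `R/dual.R` — threshold → regions → dual MILP → cMCS
- `R/pso.R` — the swarm
- `R/synthetic.R` — fixtures, random networks, brute-force oracles
- `R/cli.R` — `run`, `envelope`, `synth`, `validate` subcommands

See `vignettes/psomcs-methods.Rmd` for the model, numerical choices and
limitations.
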