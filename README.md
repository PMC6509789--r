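# paretoflux

Multi-objective Pareto-front analysis of constraint-based metabolic models.

Living cells juggle competing objectives — growth, ATP yield, carbon
efficiency, export of storage compounds or of products like H₂ — and the
observed phenotype is a trade-off among them, not the optimum of any single
one. Classical flux balance analysis (FBA) optimises one linear objective
over the steady-state flux polytope `S·v = 0, α ≤ v ≤ β`; paretoflux extends
this to *n* objectives at once, mapping the n-dimensional Pareto front with
the Normalized Normal Constraint (NNC) method: anchor points (single-task
archetypes), scale-free normalisation of objective space, an even lattice on
the utopia hyperplane through the anchors, one constrained LP per lattice
point, and dominance filtering. It is aimed at systems biologists studying
metabolic trade-offs (for instance in photoheterotrophs, where light-limited
growth competes with carbon efficiency and biofuel H₂ production) and at
metabolic engineers who need to know what a design goal costs the rest of
the network.

Alongside the core method the package provides:

- FBA with deterministic minimum-total-flux refinement of alternate optima,
  flux variability analysis (FVA), transport-sum minimisation, single-gene
  knockout scans over GPR rules, doubling-time conversion, and bisection
  fitting of an uptake bound to a measured growth rate;
- GX-FBA, transcriptome-constrained flux prediction across an environment or
  carbon-source transition (objective `Z = Σ log₂(C) · v/v̄` over
  expression-mapped reactions);
- Roels degree-of-reduction electron accounting
  (`κ = (4C + H − 2O − 3N − charge)/C`) and element/charge balance checking
  of reactions and lumped conversion equations;
- readers/writers for SBML (Level 2 and Level 3 + fbc) and a plain tabular
  model dialect, YAML medium configs, and a bundled analytically solvable
  "toy phototroph" network;
- tidyverse-style results: tibbles everywhere, `tidy()`/`glance()` on fitted
  objects, `autoplot()` heat maps of fronts, and a thin command-line front
  end (`inst/cli/paretoflux.R`) with `fba`, `fva`, `knockout`, `fit`,
  `mofa`, `gxfba`, `balance` and `fixtures` subcommands.

## Worked example

The toy phototroph couples light-driven ATP supply to acetate metabolism,
with an ATP-consuming H₂-evolving electron sink. With a photon cap of 50 and
an acetate cap of 10 the closed-form growth optimum is 1 h⁻¹:

```r
library(paretoflux)

toy <- make_toy(P = 50, A = 10)
sol <- fba(toy)
sol
#> <flux_solution> growth: optimal, objective = 1

front <- run_mofa(mofa_problem(
  toy,
  list(biomass_objective(toy), reaction_objective("EX_h2", label = "H2")),
  spacing = 10
))
front
#> <pareto_front> 2 objectives, spacing 10: 11 unique Pareto-optimal of
#>   11 feasible lattice points (0 skipped)

tidy(front)[c(1, 6, 11), ]
#>   point norm_growth  norm_H2 raw_growth raw_H2
#> 1     1         1.0 9.09e-10        1.0    9.0
#> 2     6         0.5 5.00e-01        0.5   14.5
#> 3    11         0.0 1.00e+00        0.0   20.0
```

The front reads as `H₂ = 20 − 11·growth`: at maximum growth the network
already exports 9 units of H₂ (the obligatory electron sink), every extra
unit of H₂ beyond that costs 1/11 of the growth rate, and maximum H₂
production (20, i.e. 2 per acetate) stops growth entirely.
`autoplot(front)` renders the front as the usual solutions-by-objectives
heat map.

Electron bookkeeping ties the boundary flows together:

```r
degree_of_reduction("CH1.93O0.54N0.22")  # biomass kappa
#> [1] 4.19
boundary_electron_balance(toy, sol)      # ~0 on any balanced steady state
#> [1] 1.42e-14
check_overall_equation(
  "CH0.71O0.43 + 0.2 NH4+ + 0.26 H2O -> 0.9 CH1.93O0.54N0.22 + 0.1 CO2 + 0.29 H+"
)$balanced
#> [1] TRUE
```

Genome-scale SBML models load with `read_sbml()`; `paper_scenarios()`
provides the standard photoheterotrophic condition ladder (fixed acetate
uptake, CO₂ export pin, CBB knockout, fitted light cap, H₂ archetype) as
role-based configs that a per-model name map resolves onto whatever
identifiers the model uses.

See `vignettes/multiobjective-flux.Rmd` for the full account of the method,
its parameters and its numerical choices.

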