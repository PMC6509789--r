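---
title: "Multi-objective flux analysis with paretoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective flux analysis with paretoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretoflux)
```

## The modelling framework

paretoflux works with stoichiometric models of metabolism: a matrix $S$
($m$ metabolites $\times$ $n$ reactions) whose columns encode reaction
stoichiometries. Under the steady-state assumption every internal metabolite
balances,

$$\frac{dX_i}{dt} = \sum_j S_{ij}\,\nu_j = 0,$$

and each flux is boxed by physiological bounds
$\alpha_j \le \nu_j \le \beta_j$ (mmol gDW$^{-1}$ h$^{-1}$; the biomass flux
is in h$^{-1}$ and converts to a doubling time as $\ln 2/\mu$). Flux balance
analysis (FBA) picks from this polytope the flux vector maximising a linear
objective — classically growth. Exchange reactions carry material across the
system boundary with the usual sign convention: uptake is negative flux, so a
medium entry `uptake_max: 1.96` becomes a lower bound of $-1.96$ and measured
uptake rates can be entered with their published sign.

Alternate optima are endemic in FBA: the optimal face of the polytope is
rarely a single vertex, and any statement about individual flux routes (say,
the split between two CO$_2$-fixation pathways) is degenerate without a
tie-break. All solutions returned by `fba()` (and every downstream method)
are therefore refined, by default, to the representative minimising total
flux $\sum_j |\nu_j|$ at the fixed objective optimum. Route shares that
matter scientifically should still be reported as ranges via `fva()`, which
computes each reaction's attainable $[\nu^{\min}_i, \nu^{\max}_i]$, optionally
above a biomass floor.

## Mapping trade-offs: the Normalized Normal Constraint method

A single-objective optimum says nothing about the price of pursuing a second
goal. Multi-objective flux analysis maps the Pareto front of $n \ge 2$
objectives $\{z_1(\nu), \dots, z_n(\nu)\}$: the set of flux states where no
objective can improve without another deteriorating. paretoflux implements
the Normalized Normal Constraint (NNC) method, which produces evenly
distributed Pareto points on convex and non-convex fronts for any number of
objectives, and whose results are invariant to the objectives' scales:

1. **Anchors.** For each objective $k$, the lexicographic optimum (objective
   $k$ first, then minimum total flux) is an *anchor* — the theoretical
   archetype phenotype for that single task. Each anchor is evaluated under
   all $n$ objectives, giving $n$ points in objective space.
2. **Normalisation.** Each objective is mapped affinely onto $[0,1]$ in
   maximisation sense: 1 at its best anchor value (the utopia coordinate), 0
   at its worst (the nadir over anchors). Minimisation objectives are negated
   first, so dominance is uniformly "larger is better". If an objective is
   constant across all anchors its range collapses; the normalisation guard
   maps it to 0 with unit scale rather than dividing by zero.
3. **Utopia hyperplane and lattice.** The plane through the $n$ normalised
   anchors is sampled at all weight vectors $w$ with entries in
   $\{0, 1/m, \dots, 1\}$ summing to 1 — `generate_utopia_lattice(n, m)`,
   $\binom{m+n-1}{n-1}$ points in deterministic lexicographic order
   ($m = 10$, $n = 8$ gives 19448).
4. **Per-point LPs.** At plane point $p = \sum_k w_k \bar e_k$, the $n-1$
   normal half-spaces $(\bar e_n - \bar e_k)\cdot(\bar z - p) \le 0$ are added
   to the model constraints and the *last-declared* objective is maximised.
   The half-space direction follows from translating the method's canonical
   minimisation form into maximisation sense; with the opposite sign every
   lattice point provably collapses onto the last anchor, which is a useful
   smoke test for any reimplementation. Which objective is "the lone one" is
   a free choice in the method; paretoflux uses the last in the declared
   order, and reordering the list changes it.
5. **Filtering.** Lattice points can be infeasible (non-convex reachable
   sets); they are counted and reported, not fatal. Feasible solutions are
   de-duplicated (normalised vectors equal after rounding to 6 decimals) and
   dominance-filtered at tolerance $10^{-6}$. Unique-solution counts are
   sensitive to exactly these two constants, which is why counts are
   reported but never treated as a reproducible quantity of the method.

On a two-objective problem the NNC front must coincide with an
$\varepsilon$-constraint sweep, and the test suite holds the implementation
to that within $10^{-6}$. The nutrient-allocation objective (minimise total
transport $\sum_e |\nu_e|$) is not linear in general; on a minimal medium
every exchange is one-directional, $|\nu_e|$ is $\pm\nu_e$, and
`transport_objective()` builds the exactly-linear signed form (it refuses
sign-free exchanges, for which `minimize_total_transport()` uses
split-variable auxiliaries $t_e \ge |\nu_e|$).

## Expression-constrained transitions (GX-FBA)

To predict flux rearrangement across an environment or carbon-source shift,
`run_gxfba()` combines four ingredients: the pre-shift reference flux
$\nu^1$ (a minimum-total-flux refined optimum — a reproducible stand-in for
an interior-point centred solution); post-shift FVA envelopes with the
biomass floor at zero, giving each reaction's mean feasible flux $\bar\nu_i$
and the mean capacity $\bar\nu^{\mathrm{all}}$ of active reactions (envelope
width $> 10^{-9}$); a set $T$ of reactions with usable expression; and the
objective

$$Z = \sum_{i \in T} \log_2\!\big(C_i^{\mathrm{mRNA}}\big)\,
      \frac{\nu_i}{\bar\nu_i},$$

maximised under the post-shift constraints. Mapping genes to reactions uses
the GPR rules: changes below $\pm 0.5$ log$_2$ (50%) are ignored; among a
reaction's remaining genes the maximal-magnitude value is used when all
share a sign, and mixed up/down regulation excludes the reaction from $T$.
Where $\nu^1_i = 0$ the denominator falls back to $\bar\nu^{\mathrm{all}}$;
envelopes spanning zero use $|\bar\nu_i|$; denominators below $10^{-9}$ drop
the reaction from $Z$ with a warning. Upregulated reactions thus pull flux
proportionally to their fold change, downregulated ones push it toward their
envelope minimum.

## Electron bookkeeping and balance checking

The Roels degree of reduction quantifies available electrons per carbon
mole: $\kappa = (4C + H - 2O - 3N + 6S + 5P - \text{charge})/C$. It makes
boundary flows comparable across compounds — acetate carries $\kappa = 4$,
succinate 3.5, $\alpha$-ketoglutarate 3.2, CO$_2$ 0, and a biomass of
composition CH$_{1.93}$O$_{0.54}$N$_{0.22}$ carries 4.19. On a fully
balanced model, any steady-state flux vector moves zero net electrons across
the boundary (`boundary_electron_balance()`), which is both a model
diagnostic and a readable statement of what an electron sink like H$_2$
evolution costs.

`check_overall_equation()` verifies lumped conversion equations element by
element. Its `balanced` verdict deliberately covers elements only: published
lumped equations write free protons without their counter-ions, so charge
often cannot balance even when every element does; the charge residual is
reported alongside and can be opted into the verdict. The default tolerance
of 0.02 absolute suits equations printed with two-decimal coefficients;
model reactions are checked at $10^{-6}$. Species without formulas
(photons, generic energy tokens) are skipped inside a reaction; a reaction
with no formula-bearing participant is `unchecked`, never silently passed.

## The toy phototroph

`make_toy(P, A)` builds a fixed 12-internal-reaction network that reproduces
the *structure* of anaerobic photoheterotrophic metabolism in a form where
every optimum is hand-checkable: light-harvesting converts photons to ATP
(decoupled from carbon), acetate activation yields fixed carbon and a
2-electron carrier 1:1, two CO$_2$-fixation routes differ only in ATP cost
(3 vs 2, mirroring the expense gap between the Calvin–Benson–Bassham cycle
and the reductive TCA route), an ATP-consuming nitrogenase-like reaction
evolves H$_2$, and a reduced byproduct ($\kappa = 4$) can be exported. All
coefficients are small integers; every internal reaction is element- and
electron-balanced under the fixture formulas, so the boundary electron
balance closes exactly.

The defaults $P = 50$, $A = 10$ put the network in the carbon-limited
regime with closed-form optima: maximum growth
$\mu^* = \min(A/10,\, 2P/33) = 1$, maximum H$_2$ yield $2A = 20$ with zero
growth, minimum transport $36.5$ at $\mu^* = 1$, and a two-objective front
$\mathrm{H_2} = 20 - 11\mu$. Below $P = 16.5$ growth is light-limited and
rises strictly with the photon cap — the qualitative light-limitation
behaviour of the organism the network emulates. What the toy does *not*
emulate: a realistic biomass composition, photon physics, maintenance ATP,
proton economy, or genome-scale degeneracy; a test passing on the toy
demonstrates the algorithms, not the biology of any particular organism.
One structural consequence worth knowing: acetate activation produces
carbon and electrons 1:1 while biosynthesis consumes them 10:1, so at the
growth optimum the surplus electrons *must* leave through the nitrogenase
sink — the growth archetype exports H$_2$ by stoichiometric necessity, and
the H$_2$/growth trade-off is read from the strict monotonicity of the
front rather than from "zero H$_2$ at maximum growth".

`paper_scenarios()` encodes the standard photoheterotrophic condition
ladder (measured acetate uptake 1.96, CO$_2$ export pin 0.23, CBB knockout,
fitted light cap 36.6, H$_2$ archetype, blocked byproduct export, closed
proton uptake, nitrogen-starved PHB production) against *roles* resolved by
a per-model name map, so the same configs drive the toy and any genome-scale
SBML model whose identifiers are supplied.

## Numerical choices

- **LP core.** No LP solver package is available in the package's dependency
  footprint, so paretoflux carries a dense bounded-variable two-phase primal
  simplex: inequality rows get slacks, phase 1 drives artificials out, the
  basis system is re-solved from scratch each iteration (stability over
  speed), Dantzig pricing switches to Bland's rule after $10(n+m)$
  iterations to break cycling. This is deliberately sized for fixture-scale
  and mid-size models; genome-scale MOFA (tens of thousands of LPs over
  thousands of reactions) wants a sparse industrial solver and is out of
  this implementation's comfortable range.
- **Finite bounds.** "Unlimited" bounds are $10^6$ mmol gDW$^{-1}$ h$^{-1}$.
  Every LP is therefore bounded, and a phase-1 failure always means
  infeasible — the infeasible/unbounded ambiguity is designed out.
- **Tolerances.** Pivot tolerance $10^{-9}$; phase-1 feasibility $10^{-6}$;
  zero-flux threshold $10^{-9}$; objective pinned within a relative
  $10^{-9}$ band during parsimonious refinement; dominance and duplicate
  tolerance $10^{-6}$ normalised units.
- **Determinism.** No randomness anywhere in the solver path; repeated runs
  are bit-comparable, and the refinement makes reported flux vectors
  well-defined despite alternate optima.

## Problem sizes used in validation

The shipped validation runs are sized to stay hand-checkable: MOFA at
spacing 10 with 2 objectives (11 LPs) and spacing 5 with 3 objectives
(21 LPs) on the toy; the $n = 8$, $m = 10$ lattice (19448 points) is
validated combinatorially against the closed form rather than solved
point-by-point. Dominance filtering is cross-checked against a quadratic
brute-force oracle on 500 random vectors; FBA optima against closed forms
and an explicitly constructed dual LP; the two-objective front pointwise
against an $\varepsilon$-constraint sweep.

## Known limitations

- The SBML layer covers what constraint-based models need (fbc bounds,
  objectives, gene associations, formulas/charges, Level-2 note and
  kinetic-law conventions); it is not a general SBML toolkit.
- Thermodynamic loop elimination is not implemented; fluxes may contain
  internal cycles that the parsimonious refinement suppresses but does not
  forbid.
- GX-FBA implements the published four-step procedure; variants that also
  impose expression-derived flux *bounds* are out of scope.
- pKa-resolved proton speciation is out of scope; balance checking treats
  protons as written.
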