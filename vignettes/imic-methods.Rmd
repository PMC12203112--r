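---
title: "Transcriptome-constrained community metabolic modeling with imicr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-constrained community metabolic modeling with imicr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imicr)
```

## The problem

A microbial community at (quasi-)steady state can be described by one
stoichiometric matrix in which every member occupies its own compartment and
all members share an extracellular space. Flux balance analysis on such a
model predicts *a* community optimum, but without organism-specific data it
cannot say which member grows how fast. Metatranscriptomes are the most
widely available organism-resolved functional data, and this package
integrates them: per-gene expression becomes per-reaction capacity, and a
single linear program predicts individual growth rates and the metabolite
traffic that couples the members.

## Model and assumptions

**Community assembly.** Member models are merged with namespaced
intracellular species and reactions; extracellular species with the same
identifier become one shared row (we assume identifiers are already
harmonized across members, as modern reconstruction pipelines produce; no
chemical-formula reconciliation is attempted). Community-level exchange
reactions are deduplicated to one per species. The growth medium enters only
through exchange bounds — either from the SBML or via `apply_medium()`; the
package never gap-fills. For the LP convention `0 ≤ v`, every reversible
reaction is split into forward and reverse columns (`to_irreversible()`);
both columns inherit the reaction's GPR rule and share one pair of
relaxation variables, since they describe the same enzyme.

**Expression scoring.** For a reaction with GPR rule g̃ the correction factor
f(g̃) is evaluated recursively: a gene leaf is its TPM, an AND node is the
minimum of its children, an OR node is the sum. Genes present in a GPR but
absent from the expression table count as zero rather than missing at
random: metatranscriptomes are sparse, and the relaxation mechanism below
exists precisely to rescue reactions silenced this way — imputing them would
erase the method's signal. Factors are scaled by M, the maximum f(g̃) over
all members *within the sample*; the maximum is community-wide (so members
are comparable) but sample-specific (constraints are built per time point).
TPM is used on the linear scale.

**The program.** With scaled factors s = f/M ∈ [0, 1],

$$\max \sum_j \mu_j - \lambda \sum_{i,j}\left(\beta^+_{ij} + \beta^-_{ij}\right)$$

subject to steady state S·v = 0, the expression-scaled bounds
0 ≤ v ≤ vmax·(s + β⁺ − β⁻) for GPR-bearing reactions, the plain bounds
0 ≤ v ≤ vmax everywhere, the factor box 0 ≤ s + β⁺ − β⁻ ≤ 1, and
0 ≤ β⁺, β⁻ ≤ 1000. μ_j is the biomass flux of member j. The loosening β⁺ can
re-open a silenced reaction at price λ; the tightening β⁻ is provably
redundant at the optimum (it only shrinks the feasible set while costing
λ > 0) and the test suite asserts this, but it is kept in the program — and
can be disabled via `imic_config(use_beta_minus = FALSE)` — because it is
part of the stated constraint system.

## Choosing the balancing factor

The value function z*(λ) is convex, piecewise linear and non-increasing, as
is standard for a parametric LP penalty; so are Σμ(λ) and Σβ(λ). Two
selectors are provided over the grid `0.1, 0.5, 1, 2, …, 50`:

* **Sensitivity analysis** (`select_lambda_sensitivity()`): both axes of the
  (λ, z*) curve are min–max normalized and the grid point with the largest
  discrete second difference — the transition point where relaxation stops
  paying for growth — is selected; ties break toward the smaller λ, and a
  flat curve falls back to the smallest grid value with a warning. The
  detector is a plain curvature maximum; it is deliberately simple and lives
  behind one internal function so alternative knee detectors can be swapped
  in.
* **Cross-validation** (`select_lambda_cv()`): when relative abundances are
  available, samples are partitioned into k seeded folds; for each fold and
  each grid λ the mean Spearman correlation between predicted μ and abundance
  is evaluated **on the held-out samples**, the fold's best λ (ties toward
  smaller) is recorded, and the mean of the per-fold bests is returned. The
  per-sample correlation involves no fitting, so the training split carries
  no information; scoring on the held-out samples is the conservative reading
  of the procedure and is the documented choice here.

## Degenerate optima and the reported solution

At a transition point the optimal face is typically not a single vertex —
that is what makes it a transition point. z* is always unique, but μ and β
are not. The package therefore reports a deterministic representative: after
the optimum is found, a second LP stage fixes the objective (within a
relative 10⁻⁹ window) and minimizes the total relaxation Σ(β⁺+β⁻). This
least-relaxed point keeps the expression signal visible exactly at the
selected λ and makes results solver-stable; it can be disabled with
`imic_config(refine = FALSE)`. Claims about the *precision* of growth rates
are never made from the point solution but from `growth_variability()`,
which maximizes and minimizes each μ_j under the full constraint set plus
z* − ε ≤ Σμ − λΣβ ≤ z* with relative ε = 10⁻⁶ (an exact equality is
numerically brittle) and reports (μ_max − μ_min)/μ_max, defined as 0 when
μ_max = 0.

## Metabolite interactions and key reactions

The flux sum Φ_m = ½ Σ_i |S_mi| v_i is the turnover of metabolite m
(production = consumption at steady state); in the irreversible model it is
linear, so `min_flux_sum()` minimizes it by LP over the near-optimal set
(Σμ − λΣβ ≥ z* − ε, same ε convention). A metabolite with Φ_min > 10⁻⁵
mmol/gDW/h is *essential*: the community cannot reach its optimum without
turning it over. Candidates are either the extracellular species of import
reactions shared by all members (`candidates = "common_imports"`) or all
extracellular species; across samples each metabolite is classified
time-independent (essential everywhere), time-dependent (sometimes) or never
essential. `key_reactions()` correlates the net flux of common reactions
with member abundances (Spearman, across members), corrects p-values per
sample by Benjamini–Hochberg (`stats::p.adjust`), and flags reactions with
ρ > 0.7 and adjusted p < 0.05 in more than a configurable fraction of
samples (default: strict majority). Panels with fewer than four members are
skipped — the exact permutation null for n = 3 cannot reach p < 0.05.
`knockout_scan()` zeroes all columns of a reaction community-wide, re-solves
at the same λ, and never mutates the input model, so the baseline is
identical between knockouts.

## Numerical choices

* **LP kernel.** The package carries its own dense two-phase primal simplex
  (`R/simplex.R`). Stoichiometric LPs are maximally degenerate (almost all
  right-hand sides are exactly zero), which is precisely the regime where
  textbook tableau implementations stall or crash; the kernel uses Dantzig
  pricing with an automatic switch to Bland's rule after a run of degenerate
  pivots, drives leftover artificial variables out of the basis after
  phase 1, drops redundant rows, and eliminates zero-upper-bound variables
  (knocked-out reactions) before the solve. It is validated in the test
  suite against an independently assembled formulation of the same programs
  and against closed-form optima of hand-computable toys.
* **Tolerances.** Pivot and reduced-cost tolerances are 10⁻⁹–10⁻¹⁰; feasibility
  checks in results use 10⁻⁶. Reactions with non-finite upper bounds default
  to 1000 mmol/gDW/h, the usual FBA convention and the same magnitude as the
  β box.
* **Ties.** λ-selection ties break toward the smaller λ (the weaker penalty
  claim); ratio-test ties in the simplex break toward the smallest basis
  index.
* **Degenerate inputs.** All-zero expression is a fatal error ("expression
  data provide no constraints"); a metabolite with no incident reactions has
  flux sum 0 with a warning; constant flux or abundance vectors are skipped
  per sample in the correlation analysis with a note.

## What the synthetic fixtures emulate — and what they do not

`make_toy_community()` builds the study conditions used throughout the tests
and the acceptance script: `n` members, each a linear pathway (substrate
import → `pathway_depth` conversions → biomass) with one unique gene per
reaction; member j secretes a byproduct (yield 0.5 per unit of pathway flux)
that member j+1 must import (0.1 per unit of biomass), and member 1
analogously imports an externally supplied cofactor, so every member has the
same number of GPR reactions and symmetric relaxation economics. Designed
activities scale each member's gene expression
(`TPM ∝ activity × position weight × lognormal noise`, then a sparsity
fraction of entries is zeroed and the sample renormalized to 10⁶).

The defaults were fixed by analysis of the program's piecewise-linear
economics, not by tuning: GPR reactions share vmax = 40 and each member's
equal-flux chain has four GPR reactions, so the lift-everything regime ends
exactly at λ = vmax/4 = 10 — a grid point. The curvature detector therefore
selects λ = 10 deterministically, and at that λ the least-relaxed optimum
reproduces each member's activity ranking (the binding level is the member's
largest scaled factor, which is proportional to its activity). Substrate and
cofactor supplies (1000) are deliberately non-binding so that growth is
limited by expression, not by the medium; position weights 0.85^k keep
within-member factors distinct; activity defaults 1:n keep adjacent ratios
above the noise scale. Test problem sizes (n = 4 members, depth 3, ≤ ~45
reaction columns; ten replicate seeds) were chosen so every oracle remains
enumerable and the whole suite solves a few thousand LPs comfortably.

What passing these tests does **not** show: fixtures are linear pathways
with single-gene GPRs at toy scale, while real communities have
genome-scale, highly branched networks with thousands of alternative optima;
real metatranscriptomes have taxon-abundance-driven coverage, overdispersion
far beyond lognormal noise, ambiguous read assignment between members, and
compositional artifacts; and real member models carry reconstruction and
gap-filling errors upstream of anything this package controls. The fixtures
validate the machinery — GPR scoring, the LP and its limits, λ selection,
flux-sum logic — not the biology of any particular community.

## Known limitations

* Growth rates are fluxes of biomass reactions under a community-summed
  objective; without abundance data the absolute scale is model-determined,
  and only rankings/correlations should be interpreted.
* At a transition-point λ the optimal face is large; the reported point is
  the least-relaxed representative, and `growth_variability()` should always
  accompany growth-rate claims (the fixture's lowest-activity member shows
  exactly this: a wide range on the degenerate face).
* The dense simplex targets models up to a few hundred columns. Genome-scale
  communities (10⁴⁺ columns) need a sparse industrial solver behind the same
  `lp_solve()` interface.
* The SBML layer covers the constraint-based subset (fbc bounds, gene
  associations) only.
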