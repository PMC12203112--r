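# imicr

Constraint-based prediction of **individual growth rates and metabolite
interactions in microbial communities from metatranscriptomic data**, for
microbiome and systems-biology researchers who have genome-scale metabolic
models (GEMs) of the community members and per-sample gene expression, but
not necessarily abundance measurements.

## The method

Member GEMs are assembled into one compartmentalized community model: each
member keeps a private namespace while all members share a common
extracellular space, giving a unified stoichiometric matrix **S**. Gene
expression θ (TPM) is mapped to a per-reaction correction factor f(g̃)
through the reaction's gene–protein–reaction (GPR) rule — AND is the minimum
of its children (an enzyme complex is limited by its scarcest subunit), OR is
the sum (isoenzymes add) — and scaled by M, the community-wide maximum of
f(g̃) in the sample. Because metatranscriptomes are sparse, a hard E-flux-style
bound `v ≤ vmax · f/M` would silence essential reactions; each GPR-bearing
reaction therefore gets relaxation variables β⁺, β⁻ that can loosen or
tighten its bound at a price. Growth and relaxation are balanced by a single
factor λ in one linear program:

```
max  Σ_j μ_j − λ Σ_{i,j} (β⁺_ij + β⁻_ij)
s.t. S·v = 0
     0 ≤ v_ij ≤ vmax_ij · (f_ij/M + β⁺_ij − β⁻_ij)   for reactions with GPR
     0 ≤ v_ij ≤ vmax_ij
     0 ≤ f_ij/M + β⁺_ij − β⁻_ij ≤ 1
     0 ≤ β⁺, β⁻ ≤ 1000
```

μ_j is the flux through member j's biomass reaction. λ is chosen
automatically: by the transition (inflection) point of the objective's
sensitivity curve over the grid `0.1, 0.5, 1, 2, …, 50`, or by k-fold
cross-validation against relative abundances when those are available.
Downstream analyses reuse the same constraint set: growth-rate variability at
the fixed optimum, minimum flux-sum quantification of exchanged metabolites
(essential when Φ_min > 10⁻⁵), key-reaction identification by Spearman
correlation of fluxes with abundances (Benjamini–Hochberg corrected), and
community-wide reaction knockouts.

## Worked example

The package ships a deterministic synthetic-community generator whose ground
truth is known by construction: four cross-feeding members with designed
activities 1:2:3:4 driving their gene expression (20 % of gene entries
zeroed, lognormal noise).

```r
library(imicr)

fx   <- make_toy_community(fixture_spec(n_members = 4, pathway_depth = 3, seed = 1))
expr <- make_expression(fx)                       # sample_id, member_id, gene_id, tpm
cf   <- correction_factors(fx$model, expr)        # GPR scoring + community scaling

scan <- select_lambda_sensitivity(fx$model, cf)   # grid scan, curvature detector
#> <lambda_scan> method = sensitivity, selected lambda = 10

fit <- solve_imic(fx$model, cf, scan$selected)
#> <imic_fit> sample s1, lambda = 10, z* = 69.1261
#>   member    mu
#> 1 m1      9.44
#> 2 m2     17.9
#> 3 m3     35.1
#> 4 m4     40
```

The predicted growth rates recover the designed 1 < 2 < 3 < 4 activity
ranking exactly (Spearman ρ = 1) even though five gene entries were zeroed —
the relaxation variables rescue silenced reactions at the selected λ.
`glance(fit)` summarizes the solve (`sum_mu = 102.4`, `sum_beta = 3.33`);
`autoplot(scan)` draws the sensitivity curve with the selected transition
point.

```r
growth_variability(fx$model, cf, scan$selected, fit$z)
#>   member mu_min mu_max    rel_var
#> 1 m1       9.43   40   0.764        # m1 sits on a degenerate face at the kink
#> 2 m2      17.9    17.9 0.000171
#> 3 m3      35.1    35.1 0.0000876
#> 4 m4      40.0    40   0.00000691

essential_imports(fx$model, cf, scan$selected, candidates = "extracellular")
#>   sample_id metabolite phi_min essential class
#> 1 s1        sub_e       102.   TRUE      time_independent
#> 2 s1        byp4_e       20.0  TRUE      time_independent
#> 3 s1        byp3_e       17.5  TRUE      time_independent
#> ...                                      # cross-fed byproducts are essential;
#>                                          # the unused medium component is not
```

Real data enter through the same interfaces: `read_member_sbml()` for SBML
L3/fbc member models, `build_community()` + `to_irreversible()`,
`read_expression()` for the TSV expression dialect (TPM, or counts +
lengths with `from_counts = TRUE`). A command-line wrapper with subcommands
`build`, `run`, `lambda-scan`, `variability`, `fluxsum`, `key-reactions`,
`knockout` and `make-fixture` is installed under `exec/imic`.

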