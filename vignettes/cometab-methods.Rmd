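---
title: "Modelling host–microbiome formate co-metabolism with cometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling host–microbiome formate co-metabolism with cometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometab)
```

## The modelling problem

Urinary formate is produced both by host pathways (serine catabolism,
formaldehyde detoxification, tryptophan degradation, methionine salvage) and
by fermentation in the gut microbiome, which can also feed the host pathways
with precursors such as L-serine or L-tryptophan. `cometab` implements a
constraint-based (COBRA-style) pipeline that separates these contributions:
it builds a personalised community metabolic model from a sample's species
relative abundances, attaches it to the intestinal lumen of a multi-organ
host model, and decomposes the gain in maximum urine secretion of a target
metabolite into direct microbial secretion plus a co-metabolism residual.

All computations reduce to linear programming over a stoichiometric model:
flux vectors $v$ satisfying the steady-state mass balance $S v = 0$, flux
bounds $lb \le v \le ub$, and any extra linear constraint rows. Flux balance
analysis (FBA) maximises or minimises one flux; flux variability analysis
(FVA) reports each flux's attainable range. The steady-state assumption is
the framework's central simplification: communities and host are treated as
being at metabolic steady state on the timescale of a day, and every result
is a *capacity* (an optimum over the feasible set), not a prediction of the
realised flux.

## Community models

Pan-species models are the set-union of the strain reconstructions of one
species: union of reactions and metabolites, widest bound interval for
reactions shared between strains (a union-of-capabilities semantics). The
strain biomass reactions are merged into one `biomassPan` reaction whose
stoichiometry is the union of all strain biomass terms with the mean
coefficient over the strains carrying each term. The merge rule is a
declared convention of this package: the mean preserves the scale of the
biomass reaction while covering every strain's requirements; any fixed
convex weighting would serve, and the capability-monotonicity test in the
suite (every strain's feasible exchange fluxes are contained in the pan
model's FVA intervals) pins the property that actually matters downstream.

A sample's community model namespaces each species' reactions
(`species__reaction`), rewires all extracellular metabolites to a shared
microbial lumen compartment `[luM]`, and removes the per-species exchange
and biomass-demand reactions: metabolites move between species only through
the lumen, and species biomass is consumed only by the community biomass
reaction

$$\text{communityBiomass}: \sum_i a_i \cdot \text{biomass}_i \rightarrow \varnothing,$$

where $a_i$ is species $i$'s relative abundance. Mass balance then forces
each species' biomass flux to $a_i$ times the community growth rate.
Coupling constraints tie every other species reaction $j$ of species $i$ to
its biomass flux $b_i$:

$$-c\, b_i \le v_j \le c\, b_i, \qquad c = 400,$$

so a species that does not grow carries no flux at all. The coupling factor
400 is the standing convention of abundance-based community modelling; it is
a config key (`cometab_config()$coupling_factor`), not a hard-coded number.
Coupling rows are emitted as plain linear inequality rows appended to the LP
rather than via auxiliary variables — fewer columns, identical polytope.

Two further conventions required a decision because the upstream literature
does not fix them numerically:

* **Abundance cutoff** (`abundance_cutoff = 1e-4`): species below this
  relative abundance after coverage filtering are dropped and the rest
  renormalised. Coverage (the fraction of reads retained when restricting to
  model-covered species) is reported per sample.
* **Community growth bounds** (`growth_lb = 0.4`, `growth_ub = 1.0` per
  day): a positive lower bound makes the coupling constraints bind — with
  growth free to be zero, coupling would never constrain anything and every
  community optimum would be degenerate.

Diet is a metabolite → flux table in mmol/person/day applied as uptake
bounds: the diet-facing exchange of a diet metabolite gets lower bound
$-\text{scale} \times \text{flux}$, every other diet-facing exchange has its
uptake closed (lower bound raised to 0), and secretion bounds are never
touched. Uptake is negative exchange flux, secretion positive, everywhere in
the package. Net secretion capacity of a community is the FVA maximum of the
metabolite's fecal exchange under a fixed diet, computed on the single fecal
exchange reaction (so simultaneous diet uptake cannot inflate it); negative
maxima (forced net uptake) are floored at zero and flagged.

## Host integration and the decomposition

The toy host carries a diet compartment `[d]`, a large-intestinal lumen
`[luLI]`, organ cytosols, and a urine compartment `[u]` with exchanges
`EX_<met>[u]`. Attaching a community links each shared lumen metabolite by a
reversible transport `LUt_<met>` between `[luM]` and `[luLI]` (positive =
delivery to the host) and removes the community's own diet interface, so
attached microbes feed exclusively from the host lumen; coupling rows are
preserved. For one metabolite the pipeline reports:

* `germfree_max` — FBA maximum of `EX_<met>[u]` on the host alone;
* `personalised_max` — the same maximum with the community attached;
* `microbial_secretion_max` — the maximal `[luM] -> [luLI]` delivery flux of
  the metabolite itself, reported as a non-negative magnitude in the
  microbiome→host direction (this direction convention is ours; the
  equivalent formulation that minimises the oppositely-signed exchange gives
  the same magnitude);
* `delta = personalised_max − germfree_max` and
  `cometabolism_residual = delta − microbial_secretion_max`.

A positive residual is the share of the microbial benefit that direct
secretion cannot explain — host conversion of microbially derived
precursors. The identities hold exactly by construction; the shipped fixture
(`make_cometab_fixture()`) is built so the four quantities are analytically
2, 9, 3 and 4. Community growth is left free within its bounds during the
personalised maximisation rather than fixed at a reference value: fixing it
would make the host optimum depend on an arbitrary growth choice, whereas
the free optimum is a true capacity.

## Screens

The knockout screen deletes candidate reactions one at a time (bounds closed
to zero) and recomputes the urine maximum; the reduction fraction
$(\text{baseline} - \text{ko})/\text{baseline}$ is clamped into $[0,1]$ and
reactions above the 10% flag threshold are flagged. The supplementation
screen adds each candidate metabolite to the diet at 300 mmol/person/day
(max rule — supplementation never lowers an intake) and classifies
candidates that raise the optimum by more than $10^{-6}$.

The minimal-set search is greedy forward selection (largest marginal
reduction, ties broken by candidate order) followed by a backward pass that
drops members whose removal keeps the goal satisfied; the result is minimal
with respect to the greedy set, not globally. For candidate lists up to 15
an exhaustive enumeration over subsets in order of increasing cardinality is
available and is used as the oracle in the test suite. Greedy is exact on
the branch fixtures because independent capacity-bounded branches make the
reduction function modular; on networks with shared intermediates it is a
heuristic, which is why the exhaustive option exists.

## Cohort statistics

* `screen_metabolites()`: zeros are treated as missing (an absent NMR signal
  does not imply an absent metabolite), metabolites with under 50% non-zero
  measurements are excluded, the log concentration is regressed on group +
  age + sex + BMI, the group factor is tested by a joint Wald chi-square
  with heteroscedasticity-robust covariance, the case-vs-control contrast is
  reported separately, and Benjamini–Hochberg q-values are computed across
  metabolites. We implement the "global test" as the joint Wald test of all
  group dummies plus the separate case contrast; HC3 is the default robust
  flavour (config key) because it is the conservative small-sample choice.
* `fractional_regression()`: relative abundances in $[0,1]$ are modelled by
  a logit-link quasi-binomial GLM — the econometric fractional regression —
  fitted by IRLS with sandwich robust standard errors; species present in
  fewer than half the samples are excluded; non-convergence is flagged, not
  raised. Beta regression was deliberately not used: it cannot accommodate
  exact zeros and is not what "fractional regression" names.
* `log_ratio_test()`: per sample, the log ratio of summed counts of an
  increased-species set over a decreased-species set, with a pseudocount of
  0.5 guarding zero sums (config key), then Welch's t-test between groups.
  The degenerate zero-variance case (e.g. identical sets) returns p = 1
  rather than an error.
* `compare_fluxes()`: OLS of one flux per sample on group, APOE4 and sex
  with robust standard errors; constant covariate columns are dropped with a
  warning rather than producing a rank-deficient fit.

## The LP engine and numerical choices

All linear programming is done by a bounded-variable primal simplex written
for this package: phase I with one artificial variable per row, phase II on
the user objective, and Bland's rule (smallest eligible index for both the
entering and the leaving variable) throughout. Bland's rule makes the solver
immune to cycling under degeneracy — community models are highly degenerate
— and, with fixed input ordering, bit-reproducible run to run, which the
pipeline's determinism contract requires. The cost is speed, which is
irrelevant at the problem sizes this package targets (hundreds of columns).

Numerical conventions, centralised in `cometab_config()`:

* feasibility tolerance `tol_feas = 1e-6` (mass-balance residual, bound and
  constraint satisfaction), determinism tolerance `tol_det = 1e-9`;
* bounds absent from a model file default to ±1000;
* unbounded maximisations report `status = "unbounded"` instead of silently
  clamping at the default bound, so modelling errors surface;
* infeasibility is detected in phase I (artificial objective above
  tolerance) before any per-reaction FVA solve;
* basic variable values are recomputed from the basis factorisation every 50
  iterations to cap drift.

In the test suite the solver is checked against an independent oracle:
optima are enumerated over the basic solutions (vertices) of the bounded
polytope, and FVA envelopes are required to contain random feasible points
drawn as convex combinations of the enumerated vertices.

## What the synthetic data does and does not emulate

The generators produce every input the pipeline consumes: toy microbes with
distinct fermentation traits (formate secretors, precursor secretors, a
fructose-requiring species so growth checks can fail by design), strain
variants that lose pathways and narrow bounds (so pan-model union is
non-trivial), a multi-organ host carrying the four formate branches with
capacity-bounded endpoint reactions (`PSP_L`, `SFGTH`, `TRPO2`, `DKMPPD`)
plus a basal source, minimal/full diets, and Dirichlet-multinomial
case/control cohorts with planted compositional shifts (3-fold by default,
24 cases / 24 controls, log-normal read depths with median ≈ 2.5 million)
and planted log-normal metabolome shifts (−0.5 on the log scale in cases,
40/group, 20% zeros). The metabolome noise level (`sdlog = 0.45`) was
calibrated by power analysis so that the planted shift is detectable after
FDR correction in at least 80% of simulation seeds at the default group
sizes — the calibration accounts for the zeros reducing the analysed sample
size.

Because every branch capacity is a spec parameter, analytic values exist for
the host optima (sum of enabled capacities plus basal) and for every screen
result, which is what the tests assert. What the toys deliberately do not
emulate: realistic genome-scale network size and redundancy, growth-rate
trade-offs between species competing for many substrates, compositional
correlation structure beyond the Dirichlet, batch effects, or measurement
error in the abundances themselves. Passing tests therefore demonstrate
that the *machinery* (assembly, coupling, decomposition, screens,
statistics) is correct, not that the toy capacities transfer to real
reconstructions.

## Problem sizes

The default pipeline (`run_pipeline()`) uses 6 species × 2 strains, a
48-sample cohort for the statistics, and runs 4 samples through the
LP-heavy host integration; a full run takes well under a minute on one CPU.
The statistical calibration in the acceptance tests uses 200 simulation
seeds per procedure. These sizes are the package's chosen demonstration
scale: every stage scales to more species or samples linearly in the number
of LP solves.

## Known limitations

* The simplex is dense; genome-scale models (tens of thousands of columns)
  would need a sparse factorised implementation or an external solver.
* The minimal-set search is exact only where the reduction function is
  modular (independent branches) or the candidate list is small enough for
  enumeration.
* Secretion capacities are optima, not realised fluxes; comparing them
  between groups tests differences in *capability*, a weaker claim than a
  difference in actual secretion.
* The host model is sex-labelled but otherwise not personalised
  (no genomic, physiological or anthropometric contextualisation); the sex
  parameter changes model content only, never the code path.
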