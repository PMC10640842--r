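---
title: "Methods: manipulating plant-flower-visitor network structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: manipulating plant-flower-visitor network structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`bloomnet`. The package analyses a randomized-block field experiment in
which identical seven-species plant communities received one of four
agrochemical treatments — control water (C), low-dose fertilizer (F),
low-dose herbicide (H) or both (HF) — and asks whether those treatments
moved the structure of the plot-level plant–flower-visitor networks, in
particular their connectance.

## Networks and structural metrics

Each plot contributes a weighted bipartite matrix **A** (plants x insects,
entries = season-aggregated visit counts). Season aggregation is by
summation over sampling events: it is the only operator under which the
matrix total equals the number of specimens collected. Species that
received or made no visits in a plot are excluded from the matrix, but the
count of plant species that *bloomed* is retained in the metadata because
the connectance denominator needs it.

**Connectance** is experiment-wide: `L / (plants_bloomed x I_total)`, where
`L` is the number of realized links and `I_total` the insect richness
observed across the whole experiment (a parameter; use 92 when analysing
the original study's data, or the simulated pool's realized richness for
synthetic runs). Two readings of the numerator are possible because
"unweighted degree" is elsewhere defined as `L/S`; we use the raw link
count `L`, the only reading that keeps connectance a realized *proportion*
of the `plants_bloomed x I_total` potential links, bounded by 1. Degree
denominators, by contrast, use `S` = plants + insects present in the
realized network.

**NODF** follows the canonical paired-overlap formulation: for each ordered
pair of rows (and of columns) with strictly greater fill first, the pair
contributes `100 x shared presences / fill of the sparser`; equal-fill
pairs contribute 0; NODF is the mean over all row and column pairs. The
implementation is cross-checked in the test suite against a literal
double-loop oracle and against `vegan::nestednodf`.

**NODFc** corrects NODF for matrix size and fill so that networks of
different dimensions are comparable:

```
NODFc = (NODF / max_NODF) / (C_fill * ln(sqrt(m * n)))
```

with `C_fill = L/(m n)` the within-matrix fill. The source analysis only
states that the correction is "relative to network size"; the constants
here follow the normalization of the `maxnodf` line of work that the
analysis cites (fill times log geometric-mean dimension). `max_NODF` is the
largest NODF over binary matrices with the same dimensions and link count
and no empty row or column. For `m*n <= 12` cells it is found by exhaustive
enumeration; otherwise by a deterministic greedy construction (first
row/column cover, then frontier cells chosen by immediate NODF gain)
refined with best-improvement single-link relocations, capped at 10,000
evaluated moves. The search equals exhaustive enumeration on every feasible
case up to 3x4 (tested), and results are cached by `(m, n, L)` because null
ensembles revisit the same few link counts repeatedly. Two degenerate cases
are defined explicitly: a single row or column has no NODF, and when
`max_NODF = 0` (e.g. a completely filled matrix, where every fill ties)
NODFc is reported missing rather than 0/0.

**Modularity** is Barber's weighted bipartite
`Q = (1/F) sum_ij (A_ij - k_i d_j / F) delta(g_i, h_j)`, maximized by
weighted label propagation (columns adopt the best row module and vice
versa, with a fresh singleton module when every candidate has negative
gain) alternating with greedy module agglomeration, in the spirit of the
DIRTLPAwb+ algorithm. The optimizer is stochastic, so reproducibility is by
policy: every run takes an explicit seed, 20 restarts by default (the first
from singleton initialization, the rest random), ties broken toward fewer
modules. Null-model scoring uses 5 restarts per draw by default — a
deliberate budget choice; the null matrices are small and the z-scores
average over hundreds of draws.

## Null models and z-scores

Null matrices preserve both margins exactly and are drawn with Patefield's
algorithm (`stats::r2dtable`, the same method as the original analysis).
Note this samples tables with probability proportional to their
multinomial multiplicity (the Fisher-exact conditional distribution), not
uniformly over distinct tables; the test suite checks the sampler against
this exact distribution by enumerating all feasible 2x2 tables with their
weights. Each of the `n_null` draws (500 by default, per the study) is
scored with the same six metrics as the observed network, and
`z = (obs - mean_null)/sd_null`. Metrics that the margins fix completely —
total abundance, and with it weighted degree, since margins also fix the
matrix dimensions — have `sd_null = 0` and are flagged degenerate and
reported missing rather than infinite. A treatment is said to depart from
the null expectation for a metric when the mean ± sd of its networks'
z-scores excludes 0. Treatment-level contrasts on z-scores reuse the same
mixed-model machinery with treatment as the only fixed effect (the
original methods mention no display covariate at this stage, so none is
included).

## Diversity

Per-treatment visitor abundances pooled across plots feed Hill numbers
`qD = (sum p_i^q)^(1/(1-q))` for q = 0, 1 (limit form), 2; sample coverage
uses the singleton/doubleton estimator
`1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`; rarefaction interpolates
richness with the exact hypergeometric formula and q = 1, 2 with the
standard estimators built from expected frequency counts. Extrapolation
beyond the observed sample size and bootstrap confidence bands are out of
scope: the quantitative claim the pipeline reproduces is the coverage
itself (>96% per treatment in the original data, and similar in synthetic
runs). Exhaustive subsample enumeration at small n is the test oracle.

## Treatment inference

Although the original analysis calls its models GLMMs, the reported t
statistics and log-transformed responses imply Gaussian linear mixed
models on (possibly log) responses; that is what `fit_lmm` fits, by REML,
with treatment (reference C) and log floral display as fixed effects and
block as a random intercept. The treatment x display interaction is fitted
first and dropped unless some interaction contrast has p < 0.05 (the
pruning threshold is our concretization of "excluded where not
significant"). t and p values use lmerTest's Satterthwaite approximation.
Marginal and conditional R² follow the variance-components formulation
(`R2m = s2_f / (s2_f + s2_a + s2_e)`, `s2_f = var(X beta)`). Singular
random-effect fits are flagged, not hidden; a constant response yields
zero effects and R²m = 0 by convention.

When the interaction is retained, the treatment coefficients are contrasts
at log display = 0 — faithful to how such tables are usually printed, but
not centered quantities. Simulation-recovery checks therefore fit the
correctly-specified model without the interaction term.

The per-species tests for the commonest visitors use Kruskal–Wallis with
tie correction and Dunn-type pairwise contrasts against the control
(mean rank differences on the joint ranking, normal-approximation p).
"Dunn-type" is a documented choice; the original analysis names only the
omnibus test and a Bonferroni correction, whose family size we take to be
the number of species tested (10).

## The synthetic experiment generator

The generator exists so that every stage of the pipeline can run, and be
tested, without the field data. It emulates the study *design* exactly —
8 blocks (site-years) x 4 treatments x 1 plot, 7 planted species, ~90
insect species — and the *statistical structure* of the findings
directionally; it is not a mechanistic visitation model. Per plot:

- floral display ~ lognormal(meanlog 8 + block shift, sdlog 0.5), in mm²,
  independent of treatment (matching the finding of no treatment effect
  on display); block shifts sd 0.4.
- each insect species `s` with activity `a_s ~ lognormal(0, 1.5)` is
  *included* with probability from base rate `1 - exp(-0.10 a_s)`, odds
  multiplied by relative display and, under fertilizer, by `rho_F = 1.85`;
- included species draw negative-binomial visits (size 1.5) with mean
  `1.15 * sqrt(a_s) * (display/ref) * exp(-0.33 [herbicide] + block
  effect)`, allocated across bloomed plants by attractiveness weights;
  zero draws leave the species unrecorded, so realized richness emerges
  from inclusion and counts jointly.

The square-root activity exponent decouples commonness from per-plot
superabundance: with a linear coupling the heavy-tailed activity
distribution produced totals an order of magnitude above the ~60
visits/plot scale of the field data. The defaults were calibrated once,
before any acceptance measurement, to that scale: ~70 visits and ~12
realized species per control plot (~2,200 specimens per experiment), a
fertilizer richness gain averaging +4.6 species (the study's printed
contrast is +4.68) and a herbicide log-abundance decrement of
0.33 (the study's −0.33). Because fertilizer acts on *inclusion odds* and
the added species are drawn from the rare tail, richness rises much more
than abundance — the study's stated mechanism for the connectance
increase. Year effects are folded into block effects, as in the original
design (8 site-years as blocks).

What the generator does **not** emulate: within-season phenology,
taxonomic structure of the insect pool, plant-species-specific visitor
guilds, density dependence, or any treatment effect on display. Passing
recovery tests on these simulations therefore shows the pipeline's
estimators are unbiased and appropriately powered under the study design —
not that the field system obeys this generative model.

The dose arithmetic treats a month as 4 weekly applications of 10 L over a
4 m² plot; these are the only values consistent with the printed seasonal
totals (e.g. glyphosate (0.7+0.3+0.1) mg/L x 40 L / 4 m² = 0.011 g/m²,
110 g/ha, 7.6% of a 1,440 g/ha field rate).

## Problem sizes and runtimes

Defaults follow the study (500 null draws per network, 20 modularity
restarts). Full-size runs are deliberate: a 32-plot experiment with
500-draw ensembles takes ~25 minutes on one CPU, dominated by max-NODF
searches and null modularity. The bundled acceptance script instead uses
100-draw ensembles for its single end-to-end run (null means and sds are
stable well before 100 draws for these small matrices) and 50 replicate
experiments for the recovery rates; the test suite exercises the 500-draw
reproducibility contract on a small fixture network. The `analysis/`
scripts run the full-size configuration.

## Known limitations

- The max-NODF hill climb is a local search; beyond exhaustively verified
  sizes it is a lower bound on the true maximum (so NODFc can be slightly
  overestimated on large, dense matrices).
- Satterthwaite p-values differ in the third decimal from other df
  approximations; published p-values from other software reproduce to
  about ±0.01.
- The Patefield null conditions on both margins; probabilistic nulls that
  relax margins (Bascompte-style cell probabilities) are out of scope.
- With all margins fixed, weighted degree is constant across the ensemble
  and has no z-score; the published per-network tables list one — any
  such value must come from a different null family, and we report the
  metric as degenerate instead of imitating it.
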