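---
title: "Forming and characterizing sufficiently similar mixtures with mixrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forming and characterizing sufficiently similar mixtures with mixrank}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(mixrank)
```

## The problem

Environmental samples — here, air impacted by creosote contamination and
wildfire smoke — contain dozens of co-occurring chemicals such as
polycyclic aromatic hydrocarbons (PAHs). Testing the whole mixture is
rarely feasible, so a *sufficiently similar* surrogate is built from a
prioritized subset of components, mixed at their environmental
proportions. mixrank implements that workflow end to end: prioritization
of components from heterogeneous toxicity metrics, recipe formulation,
and hazard characterization of the resulting mixtures in continuous
(in vitro) and quantal (zebrafish developmental) assays.

## Prioritization model

Each chemical $i$ carries an air concentration $c_i$ (ng/m³) and a sparse
set of toxicity metrics. Three selection schemes are provided:

* **Abundance** — rank by $c_i$, select the top $k$.
* **Toxicity** — for each metric $m$ in {abundance, RPF, CPV, IUR, RfC,
  OSF, RfD, zebrafish BMC}, rank chemicals from most to least hazardous
  (rank 1 = most hazardous), then average each chemical's available
  ranks:
  $$\bar r_i = \frac{\sum_{m \in M_i} r_{im}}{|M_i|},$$
  where $M_i$ is the set of metrics observed for chemical $i$. The $k$
  smallest $\bar r_i$ are selected.
* **Weighted toxicity** — each metric in {IARC, TEF, IUR, RfC, OSF, RfD,
  BMC} is first multiplied by the chemical's proportion of total
  concentration $p_i = c_i / \sum_j c_j$, then ranked and averaged as
  above.

Metric *direction* matters: for reference doses/concentrations (RfD,
RfC) and benchmark concentrations (BMC) a **smaller** value is more
hazardous; for cancer potencies (OSF, IUR, CPV), potency scalers (RPF,
TEF) and abundance a **larger** value is; IARC classes are ordinal
(1 > 2A > 2B > 3 > NC).

### Design choices that were genuinely open

* **Ties** receive the mean of the ranks they span. This keeps the rank
  sum of every metric column invariant ($\sum r = m(m+1)/2$), which is
  what makes brute-force cross-checks exact, and is the convention of
  every standard rank test.
* **Missing metrics**: the denominator of the average is the count of
  *available* ranks per chemical. A fixed denominator would
  systematically favor data-poor chemicals (missing ranks would act as
  zeros); `denominator = "fixed"` is available for sensitivity analysis.
* **Weighting inverse metrics**: a literal product $p_i \times
  \mathrm{RfD}_i$ would make abundant chemicals look *safer*, because
  small RfD means high hazard. The default therefore inverts such
  metrics to a potency ($1/\mathrm{RfD}$) before multiplying, so
  abundance monotonically increases the hazard score of every weighted
  metric. The literal product is available behind `literal = TRUE` and
  warns.
* **IARC in the weighted scheme** is mapped to an ordinal integer score
  (group 1 → 5 down to NC → 1) before multiplication; only the ordering
  of the categories is defined, so any monotone recoding is equally
  defensible and the integer one is the simplest.
* **The abundance rank term** is included in the toxicity scheme by
  default (it is one of the eight aggregated metrics), with
  `include_abundance = FALSE` to drop it for a purely effect-based
  ranking.
* **Boundary ties** at the $k$-th place are an error by default — a
  silent arbitrary choice of mixture components would be worse than a
  loud one. `tie_policy = "include_all"` or `"cas"` (deterministic CAS
  string order) override.

```{r}
ct <- simulate_chemical_table(seed = 1)
tt <- simulate_toxicity_table(ct, seed = 1)
res <- prioritize(ct, tt, scheme = "weighted_toxicity", k = 7,
                  tie_policy = "cas")
res
```

## Recipe formulation

A recipe rescales the selected chemicals' concentrations to the most
abundant selected component, so the surrogate preserves environmental
ratios. Coverage is the share of the source mixture's total detected
concentration captured by the recipe; the abundance scheme's top 7 is
constructed to cover 97% in the emulated data:

```{r}
sel <- prioritize(ct, scheme = "abundance", k = 7, tie_policy = "cas")
rec <- formulate(sel$selected, ct, "abundance mix")
coverage_percent(rec)
```

Components lacking an analytical standard are removed via `exclude=`;
the remaining proportions are re-scaled to the new maximum and the
exclusion is reported, never silent. Recipes are dimensionless —
conversion to stock concentrations is presentation, not model.

## Continuous dose–response

Plate signals are normalized per plate to percent of the vehicle-control
mean (`percent_control()`); LDH absorbances are background-subtracted
(`ldh_signal()`, negative values passed through with a warning, since
clipping would bias the control mean) and the mitochondrial
membrane-potential readout is the 525/590 nm emission ratio
(`mmp_ratio()`).

`fit_dose_response()` fits six candidate curves by least squares on
log-concentration — log-logistic with 2, 3, 4 and 5 parameters and the
two 4-parameter Weibull forms — and keeps the converged fit with the
lowest AIC. These six are the standard continuous suite for in vitro
concentration–response work. Numerical choices:

* The location parameter is fitted as $\log e$, keeping the optimizer
  unconstrained while guaranteeing a positive EC50.
* Starts are deterministic self-starting heuristics: asymptotes from the
  per-concentration mean extremes, $e$ from the concentration nearest
  half-response, slope tried at ±1 (both fitted, better SSE kept). Same
  data, same selected model, always.
* EC50 is the *absolute* half-effect concentration (midpoint of the
  asymptotes), which for the asymmetric and Weibull forms differs from
  the location parameter; its standard error comes from the delta method
  on the fitted covariance. An SE, not a CI, is reported by default.
* Vehicle wells anchor normalization only; they are excluded from the
  regression rather than placed at a pseudo-dose.
* Degenerate inputs (constant response) leave every candidate
  unconverged and are reported as non-bioactive rather than forced to a
  curve.

The lowest effect level (LEL) is the smallest tested concentration whose
response differs from vehicle control by one-way ANOVA with Dunnett's
many-to-one comparisons (multivariate-t adjustment, pooled variance;
`pool_variance = FALSE` switches to Welch t-tests with Bonferroni).
Replicates are pooled across plates.

```{r}
d <- percent_control(simulate_dose_response(ec50 = 50, hill = 2,
                                            cv = 0.1, seed = 2))
fit_dose_response(d)
lel(d)
```

## Binary developmental endpoints

Zebrafish embryos are scored for 13 binary endpoints (mortality and
spontaneous movement at 24 hpf; mortality plus ten morphological defects
at 120 hpf; registry in `zf_endpoint_registry()`). Statistics:

* **Incidence** composites: *any effect* is the per-animal union over
  all endpoints; *mortality* is death at either time point. Dead animals
  are excluded from single-endpoint morphology denominators (a defect
  cannot be scored on a dead embryo); `exclude_dead = FALSE` reverts.
* **Significance thresholds**: the smallest affected count whose exact
  binomial upper tail under the control background rate falls below
  α = 0.01. A clean control (0 background) is add-one smoothed to
  $1/(n+2)$ so a single event is never automatically significant. The
  group size $n$ is always taken from the data, never from a design
  constant.
* **Fisher's exact test** against control with Bonferroni correction
  over the 13-endpoint family (two-sided by default). Concentration-level
  multiplicity is handled by the threshold procedure, not corrected
  twice.
* **Outlier screen**: control incidences more than 3 single-pass SDs
  from the mean. **QC gate**: negative controls ≤ 20% combined
  mortality/morbidity and a positive-control EC50 inside 19.3 ± 4 µM.
* **Quantal PODs**: incidence (%) versus concentration is fitted with
  the same six-model suite; mortality PODs are reported as LC50.

```{r}
z <- simulate_binary_endpoints(ec50 = 40, hill = 4, seed = 3)
quantal_pod(z, "mortality")
```

## Ranking diagnostics

`rank_correlation()` correlates per-metric rank columns with Pearson's
$r$ over complete observations — pairwise by default (each cell uses its
own complete pairs, which maximizes usable data under the heavy
missingness typical of PAH toxicity values; `use = "listwise"` is the
stricter alternative). Cells with fewer than 3 complete pairs are
undefined rather than errors, p-values are plain two-sided t-transforms
with no multiplicity adjustment, and the significance mask at α = 0.05
marks which cells a correlation plot would cross out.

```{r}
res_tox <- prioritize(ct, tt, scheme = "toxicity", k = 7,
                      tie_policy = "cas")
rank_correlation(res_tox$rank_matrix)
```

## What the generators emulate — and what they do not

The simulators reproduce the *statistical structure* of the study
inputs, not any published numbers:

* `simulate_chemical_table()`: 30 detected chemicals, log-normal
  concentrations, rescaled so the top 7 hold exactly 97% of total mass.
  Exact (deterministic) dominance makes composition tests sharp; a real
  sample only approximately satisfies it.
* `simulate_toxicity_table()`: per-metric-group availability placed to
  hit the counts {RfD|RfC: 10, OSF|IUR: 6, IARC: 18, RPF: 7, TEF: all,
  BMC: 14} out of 30 exactly; RfC/RfD and OSF/CPV coupled through a
  shared latent hazard (they are derived from common studies in
  practice), IARC cut from the same latent. Real missingness is not
  random — it tracks how well-studied a chemical is — and real values
  have heavier tails than the log-uniform ranges used here.
* `simulate_dose_response()`: multiplicative Gaussian noise at a stated
  CV around a 4-parameter log-logistic curve, 7 concentrations, 6
  replicates; real plates add edge effects and plate-to-plate drift that
  the generator omits (and the per-plate normalization is designed to
  absorb).
* `simulate_binary_endpoints()`: per-animal Bernoulli draws,
  36 animals/concentration over 3 plates, 12 controls/plate, optional
  within-animal endpoint correlation through a single latent Gaussian
  severity factor. Real endpoints are correlated in more structured
  ways (e.g. edemas co-occur); the single-factor model is the simplest
  structure that can break naive independence assumptions in tests.

Passing tests on these inputs therefore demonstrate the *procedures* —
exact rank arithmetic, curve-fit recovery at realistic noise, type-I
control of the LEL and Fisher/Bonferroni machinery — not agreement with
any particular field sample.

Every generator is a pure function of its arguments and seed, and a
global seed fans out to per-component child seeds via fixed offsets
(`child_seed()`), so adding a generator never perturbs existing streams.

## Problem sizes used in the shipped checks

The package's own verification uses desk-scale simulation sizes chosen
to give stable Monte-Carlo estimates while staying quick to run: 200
replicates for continuous EC50 recovery (median relative error < 10% at
10% CV), 200 for quantal LC50 recovery (< 15%), and 1000 nulls each for
the LEL false-positive rate (compared against the binomial 99% interval
around α = 0.05) and the 13-endpoint family-wise error rate (< 0.01
plus Monte-Carlo margin).

## Known limitations

* No plate-effect mixed models; ANOVA/Dunnett pools replicates across
  plates.
* No benchmark-dose (BMD/BMDL) machinery; PODs are EC50/LC50 and LEL.
* No uncertainty propagation on the toxicity metric values themselves.
* The correlation output is a matrix, not a publication heatmap.
* QSAR-predicted values are consumed as table cells with provenance
  `qsar_predicted`; no prediction is performed.
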