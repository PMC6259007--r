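---
title: "Estimating and comparing ordinal symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing ordinal symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

`symptomnet` analyses questionnaires in which each of *p* symptoms is rated
on an ordinal 0–4 severity scale (here the 17 DSM-IV PTSD items of the
Davidson Trauma Scale, labelled B1–B5, C1–C2, D1, D5–D7, E1–E6). The core
object is a Gaussian graphical model (GGM): a multivariate-normal model in
which the zeros of the precision matrix \(K = \Sigma^{-1}\) encode
conditional independence. Its edges are partial correlations,

\[ w_{ij} = -\,\frac{k_{ij}}{\sqrt{k_{ii}\,k_{jj}}}, \]

the association between two symptoms after controlling for all others.
Estimation proceeds in three steps:

1. an item correlation matrix (Pearson on the raw scores by default;
   Spearman and two-step maximum-likelihood polychoric correlations are
   available for ordinal fidelity), repaired to positive semi-definiteness
   by eigenvalue clipping when needed;
2. the graphical lasso — maximization of
   \(\log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \ne j} |k_{ij}|\)
   (diagonal unpenalized) by block coordinate descent, solved along a
   log-spaced path of 100 penalties from \(\lambda_{\max} = \max_{i<j}|S_{ij}|\)
   down to \(0.01\,\lambda_{\max}\);
3. model selection by the extended Bayesian information criterion,
   \(\mathrm{EBIC} = -2\,\ell + E\log n + 4\,E\,\gamma \log p\), with
   \(\gamma = 0.5\); the selected precision matrix is converted to partial
   correlations and entries below \(10^{-10}\) are clamped to exact zeros so
   that "edge present" is well defined.

An unregularized estimator (direct pseudo-inverse of the correlation
matrix) is provided for sensitivity analyses.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | EBIC sparsity preference; 0 reduces to BIC |
| `n_lambda`, `lambda_min_ratio` | 100, 0.01 | resolution and depth of the penalty path |
| `method` | `"pearson"` | item correlation; `"polychoric"` treats scores as thresholded latent normals |
| `B` | 2000 | bootstrap replicates (edge accuracy and case dropping) |
| `drop_proportions` | 0.05–0.75 | case-dropping grid for the CS-coefficient |
| `iterations` | 1000 | permutations of the network comparison test |

The defaults for \(\gamma\) and the path follow the conventions of the
regularized-partial-correlation literature; all are exposed.

## Centrality, stability, comparison, predictability

**Centrality.** Strength \(\sum_j |w_{ij}|\), expected influence
\(\sum_j w_{ij}\) (one-step, signed — the preferred index when negative
edges exist), and closeness/betweenness on the distance graph with edge
lengths \(1/|w_{ij}|\) (zero edges are non-edges; unreachable nodes give
closeness 0; betweenness shares fractional credit among tied shortest
paths). Z-scores use the sample SD; a constant index standardizes to zero.

**Robustness.** `bootstrap_edges()` resamples cases with replacement and
re-runs the full pipeline, giving per-edge quantile confidence intervals
and per-replicate centralities for `difference_test()` (which, following
the conventions of this literature, applies no multiple-testing
correction). `case_dropping()` subsamples without replacement at each drop
proportion and correlates subsample centralities with the full-sample ones;
the CS-coefficient is the largest drop proportion at which the empirical
5th percentile of those correlations stays at or above 0.7 ("correlation
\(\ge 0.7\) with 95% probability"), scanning proportions in increasing order
and stopping at the first failure. A CS-coefficient of at least 0.5 is the
usual bar for interpreting centrality orderings.

**Comparison.** `nct()` is a permutation test: cases are pooled and
repeatedly reassigned to groups of the original sizes, the estimator is
re-run on every permuted split, and p-values are
\((1 + \#\{\text{perm} \ge \text{obs}\})/(1 + \text{iterations})\) — the
add-one convention avoids zero p-values. Statistics: structure invariance
\(M = \max_{i<j} |w^A_{ij} - w^B_{ij}|\); global strength invariance
\(S = \big|\sum |w^A_{ij}| - \sum |w^B_{ij}|\big|\); global expected
influence (the same difference on signed sums, so positive and negative
edges may cancel); per-edge and per-node expected-influence differences
(Holm adjustment optional, off by default). `balance_groups()` subsamples
the larger group to the smaller group's size, the standard remedy for the
test's instability under very unequal groups.

**Predictability.** Nodewise \(R^2\): each item regressed on the other
items by least squares, in sample. For data from a GGM the population value
is \(R^2_i = 1 - 1/(\Sigma_{ii} K_{ii})\), which the tests verify at large
n. A linear Gaussian nodewise model is used on the common severity scale —
a deliberate, deterministic simplification relative to mixed-graphical-model
predictability; in-sample (not cross-validated) \(R^2\) matches the
"shared variance" framing, and a ridge fallback handles singular designs.

**Summary-table tests.** Welch t from printed group summaries (with
Satterthwaite degrees of freedom; the sign is second-group-minus-first, so
callers choose the panel order), Yates-corrected \(\chi^2\) for 2×2 counts
(the corrected statistic is what the emulated study's printed values match),
and a two-sided variance-ratio F.

## The synthetic generator

No raw data from the emulated veteran study are available, so every stage
is exercised on synthetic data with known structure. The generator is a
Gaussian copula: a target sparse partial-correlation matrix is turned into
a precision matrix (\(k_{ii} = 1\), \(k_{ij} = -\rho_{ij}\), uniform
diagonal inflation to positive definiteness — which shrinks all targets by
one recorded factor), latent multivariate-normal cases are drawn, and each
latent value is cut at four per-item thresholds into a 0–4 score. Thresholds
are placed at the normal quantiles of Binomial(4, \(\mu/4\)) cumulative
probabilities, so each item reproduces a target mean \(\mu\) exactly in
population. Child seeds for the groups of a two-group design are derived
from one master seed, so adding a group never shifts existing draws.

`preset_ptsd17()` encodes four study-like scenarios (clinical,
subthreshold, low/high combat exposure; default sizes 912/138/639/273).
All share a 76-edge base structure whose strongest pairs are
hypervigilance–startle (E3:E4), the avoidance pair (C1:C2), loss of
interest–detachment (D5:D6) and detachment–restricted affect (D6:D7), with
trauma-related amnesia (D1) nearly isolated; thresholds reproduce the
published per-group item means. Overall connectivity is calibrated at
construction: a single multiplier is solved so the implied population mean
latent shared variance is 0.55, which after ordinal attenuation puts
observed mean predictability near 0.49–0.51 at n = 912 — inside the
mid-40s-to-mid-50s percent band reported for such networks. The preset is
structurally, not numerically, faithful: the study's true edge magnitudes
are unpublished.

What the generator does *not* emulate: item-level measurement error beyond
discretization, skew beyond what the threshold placement induces,
missingness, demographic covariate structure, or any temporal dynamics.
Passing tests therefore demonstrate correctness of the machinery under a
plausible data-generating process, not reproduction of the original
dataset's numbers.

```{r example, eval = FALSE}
spec <- preset_ptsd17("clinical", n = 912, seed = 1)
d    <- sample_ordinal(spec)
fit  <- estimate_network(d)
head(centrality_table(fit$network, standardize = TRUE))
mean_predictability(d)
```

## Numerical choices and known limitations

* **Graphical-lasso convergence** is declared when the largest change in the
  working covariance falls below `tol` (default \(10^{-6}\)) times the mean
  absolute off-diagonal of S; warm starts are used along the path. At
  \(\lambda = 0\) the solution agrees with direct inversion to \(10^{-6}\)
  (tested against both inversion and an independent ADMM solver).
* **The edge count along the path is only near-monotone.** As \(\lambda\)
  decreases the active set occasionally shrinks by an edge or two before
  growing again (on dense ordinal data the cumulative sag can reach ~5% of
  the maximum edge count). This is a property of the exact solution path,
  not a convergence artifact; the tests assert near-monotonicity rather
  than strict monotonicity.
* **EBIC specificity depends on signal strength.** With strong generators
  the selected penalty is small and many tiny spurious edges survive
  (specificity can drop towards 0.5 at n = 5000 even though every true edge
  is found); with moderate structures specificity stays around 0.85. This
  is the documented false-positive behavior of EBIC-glasso at large n.
  Structure-recovery checks on the ordinal presets therefore use polychoric
  input correlations, which consistently estimate the latent structure that
  Pearson correlations of discretized scores distort.
* **Closeness** uses the standard inverse-total-distance form
  \((p-1)/\sum_j d_{ij}\); the looser "average distance" phrasing sometimes
  seen in this literature describes the same ordering.
* **CES = 25** is assigned to the *high* combat group (the published table
  labels columns "<25" and ">25", leaving the boundary unstated); ≥25 keeps
  the group boundary aligned with the opening of the Moderate-heavy band.
* **Degenerate inputs**: zero-variance items are hard errors naming the
  item; cases with missing items are dropped and counted; permutation or
  bootstrap replicates whose estimation fails (e.g. a constant item after
  resampling) are resampled, counted, and capped.
* **Problem sizes in the shipped tests** were chosen to make every check a
  few seconds to a few minutes: calibration of the comparison test uses 200
  null simulations (n = 300 per group, 200 permutations, unregularized
  estimator) and 100 power simulations at connectivity scale 0.3; stability
  uses B = 500 case-dropping replicates at n = 10,000 on an 8-node
  generator; recovery uses one n = 5,000 draw of the 17-item preset. The
  study-scale defaults (B = 2000, 1000 permutations, regularized estimator
  throughout) remain the function defaults.
* The permutation test re-runs the full estimation pipeline — including
  EBIC selection when the regularized estimator is chosen — on every
  permuted split; this is costly but faithful to the described procedure.
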