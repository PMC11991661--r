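---
title: "Ensemble SDMs and stacked richness: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDMs and stacked richness: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmstack)
```

## The analysis in one paragraph

`sdmstack` implements consensus (ensemble) species distribution modeling with
downstream multi-species stacking. For each species, presence records and
randomly placed pseudo-absences are split repeatedly into training and test
sets; several presence/absence learners are fit per split; each learner x
replicate run is scored on its held-out rows by the true skill statistic
(TSS), Cohen's Kappa, and the rank-based AUC; runs passing a TSS cutoff are
averaged with weights proportional to their TSS into a single continuous
habitat-suitability surface per climate scenario. Suitability is binarized at
an occurrence-anchored threshold, binary ranges are stacked into a
species-richness map with four richness categories, category areas are
accumulated with exact spherical cell areas, and range shift between
scenarios is summarized by the great-circle distance and initial bearing
between range centroids.

## Evaluation metrics

With confusion counts (tp, fp, fn, tn) at a threshold (a row is predicted
present when its score is at or above the threshold — the closed lower bound
is used everywhere):

* sensitivity = tp / (tp + fn), specificity = tn / (tn + fp)
* TSS = sensitivity + specificity − 1, in [−1, 1]
* Kappa = (p_o − p_e) / (1 − p_e), with p_o the observed agreement and p_e
  the chance agreement implied by the marginals
* AUC is the Mann–Whitney statistic — the probability that a random presence
  outscores a random absence, ties counting one half — and needs no
  threshold.

TSS and Kappa are reported at the threshold that maximizes TSS over the
candidate set (midpoints between consecutive distinct scores plus the
extremes, lowest maximizer on ties). The reporting threshold is optimized on
the evaluation split; this is the common convention in ensemble SDM
platforms, and the package states it explicitly because the choice is often
left implicit in applied papers.

## Learners and the ensemble

Six learners sit behind one contract — fit a labeled point table, score new
rows in [0, 1]:

* **SRE** (surface range envelope) is implemented natively: the envelope is
  the per-variable empirical [Q(q), Q(1−q)] interval of the *presence*
  values (linear-interpolation quantiles), and a cell is suitable iff every
  variable falls inside its interval. The default q = 0.025 gives the
  conventional 95% climate envelope. SRE emits hard 0/1 scores and is
  monotone in q: widening the tails can only shrink the envelope.
* **RF** (random forest, 300 trees), **GAM** (thin-plate smooths, REML),
  **MAXENT**-like (lasso-regularized logistic regression on linear +
  quadratic features — a maximum-entropy analogue), **FDA** (linear
  discriminant posterior), and **ANN** (single hidden layer, size 5, weight
  decay 0.01) are standard implementations wrapped behind the contract;
  their internals are deliberately not part of this package's contribution.
  A constant-score learner is registered for contract tests only.

Runs with held-out TSS ≥ 0.7 enter the ensemble; weights are raw TSS values
normalized to sum to one. Weighting uses raw TSS (not TSS minus the cutoff,
not rank decay) as the most literal reading of "TSS values as weights".
Ensembling is flat over learner × replicate runs rather than first averaging
replicates within a learner; the flat pool uses all information and avoids
giving a one-good-replicate learner the same voice as a uniformly good one.
Ensemble skill is reported held-out: within each replicate, the members of
that replicate are reweighted and averaged on that replicate's test rows,
and the resulting TSS/Kappa/AUC are averaged over replicates.

Variable importance is permutation-based per member run: 1 − r between
reference predictions and predictions after permuting one variable's column,
averaged over 3 seeded shuffles (negative correlations truncate to the [0,1]
importance range). Member importances are combined by the ensemble weights
and normalized to percentages summing to 100 per species.

## Pre-modeling steps

Occurrence cleaning retains one record per species per 0.1° × 0.1° cell
(thinning grid anchored at (0°, 0°), not at the raster origin — simple and
data-independent) and drops species with fewer than 25 records; exactly 25
is kept. Within a thinning cell the first record after a deterministic sort
on (longitude, latitude, source) is retained, making the result independent
of input order.

Variable selection computes Pearson correlations over all valid study-extent
cells (no species conditioning) and iteratively removes one member of the
most correlated remaining pair while any |r| exceeds 0.8. When no external
importance ranking is supplied, the member dropped is the one with the
larger mean absolute correlation to all other variables — deterministic,
data-driven, and available before any model is fit; an explicit ranking can
be passed to force a particular retained set. Cell-based correlation (rather
than correlation over occurrence extractions) is the default because the
screening step precedes and is independent of any species.

Pseudo-absences are drawn once per species — 1000 cells uniformly without
replacement from valid cells not containing a presence of that species —
and shared across all learners and replicates. Train/test splits (75/25, 10
replicates) are stratified by presence/absence label to avoid degenerate
test sets at small sample sizes.

## Post-processing

The binarization threshold for a species is the mean ensemble suitability at
its occurrence cells minus one sample (n−1) standard deviation, clamped to
[0, 1], computed on the current-period map and reused for future scenarios
(which have no occurrence truth of their own). Richness categories partition
integer counts as 1–3 / 4–6 / 7–9 / ≥10 (the conventional labels "1–3",
"3–6", "6–9", ">9" overlap at the boundaries; integer counts force the
decided partition, which matches every printed label). Suitability tiers use
Fisher–Jenks natural breaks (exact O(k n²) dynamic program; above 4000
values a seeded subsample is used) computed on the current map and reused
across scenarios; tier intervals are half-open with a value exactly at a
break joining the upper class.

Areas use the exact spherical formula R² · Δλ · (sin φ_top − sin φ_bottom)
with R = 6371.0088 km (IUGG mean radius — a fixed, documented sphere rather
than an ellipsoid, reproducible and well within the 2-significant-figure
precision of typical reported areas). Cells count fully; there is no
partial-cell clipping at mask edges.

Centroids are unweighted means of suitable-cell centers of the *predicted*
binary range — predictions are the only quantity available in future
scenarios, and unweighted planar means match the usual "latitude and
longitude means" wording; study regions here span few tens of degrees, so
planar means are adequate. Migration is the haversine distance and initial
great-circle bearing between centroids, with 8-wind labels from 45°-wide
sectors.

## The synthetic benchmark: what it emulates, and what it does not

The virtual-species generator makes every stage testable without downloads:

* **Climate layers**: seven layers named Bio2–Bio19, each a deterministic
  linear gradient in longitude/latitude plus box-smoothed seeded Gaussian
  noise (moving-average half-width 3 cells, noise share 0.45 of the layer
  standard deviation), rescaled to magnitudes loosely matching the real
  variables. Bio2 and Bio3 are constructed as a correlated pair (r = 0.9,
  exact in-sample by orthogonalized mixing) so the selection step always has
  a pair to break; Bio4 rises eastward and Bio19 northward.
* **Species**: five virtual species with two-variable Gaussian niches on
  Bio4 and Bio19 — suitability exp(−½ Σ ((x−μ)/σ)²) — with optima spread
  across the extent and tolerances σ(Bio4) = 20, σ(Bio19) = 12. These are
  moderately specialized niches: narrow enough that occupancy is
  climatically crisp and a competent learner can recover it, which is what
  makes skill and importance recovery informative. A sixth species gets 20
  records so the minimum-record filter always has something to drop.
* **Sampling**: 200 presences per species, distinct cells drawn without
  replacement proportional to true suitability, placed at cell centers so
  grid thinning is the identity on synthetic data and tests isolate
  downstream stages.
* **Futures**: additive shifts on Bio4 (+60 for the low-emission scenario,
  +160 for the high-emission one). Because Bio4 increases eastward, raising
  its value moves each species' climatic optimum westward — a known
  direction and ordering (the stronger scenario moves it farther) that
  migration recovery is tested against.

The benchmark deliberately does *not* emulate: sampling bias along roads or
rivers, dispersal limitation, non-Gaussian or interacting niche responses,
GCM-style spatially heterogeneous climate change, or coastline masks.
Passing the recovery tests therefore shows the pipeline is correct and
well-calibrated on clean data; it does not certify performance on biased or
dispersal-limited real-world records.

Default problem sizes (150 × 150 grid at 0.1°, 5 species × 200 presences,
1000 pseudo-absences, 6 learners × 10 replicates) were chosen as the
smallest configuration at which sampling noise stops dominating the recovery
checks; the plumbing tests use smaller grids and fewer replicates.

## Numerical choices and degenerate inputs

* Cell assignment: point (x, y) belongs to column floor((x − west)/res) and
  row floor((north − y)/res); west and north edges inclusive. One rule used
  by thinning, extraction, and occurrence placement.
* Internal nodata is NA; the sentinel −9999 appears only on disk (ESRI
  ASCII grids, the package's raster interchange format). A nodata cell in
  any layer invalidates the cell in all layers (joint mask).
* A constant layer has undefined correlations: entries are flagged NA, not
  NaN-propagated, and the layer is reported.
* Constant scores make threshold optimization degenerate (single candidate,
  flagged), AUC 0.5, and permutation importance 0 with a degeneracy flag.
* A species whose ensemble output has fewer than four distinct suitability
  values (possible with a single envelope member) skips tier
  classification with a message rather than failing the run.
* A species with no run at or above the TSS cutoff aborts the pipeline with
  an explicit no-ensemble error naming the species — never a silent empty
  model.
* Seeds: every random stage derives a 31-bit seed from the master seed plus
  stage and species labels, so any stage can be reproduced in isolation and
  two runs with the same configuration produce byte-identical tables.

## Known limitations

* Only geographic (WGS84) lon/lat grids; no projection support.
* Raster I/O is plain-text ASCII grid only.
* Planar centroid means distort at polar latitudes and across the
  antimeridian.
* The MAXENT and FDA analogues are standard approximations of the eponymous
  algorithms, not re-implementations; swap in any learner via the registry
  contract if fidelity to a specific implementation matters.
* The Jenks solver is exact only up to the configured size cap; above it a
  seeded subsample is classified.
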