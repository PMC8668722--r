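---
title: "Multi-realm species distribution models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-realm species distribution models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Correlative species distribution models (SDMs) relate occurrence records to
gridded environmental covariates and predict habitat suitability. For species
that straddle the land–sea boundary — breeding seabirds are the motivating
case — a single-realm SDM is structurally incomplete: a puffin colony's
viability depends at once on the land it nests on and on the sea it forages
in. `mrsdm` implements a single-model alternative to post-hoc combination of
two separate SDMs: environmental information from the other realm is engineered
into each cell's covariate row, so one model sees both realms and their
interactions.

## Data model

A `realm_grid` is a regular lon/lat grid (reference resolution 5 arc-minutes)
whose layers are tagged `terrestrial` or `marine` and carry per-cell validity
masks. A cell valid in **both** realms is a *coastal* cell; it belongs to both
realms simultaneously. All distances are great-circle distances between cell
centres on a sphere of mean radius 6,371,008.8 m (haversine). A projection-based
distance could not be reproduced — projected distance computations in this
field rarely state their projection — and the spherical kernel meets the same
goal of avoiding high-latitude distortion while being exactly reproducible.
Grids are serialised as gridded CSV with a metadata header; values are printed
with 17 significant digits so a round trip is bit-stable.

## Derived and cross-realm covariates

Four model types share one pipeline:

* **TerrOnly / MarOnly** — local covariates of the focal realm only.
* **TerrWithMar** — each terrestrial cell finds its *nearest coast cell* (the
  nearest marine-valid cell) and receives the mean and sample standard
  deviation of every marine variable over all marine cells within the species'
  **mean maximum foraging distance (MMFD)** of that coast cell (columns
  `mean_X` and `X_variation`). The buffer is centred on the coast cell, not on
  the terrestrial cell; for far-inland cells this can summarise sea that is not
  actually reachable from the nest site. That behaviour is deliberate and
  documented rather than "fixed", because it keeps the derived covariates a
  pure function of the nearest-coast map.
* **MarWithTerr** — each marine cell inherits the values of its nearest
  terrestrially valid cell (columns `nearest_Y`), using the same nearest-cell
  map as the distance-to-land layer.

Two distance layers are derived with a *coastal-zero rule*: `distance_from_land`
(marine) and `distance_from_sea` (terrestrial) are zero for any cell valid in
both realms, else the distance to the nearest valid cell of the other realm.
Landmasses are connected components of the terrestrial mask (8-neighbour by
default, since diagonally touching coastal cells form one landmass; 4-neighbour
by flag); their area uses the spherical quadrilateral formula, so
high-latitude cells weigh less, consistent with the distance kernel; isolation
is the distance to the nearest strictly larger (by km²) landmass and is missing
for the largest landmass and under exact area ties.

Numerical choices worth knowing:

* Buffer membership is centre-to-centre distance `<= mmfd_m`. The nearest coast
  cell is always a member, so buffers are never empty; a single-cell buffer has
  variation 0 (not `NA`), so single-cell coves remain modelable. Variation uses
  the n−1 (sample) denominator.
* Nearest-cell ties break to the lowest row, then the lowest column. Ties are
  detected with a 1 mm tolerance: geometrically symmetric cells are exact ties
  whose computed distances can differ by rounding, and the tolerance makes the
  deterministic tie-break robust to that.

## Backgrounds and pseudo-absences

Presences are cells; pseudo-absences are drawn uniformly without replacement
from a constrained background excluding occupied cells. Because the target
species breed on or near the coast, the terrestrial background is restricted
to cells within 20 km of the sea; the marine background to cells within the
MMFD-derived cutoff of land. The MMFD is treated as a 90th-percentile foraging
distance; the background extends to a nominal 100th percentile,
`mmfd_m * exclusion_factor`. How the 100th percentile follows from the 90th is
not derivable from first principles, so the factor is configurable with default
10/9 (linear percentile scaling); `exclusion_factor = 1` gives a plain MMFD
cutoff. Replicate pseudo-absence sets (default 5 × 10,000) are drawn
independently and may overlap each other; a balanced diagnostic set with as
many pseudo-absences as presences (prevalence 0.5) is always drawn too. A
shortfall of eligible cells is an error naming the deficit, never a silent
truncation.

## Learners, screening, validation

Covariate pairs with |Pearson r| above 0.7 (complete cases; constant columns
excluded with a warning) are *covarying*: each pair contributes the choice of
which member to keep, giving 2^k candidate variable sets for k disjoint pairs
(pairs sharing a variable are resolved jointly into maximal conflict-free
selections). Rather than dropping one member at random and running the
alternative as a second model, `mrsdm()` enumerates the candidate sets
exhaustively and keeps the set with the highest mean cross-validated TSS —
a deterministic procedure that subsumes the two-run convention.

The learner layer is a registry behind one fit/predict interface. Shipped
defaults mirror common SDM practice, since "default settings" of any given SDM
framework are not portable:

* `glm` — logistic regression, linear + quadratic terms, no interactions;
* `rf` — random forest, 500 trees;
* `ann` — single hidden layer of size ⌈√p⌉, standardised inputs, weight decay
  0.01;
* `gam` — penalised thin-plate splines (optional registration, demonstrating
  the plug-in interface).

Iterative learners attempt 100 iterations and escalate once to 1,000 on
non-convergence, recording the flag. Fits are bit-reproducible from
(data, seed): every stage seed derives from the single configuration seed.

Validation splits 70% of presences and pseudo-absences (stratified) into a
training set, evaluates on the held-out 30%, and repeats five times with
different splits. Metrics: sensitivity, specificity, TSS = sensitivity +
specificity − 1 at the TSS-maximising threshold (grid 0, 0.001, …, 1; ties to
the smallest threshold — threshold optimisation is a convention the upstream
frameworks apply silently, made explicit here), and ROC AUC via the rank
(Mann–Whitney) formulation with ties counted ½.

## Ensemble and uncertainty

Full-data models (one per learner × pseudo-absence set) enter the ensemble
only with TSS strictly above 0.6 ("substantial" skill). Gating uses the
cross-validated mean TSS of the matching learner/pseudo-absence set — gating a
full-data model on its own training TSS would be circular. If no model passes,
the fit still returns its validation table with a warning; there is simply no
ensemble to project. Member maps are min–max rescaled to [0, 1] (a common
numerical scale; rank order is preserved exactly), then combined per cell as a
TSS-weighted mean; uncertainty is the unweighted across-model variance. As a
robustness check, an ensemble built from the 70%-calibrated validation models
is compared with the full-data ensemble by Spearman rank correlation over all
projected cells.

## Permutation variable importance

For each covariate in a fitted model: shuffle that column (seeded), re-predict
with the *fitted* model, and compute Pearson's r between reference and permuted
predictions; importance is 1 − r clipped to [0, 1], averaged over 10 shuffles
with its SD. The permute-and-repredict convention (rather than refitting a new
model on shuffled data) is chosen because it anchors the scale: a variable the
model ignores yields identical predictions, r = 1, importance exactly 0.
Constant reference predictions leave importance undefined (`NA`), flagged
rather than filled.

## The synthetic world

`generate_seascape()` builds an archipelago of meandering north–south island
strips (default two strips, eight cells ≈ 40 km wide, at 60° N) with a
one-cell coastal fringe valid in both realms; every environmental variable is
a seeded Gaussian random field (white noise smoothed with a Gaussian kernel,
length scale 5 cells, standardised). The narrow-strip geometry matters: every
terrestrial cell lies inside the 20-km coastal background band, so presences
and pseudo-absences differ by *environment*, not by distance from the sea —
the situation of real coastal breeders, whose ranges and backgrounds share the
coastal strip. On a wide landmass the band constraint itself becomes the
dominant class signal, which no real seabird exhibits and which would let a
single-realm model match a multi-realm one for spurious reasons.

The standard virtual species (`simulate_multirealm_world()`) is terrestrial
with logit suitability `-6 + 3·z(terr1) + 6·z(mean_mar1)`: a sharp,
marine-dominated niche of the kind observed for short-range coastal foragers,
with MMFD 16.6 km. Effect sizes are deliberately strong: the expected ~300
presences among ~960 terrestrial cells with weaker effects put the
Bayes-optimal TSS (measured by thresholding the *true* suitability) near 0.5,
below the 0.6 ensemble gate — i.e. the study would be unanswerable by any
model. With these defaults the Bayes ceiling is ≈ 0.8–0.94, matching the
accuracy regime the gate presumes. Presence sampling is an independent
Bernoulli draw per cell with probabilities rescaled — accounting for clipping
at 1 — so the expected presence count hits the target (default 300).
Pseudo-absence counts are scaled to the world (default 300 per set, one set),
since a 60 × 60 world's background cannot support 10,000.

What the synthetic experiments show — and what they do not: they verify that
the pipeline detects a cross-realm dependence when one exists by construction
(multi-realm TSS exceeds single-realm in replicate worlds) and that
validation-based accuracy carries over to the full-data ensemble (Spearman
ρ > 0.9). They do not emulate spatial sampling bias, observation error,
autocorrelated residuals, range disequilibrium, or realistically correlated
environmental variables; passing them says the machinery is correct, not that
any real species' range will be equally predictable.

## Problem sizes

The shipped experiments use 60 × 60 worlds (≈ 5° × 5° at 5 arc-minutes),
~300 presences, 300 pseudo-absences × 1 set, three learners (GLM, RF, ANN) and
5 validation repeats, with 10 replicate worlds for the multi- vs single-realm
comparison; brute-force oracle checks run on random grids up to 40 × 40. These
sizes were chosen to exercise every code path at desk scale; all of them are
configuration, not constants.

## Known limitations

* Buffer aggregation is unweighted within the radius; no distance-decay kernel.
* Distances are through-water/through-land agnostic (no least-cost paths
  around landmasses).
* No spatially blocked cross-validation; random splits overestimate
  transferability under strong spatial autocorrelation.
* GeoTIFF ingestion is out of scope; gridded CSV is the interchange format.
* Pseudo-absence schemes beyond uniform background sampling (target-group,
  environmentally stratified) are not provided.
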