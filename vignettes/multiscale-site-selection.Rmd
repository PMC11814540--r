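---
title: "Multi-scale colony-site selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale colony-site selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Colonial waterbirds (herons are the motivating case) choose communal
nesting sites in response to the surrounding landscape, but the radius at
which the landscape matters — the *scale of effect* — is unknown a priori.
The approach implemented here compares presence sites against
pseudoabsence sites using the composition of a categorical land-use map
inside buffers of many radii, lets a random-forest classifier measure how
separable the two classes are at each radius, and reads the scale of
effect off the radius with the highest mean out-of-bag (OOB) accuracy.
Around that workflow sit four supporting analyses: constrained
pseudoabsence sampling, variable importance at the focus scales, a
deletion-based outlier screen, and landscape-diversity comparisons with an
NMDS ordination.

Because real colony coordinates and a national land-use raster cannot ship
with a package, `heronscape` is organised around a synthetic study system
with a *planted, recoverable* preference. Every claim the package makes
about itself is therefore a property claim — "the pipeline recovers a
known signal under known conditions" — not a reproduction of any field
estimate.

## The synthetic study system

`generate_landscape()` builds the land-use raster as a neutral landscape:
one spatially autocorrelated Gaussian field per class (separable Gaussian
smoothing of white noise; correlation length = `patchiness`, default
500 m), combined cell-wise by `argmax` after adding per-class shifts that
are calibrated by a damped fixed-point iteration until the realised class
proportions match `class_mix` (within a few tenths of a percentage point
in practice). Two properties motivated this design over slicing a single
field by quantiles:

* each class's spatial structure is independent of every other class's
  field, so a preference planted on one class does not leak into the
  geometry of the others; and
* classes interlock like a patch mosaic rather than forming bands that are
  adjacent in legend order.

The default `class_mix` (cropland 0.20, forest 0.25, shrub 0.05, grassland
0.20, water 0.08, barren 0.10, impervious 0.05, wetland 0.07) is a
continental-style composition: crop- and forest-dominated with minority
water, wetland and built cover.

`place_presences()` plants the ground truth. A candidate site drawn
uniformly over valid cells is accepted with probability

$$\Pr(\text{accept}) = \operatorname{logit}^{-1}\!\big(
  \operatorname{logit}(b) + s\, z \big), \qquad
  z = \frac{p - \bar p}{\operatorname{sd}(p)},$$

where $p$ is the focal-class cover proportion inside the focal radius,
standardised against a seeded probe sample of the valid region, $b$ is the
baseline acceptance rate (0.5) and $s$ is the selection `strength`.
Standardising $p$ makes `strength` a log-odds slope *per standard
deviation of focal cover*, hence comparable across landscapes and
patchiness settings; `strength = 0` reduces exactly to uniform placement.
Presences keep a minimum spacing (2 km at study scale — the desk-scale
analogue of using only well-separated colonies) and avoid both the border
band and the towns. The town exclusion matters: pseudoabsences must avoid
towns, so if presences could sit in them, impervious cover would separate
the classes at every scale and mask the planted signal. With both classes
excluded from towns, the planted water preference is the only systematic
difference.

`make_masks()` supplies the exclusion geometry: a border band (cells whose
centre is within the band of the domain edge) and towns as discs whose
cells are forced to impervious. The sighting pool is uniform over data
cells.

One calibration deserves note. The sighting-exclusion rule removes a disc
around every sighting, and the *fraction of the domain excluded* controls
the character of the remaining valid region. The study-scale defaults
(200 sightings, 1 km exclusion on a 51.2 km domain) remove roughly a
quarter to a third of the domain, which mirrors the regime of
continental-scale sighting data. If the exclusion fraction approaches one,
the surviving pockets are few and idiosyncratic, and pseudoabsences become
separable from presences through the geometry of the pockets alone — an
artifact, not habitat selection. The generator's defaults deliberately stay
in the benign regime.

## Buffers and features

`extract_buffer_areas()` uses cell-centre membership in the half-open
annulus $[\text{inner}, \text{outer})$: the area of class $k$ is the count
of class-$k$ cells whose centre falls in the annulus, times the cell area.
Cell-centre counting is the standard zonal-statistics rule on 30–100 m
grids, is exactly reproducible by a brute-force loop (the test suite holds
the implementation to *exact* equality with such an oracle), and the
half-open convention makes neighbouring rings a perfect partition of the
enclosing disc — the 1–2 km ring is literally `disc(2 km) − disc(1 km)`,
class by class. Buffers may overhang the domain; the overhang contributes
nothing and its fraction is recorded (rows whose largest buffer overhangs
more than 50% are flagged). Ring-scale models see only the ring's own
areas, not the enclosed disc.

The per-row Shannon index is $H = -\sum_k p_k \ln p_k$ over the classes
with positive area, in nats (the ecology default; the base is an
argument). $H$ ranges from 0 (single class) to $\ln 8 \approx 2.079$.

## Per-scale ensembles

`fit_scale_ensemble()` fits `n_models` random forests (study default 100;
tests and the shipped configurations use 20) of `n_trees` trees (500 in
the study design; 100 here) per buffer spec, on the eight area features of
that spec only. Two design points:

* **"30% OOB" is taken literally.** Each tree trains on a 70% row
  subsample drawn *without* replacement, so its OOB set is exactly 30% of
  the rows. A classic bootstrap leaves ~36.8% out; `sampling = "bootstrap"`
  restores that behaviour for users who want it.
* **Accuracy** is $1 -$ OOB misclassification under majority vote.
  Per-repeat accuracies give the max / mean / min summaries per scale; the
  scale of effect is the argmax of the mean, with ties broken toward the
  smaller radius and reported as ties.

Variable importance is the permutation importance (mean decrease in OOB
accuracy) of the single best repeat, clamped at zero and normalised to sum
to one; an impurity-based alternative is a config switch. Permutation
importance was chosen because the area features are compositionally
correlated, and it is measured on exactly the rows a tree did not see.
A caveat discovered while freezing the test bands: when *no* feature
carries signal, the clamped-normalised vector is close to an arbitrary
point on the simplex, so null behaviour is asserted on the raw importance
scale (all raw importances below 0.05 in pure-noise fits) rather than on
normalised shares.

Pearson correlation matrices of the features at the focus scales
accompany the importance tables; zero-variance columns yield missing (not
zero) entries.

## The deletion screen

`deletion_screen()` deletes `k` rows at random (stratified so the class
balance never shifts by more than one row), refits the ensemble with the
same model-seed stream as the undeleted baseline, and repeats this
`reps_per_k` times for each `k` in the schedule (default
`{1, 5, 10, 25, 50}` × 5 — fifty is the cap on deletions, five the number
of repetitions, and the intermediate counts keep the sweep affordable).
The replicate with the highest mean accuracy flags its deleted rows; its
margin over the baseline (`delta`) is the headline effect.

Two statistical properties of this protocol shape how its results are
read, and both are verified by simulation in the test suite:

* **The per-`k` mean accuracy is flat by construction.** Deleting rows
  uniformly at random preserves the expected fraction of problem rows, so
  the *average* screened accuracy cannot trend upward in `k`; if anything
  it drifts slightly down as the training set shrinks. `trend_test()`
  therefore regresses the per-`k` *best* accuracy on `k` by default — the
  protocol's object of interest is explicitly the best deletion group —
  and the per-`k` mean remains available as an option. Even the best
  statistic moves by only about one accuracy point across the schedule at
  the shipped sample sizes, so the trend classification has modest power;
  `delta` and the flagged-row recovery carry most of the screen's
  information.
* **`delta` is a maximum over 25 draws**, so under a clean null it sits
  above zero by selection alone. The null-safety check accordingly bounds
  the *mean* screen deviation (all cells averaged, minus baseline) by
  twice the baseline's repeat SD; the maximum-based `delta` is reserved
  for flagging, not for null calibration.

## Diversity tests and ordination

`compare_diversity()` compares presence and pseudoabsence Shannon indices
per scale: Shapiro–Wilk on each group at $\alpha = 0.05$; if both pass, a
Welch two-sample $t$ (robust to unequal variances, equal to Student's
asymptotically when variances agree); otherwise the Mann–Whitney $U$,
reported for the presence group with midpoint tie scoring
($U + U' = n_1 n_2$), exact enumeration for $n_1 + n_2 \le 12$ and the
tie- and continuity-corrected normal approximation otherwise. All tests
are two-sided; the direction field records which group is more diverse.
Note that the shipped synthetic conditions plant a *water* preference, not
a diversity preference, so the per-scale diversity tests on pipeline output
are typically non-significant; the power of the gated test itself is
demonstrated on explicit planted-shift simulations (a 0.5-nat shift at
SD 0.3, n = 100 per group, is detected at $p < 0.001$ at every scale).

`nmds_ordination()` runs 2-D non-metric multidimensional scaling
(`vegan::metaMDS`, multiple random starts) on Bray–Curtis dissimilarities
of row-normalised class proportions. Stress (monotone-regression stress-1)
is reported descriptively with the usual < 0.2 interpretability rule of
thumb; no significance test is attached, because there is no agreed null
for stress.

## Determinism and problem sizes

Every operation is a pure function of its inputs and a seed. The pipeline
derives one seed per stage by hashing the master seed with the stage name,
so adding a stage never perturbs the random streams of the others, and two
runs with the same configuration produce byte-identical output files.

The shipped configurations are sized for a desk machine: the demo
(`default_config()`) uses a 256 × 256 grid with 60 presences, and the
study configuration (`study_config()`) a 512 × 512 grid (51.2 km at 100 m
cells) with 100 presences against 100 of 500 pseudoabsence candidates,
ensembles of 20 forests × 100 trees across all 13 radii. At those sizes a
full pipeline run takes well under a minute, and the multi-seed recovery
experiments in the test suite a few minutes. Scaling `n_models` to the
study design's 100 forests of 500 trees changes runtimes, not interfaces.

## What passing tests do and do not show

The synthetic generator emulates: a multi-class autocorrelated mosaic,
exclusion geometry (borders, towns, sighting discs), a scale- and
class-specific selection signal, and balanced presence/pseudoabsence
designs. It does not emulate: real map legends and their thematic error,
geodesy and projection distortion (all geometry is planar metres),
spatially biased sighting effort, non-stationary landscapes, colony-size
effects, or temporal turnover. Consequently, green tests certify that the
pipeline's machinery is correct and that a known signal of realistic
strength is recoverable — not that any particular field system behaves
like the synthetic one.

## Known limitations

* Raster I/O is a plain-text grid plus CSV/GeoJSON points; there is no
  GeoTIFF reader or writer, and no coordinate reference system handling.
* The pseudoabsence sampler is exact but rejection-based; pathological
  configurations (valid region a sliver) end with an informative
  infeasibility error rather than a result.
* The deletion screen's trend statistic has intrinsically low power at
  desk-scale sample sizes (see above); treat `classification` as
  descriptive.
* `balanced_resample()` interprets the repeated-draws mechanism as
  independent re-draws of the negative subset; within-draw replacement
  (which would duplicate coordinates) is deliberately not offered.
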