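# heronscape

Multi-scale colony-site selection analysis for colonial waterbirds.

Colonial waterbirds such as herons nest communally, and the landscape
around a colony influences where colonies form — but at an unknown radius.
`heronscape` implements the full analysis pipeline for finding that
*scale of effect*: it compares presence sites against constrained
pseudoabsence sites using the composition of a categorical land-use map
(eight classes: cropland, forest, shrub, grassland, water, barren,
impervious, wetland) inside buffers of 13 radii (0.5–20 km), fits an
ensemble of random-forest classifiers per radius, and selects the radius
whose models have the highest mean out-of-bag accuracy. Supporting
analyses cover permutation variable importance at the focus scales,
Pearson correlation structure, a deletion-based outlier screen on annular
scales, per-scale Shannon-diversity comparisons (normality-gated Welch *t*
vs Mann–Whitney *U*), and NMDS ordination of buffer compositions.

The core quantities, per buffer spec *b* and point *i*:

- class areas `A_k(i, b)` by cell-centre counting in the half-open annulus
  `[inner, outer)`, so adjacent rings partition the disc exactly;
- Shannon diversity `H(i, b) = −Σ_k p_k ln p_k`, `p_k = A_k / Σ A`;
- per-scale OOB accuracy `acc_j = 1 − err_OOB` over repeated forests
  (each tree trains on a 70% subsample without replacement, leaving an
  exact 30% OOB set), summarised as max / mean / min;
- scale of effect `b* = argmax_b mean_j acc_j(b)`.

Because real colony data and a national raster cannot ship with a
package, everything runs on a synthetic study system with a *planted*
preference (by default: water cover within 1 km, logistic selection slope
5 per SD of cover) that the downstream pipeline must recover — the
package's tests are property checks against that known ground truth and
against brute-force oracles.

## Worked example

The one-call demo runs the whole pipeline on a 25.6 km synthetic domain
(60 presences, 60 of 500 pseudoabsences, all 13 radii, reduced ensembles):

```r
library(heronscape)
rep <- run_pipeline(default_config(), out_dir = "demo_out")
print(rep)
#> <run_report> multi-scale colony-site selection pipeline
#>   best scale: disc_1km (mean OOB acc 0.571, max 0.650)
#>   top variable there: water
#>   diversity tests: all p < 0.05: FALSE (max p 0.4234)
#>   NMDS stress: 0.232
#>   screen ring_1-2km: delta +0.079, slope 0.0014 (increasing)
#>   screen ring_6-8km: delta +0.109, slope 0.0017 (increasing)
```

Reading the output: the generator planted a water preference at 1 km, and
the accuracy sweep recovers `disc_1km` as the scale of effect with water
as the top-ranked variable there — the headline property of the method.
The diversity tests are mostly non-significant because the synthetic
conditions plant a water preference, not a diversity shift (the gated
test's power is exercised separately in the test suite). The screen's
`delta` is the accuracy gained by the best deletion group on each annular
scale, and `slope` the trend of the per-k best accuracy.

`demo_out/` then contains the landscape grid, all point sets, the
feature table, per-scale accuracy summaries, importance and Pearson
tables, screen and diversity tables, NMDS coordinates and a JSON run
report. Runs are byte-for-byte reproducible for a fixed seed.

The `analysis/` directory holds the same workflow as six numbered,
narrated scripts at the full study scale (512 × 512 grid, 100/100
points): `01_simulate.R` → `06_landscape_stats.R`, writing to
`results/analysis/`.

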