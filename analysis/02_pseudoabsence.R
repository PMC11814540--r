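#!/usr/bin/env Rscript
# Stage 2 — the negative class.
#
# Samples 500 pseudoabsence candidates uniformly over the part of the
# domain that is at least 1 km from every sighting, outside the 5 km border
# band and outside towns (the desk-scale analogue of the study's 5 km /
# 100 km / large-town exclusions), then draws the 100 negatives used by the
# models. Masks are regenerated deterministically from the stage seeds.

library(heronscape)

cfg <- validate_config(study_config(seed = 1))
out <- "results/analysis"
raster <- read_raster_txt(file.path(out, "landscape.txt"))
sightings <- read_points_csv(file.path(out, "sightings.csv"))

masks <- make_masks(raster, border_band = cfg$pseudoabsence$border_dist,
                    town_count = 0L)  # towns already stamped in the raster
masks$town_mask <- make_masks(
  generate_landscape(cfg$landscape$n_rows, cfg$landscape$n_cols,
                     cfg$landscape$cell_size,
                     class_mix = cfg$landscape$class_mix,
                     patchiness = cfg$landscape$patchiness,
                     seed = derive_seed(cfg$seed, "landscape")),
  border_band = cfg$pseudoabsence$border_dist,
  town_count = cfg$landscape$town_count,
  town_radius = cfg$landscape$town_radius,
  seed = derive_seed(cfg$seed, "towns"))$town_mask

spec <- constraint_spec(
  min_sighting_dist = cfg$pseudoabsence$min_sighting_dist,
  border_dist = cfg$pseudoabsence$border_dist,
  avoid_towns = cfg$pseudoabsence$avoid_towns,
  n_candidates = cfg$pseudoabsence$n_candidates,
  n_draw = cfg$pseudoabsence$n_draw)
candidates <- sample_candidates(raster, sightings, masks, spec,
                                seed = derive_seed(cfg$seed, "candidates"))
negatives <- draw_negatives(candidates, spec$n_draw,
                            seed = derive_seed(cfg$seed, "negatives"))

rej <- attr(candidates, "rejections")
cat(sprintf(
  "Accepted %d candidates; rejections — sighting: %d, border: %d, town: %d.\n",
  nrow(candidates), rej["sighting"], rej["border"], rej["town"]))
cat("Candidate land use:\n")
print(table(candidates$landuse))

write_points_csv(candidates, file.path(out, "candidates.csv"))
write_points_csv(negatives, file.path(out, "negatives.csv"))
cat("Wrote candidates.csv and negatives.csv to", out, "\n")
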