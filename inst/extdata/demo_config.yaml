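# Demonstration-scale pipeline configuration: a 25.6 km synthetic domain
# with a planted water preference at 1 km. Mirrors default_config().
seed: 1
landscape:
  n_rows: 256
  n_cols: 256
  cell_size: 100
  class_mix: [0.20, 0.25, 0.05, 0.20, 0.08, 0.10, 0.05, 0.07]
  patchiness: 500
  town_count: 4
  town_radius: 1200
presence:
  n_points: 60
  min_spacing: 1500
  focal_class: water
  focal_radius: 1000
  strength: 5
  baseline_rate: 0.5
sightings:
  n_sightings: 150
pseudoabsence:
  min_sighting_dist: 500
  border_dist: 2000
  avoid_towns: true
  n_candidates: 500
  n_draw: 60
  n_reps: 10
features:
  radii_m: [500, 1000, 2000, 3000, 4000, 5000, 6000, 7000, 8000, 9000, 10000, 15000, 20000]
model:
  n_trees: 100
  n_models: 20
  oob_fraction: 0.30
  sampling: subsample70
  importance: permutation
screen:
  deletion_counts: [1, 5, 10, 25, 50]
  reps_per_k: 5
  rings_m: [[1000, 2000], [6000, 8000]]
  enabled: true
stats:
  alpha_normality: 0.05
  nmds_radius_m: 1000
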