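empty_sightings <- function() {
  labeled_points(numeric(0), numeric(0), label = character(0),
                 id = character(0))
}

test_that("unconstrained sampling returns the requested pool size", {
  r <- random_raster(64, 64, cell_size = 100, seed = 1)
  spec <- constraint_spec(min_sighting_dist = 0, n_candidates = 120,
                          n_draw = 50)
  cand <- sample_candidates(r, empty_sightings(), NULL, spec, seed = 2)
  expect_equal(nrow(cand), 120)
  expect_true(all(cand$label == 0L))
  expect_true(all(cand$landuse %in% names(landuse_classes)))
})

test_that("every candidate honours the sighting exclusion by brute force", {
  r <- random_raster(64, 64, cell_size = 100, seed = 3)
  sight <- labeled_points(3200, -3200, label = "sighting")
  spec <- constraint_spec(min_sighting_dist = 2000, n_candidates = 100,
                          n_draw = 50)
  cand <- sample_candidates(r, sight, NULL, spec, seed = 4)
  d <- sqrt((cand$x - 3200)^2 + (cand$y + 3200)^2)
  expect_true(all(d >= 2000))
})

test_that("all active constraints hold simultaneously (exhaustive audit)", {
  r <- random_raster(128, 128, cell_size = 100, seed = 5)
  m <- make_masks(r, border_band = 1500, town_count = 3, town_radius = 800,
                  seed = 6)
  sight <- generate_sighting_pool(m$raster, 60, seed = 7)
  spec <- constraint_spec(min_sighting_dist = 700, border_dist = 1500,
                          n_candidates = 200, n_draw = 100)
  cand <- sample_candidates(m$raster, sight, m, spec, seed = 8)
  dmin <- vapply(seq_len(nrow(cand)), function(i) {
    min(sqrt((sight$x - cand$x[i])^2 + (sight$y - cand$y[i])^2))
  }, numeric(1))
  expect_true(all(dmin >= 700))
  rowcol <- cbind(floor(-cand$y / 100) + 1, floor(cand$x / 100) + 1)
  expect_false(any(m$border_mask[rowcol]))
  expect_false(any(m$town_mask[rowcol]))
})

test_that("saturated sighting coverage raises an infeasibility error", {
  r <- random_raster(32, 32, cell_size = 100, seed = 9)
  xy <- expand.grid(x = seq(200, 3000, 400), y = seq(200, 3000, 400))
  sight <- labeled_points(xy$x, -xy$y, label = "sighting")
  spec <- constraint_spec(min_sighting_dist = 500, n_candidates = 50,
                          n_draw = 10)
  expect_error(
    sample_candidates(r, sight, NULL, spec, seed = 10, budget_factor = 20),
    "infeasible")
})

test_that("candidate density is conditionally uniform over the valid region", {
  r <- random_raster(128, 128, cell_size = 100, seed = 11)
  sight <- generate_sighting_pool(r, 30, seed = 12)
  spec <- constraint_spec(min_sighting_dist = 600, n_candidates = 600,
                          n_draw = 100)
  cand <- sample_candidates(r, sight, NULL, spec, seed = 13)
  # expected counts proportional to the valid cell count per coarse bin
  cx <- (seq_len(128) - 0.5) * 100
  valid <- matrix(TRUE, 128, 128)
  for (s in seq_len(nrow(sight))) {
    d2 <- outer((-cx - sight$y[s])^2, (cx - sight$x[s])^2, "+")
    valid <- valid & d2 >= 600^2
  }
  bin <- function(v) pmin(4L, floor(v / (12800 / 4)) + 1L)
  obs <- table(factor(bin(cand$x), 1:4), factor(bin(-cand$y), 1:4))
  expct <- matrix(0, 4, 4)
  for (i in 1:128) for (j in 1:128) {
    if (valid[i, j]) {
      expct[bin((j - 0.5) * 100), bin((i - 0.5) * 100)] <-
        expct[bin((j - 0.5) * 100), bin((i - 0.5) * 100)] + 1
    }
  }
  p <- stats::chisq.test(as.vector(obs),
                         p = as.vector(expct) / sum(expct))$p.value
  expect_gt(p, 0.001)
})

test_that("negative draws are exact without-replacement samples", {
  r <- random_raster(48, 48, cell_size = 100, seed = 14)
  spec <- constraint_spec(min_sighting_dist = 0, n_candidates = 40,
                          n_draw = 40)
  cand <- sample_candidates(r, empty_sightings(), NULL, spec, seed = 15)
  full <- draw_negatives(cand, 40, seed = 16)
  expect_setequal(full$id, cand$id)
  expect_equal(nrow(draw_negatives(cand, 0, seed = 17)), 0)
  expect_error(draw_negatives(cand, 41, seed = 18), "exceeds")
})

test_that("inclusion frequency over repeated draws is near-uniform", {
  cand <- labeled_points(seq_len(500), seq_len(500), label = 0L)
  counts <- integer(500)
  for (i in seq_len(2000)) {
    drawn <- draw_negatives(cand, 100, seed = i)
    counts[match(drawn$id, cand$id)] <- counts[match(drawn$id, cand$id)] + 1L
  }
  freq <- counts / 2000
  expect_true(all(abs(freq - 0.20) <= 0.04))
})

test_that("balanced resampling derives deterministic per-rep sub-seeds", {
  cand <- labeled_points(seq_len(50), seq_len(50), label = 0L)
  one <- balanced_resample(cand, 20, n_reps = 1, seed = 5)
  expect_identical(one[[1]],
                   draw_negatives(cand, 20, seed = derive_seed(5, "rep1")))
  a <- balanced_resample(cand, 20, n_reps = 5, seed = 5)
  b <- balanced_resample(cand, 20, n_reps = 5, seed = 5)
  c <- balanced_resample(cand, 20, n_reps = 5, seed = 6)
  expect_identical(a, b)
  expect_false(identical(
    sort(unique(unlist(lapply(a, `[[`, "id")))),
    sort(unique(unlist(lapply(c, `[[`, "id"))))
  ) && all(mapply(identical, a, c)))
})

test_that("averaging over replicates reduces the downstream accuracy noise", {
  # fixed landscape and presences; 10 negative re-draws at the study's
  # 1:5 draw ratio. The across-rep mean accuracy must be estimated more
  # tightly than the typical fit-to-fit spread of a single replicate.
  r <- generate_landscape(128, 128, 100, patchiness = 500, seed = 20)
  pres <- place_presences(r, preference_spec("water", 1000, 5), 50,
                          seed = 21)
  spec <- constraint_spec(min_sighting_dist = 0, n_candidates = 250,
                          n_draw = 50)
  cand <- sample_candidates(r, empty_sightings(), NULL, spec, seed = 22)
  reps <- balanced_resample(cand, 50, n_reps = 10, seed = 23)
  disc1 <- list(buffer_spec(0, 1000))
  rep_stats <- vapply(seq_along(reps), function(i) {
    pts <- rbind(pres, reps[[i]][, names(pres)])
    ft <- build_feature_table(r, pts, disc1)
    fit <- fit_scale_ensemble(ft, disc1[[1]], test_model_config(seed = 30 + i))
    c(fit$mean, stats::sd(fit$accuracies))
  }, numeric(2))
  se_of_mean <- stats::sd(rep_stats[1, ]) / sqrt(ncol(rep_stats))
  expect_lt(se_of_mean, stats::median(rep_stats[2, ]))
})
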