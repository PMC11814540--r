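test_that("degenerate class mix fills the grid with a single class", {
  r <- generate_landscape(32, 32, cell_size = 30,
                          class_mix = c(1, 0, 0, 0, 0, 0, 0, 0),
                          patchiness = 60, seed = 1)
  expect_true(all(r$grid == 1L))
})

test_that("landscape generation is a pure function of its seed", {
  a <- generate_landscape(64, 64, 30, patchiness = 150, seed = 7)
  b <- generate_landscape(64, 64, 30, patchiness = 150, seed = 7)
  c <- generate_landscape(64, 64, 30, patchiness = 150, seed = 8)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, c$grid))
})

test_that("realised class proportions track the requested mix", {
  for (seed in 1:2) {
    r <- generate_landscape(512, 512, 30, class_mix = rep(1 / 8, 8),
                            patchiness = 300, seed = seed)
    p <- raster_class_proportions(r)
    expect_true(all(p >= 0.095 & p <= 0.155),
                info = sprintf("seed %d: %s", seed,
                               paste(round(p, 3), collapse = " ")))
  }
  # patches are spatially contiguous: neighbouring cells agree far more
  # often than under an iid shuffle of the same composition
  r <- generate_landscape(128, 128, 30, patchiness = 300, seed = 3)
  agree <- mean(r$grid[, -1] == r$grid[, -ncol(r$grid)])
  expect_gt(agree, 0.5)
})

test_that("invalid generator inputs are rejected", {
  expect_error(generate_landscape(0, 10, 30), "positive")
  expect_error(generate_landscape(10, 10, 30, class_mix = rep(0.2, 8)),
               "summing to 1")
  expect_error(generate_landscape(10, 10, 30, patchiness = 10),
               "cell_size")
})

test_that("zero-strength preference places presences uniformly", {
  r <- generate_landscape(128, 128, 100, patchiness = 500, seed = 2)
  pref <- preference_spec("water", 1000, strength = 0)
  pts <- place_presences(r, pref, 50, min_spacing = 0, seed = 11)
  expect_equal(nrow(pts), 50)
  expect_true(all(pts$label == 1L))
  # focal cover of presences within ~2 SE of the landscape candidate mean
  prop_at <- function(x, y) {
    a <- extract_buffer_areas(r, c(x, y), buffer_spec(0, 1000))
    a[["water"]] / sum(a)
  }
  pres <- mapply(prop_at, pts$x, pts$y)
  probe <- withr::with_seed(99, {
    i <- sample.int(128, 200, TRUE); j <- sample.int(128, 200, TRUE)
    mapply(prop_at, (j - 0.5) * 100, -(i - 0.5) * 100)
  })
  se <- sqrt(stats::sd(pres)^2 / length(pres) +
               stats::sd(probe)^2 / length(probe))
  expect_lt(abs(mean(pres) - mean(probe)), 3 * se)
})

test_that("planted water preference shifts presence focal cover upward", {
  r <- generate_landscape(128, 128, 100, patchiness = 500, seed = 2)
  pref <- preference_spec("water", 1000, strength = 5)
  pts <- place_presences(r, pref, 60, min_spacing = 0, seed = 12)
  prop_at <- function(x, y) {
    a <- extract_buffer_areas(r, c(x, y), buffer_spec(0, 1000))
    a[["water"]] / sum(a)
  }
  pres <- mapply(prop_at, pts$x, pts$y)
  probe <- withr::with_seed(98, {
    i <- sample.int(128, 300, TRUE); j <- sample.int(128, 300, TRUE)
    mapply(prop_at, (j - 0.5) * 100, -(i - 0.5) * 100)
  })
  expect_lt(stats::t.test(pres, probe, alternative = "greater")$p.value,
            0.01)
})

test_that("a single presence and spacing enforcement both work", {
  r <- generate_landscape(64, 64, 100, patchiness = 200, seed = 4)
  pref <- preference_spec("water", 500, strength = 0)
  one <- place_presences(r, pref, 1, seed = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$label, 1L)
  pts <- place_presences(r, pref, 15, min_spacing = 1000, seed = 6)
  d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
  expect_true(all(d[upper.tri(d)] >= 1000))
  # infeasible spacing names the constraint
  expect_error(place_presences(r, pref, 80, min_spacing = 2000, seed = 7),
               "min_spacing")
})

test_that("border mask matches the brute-force band count", {
  r <- random_raster(40, 55, cell_size = 30, seed = 9)
  band <- 10 * 30  # ten cells' worth
  m <- make_masks(r, border_band = band, town_count = 0, seed = 1)
  expect_equal(sum(m$border_mask), oracle_border_count(r, band))
  m0 <- make_masks(r, border_band = 0, town_count = 0, seed = 1)
  expect_false(any(m0$border_mask))
  expect_false(any(m0$town_mask))
  expect_error(make_masks(r, border_band = 40 * 30 / 2 + 1),
               "exhausts")
})

test_that("towns stamp impervious cover only inside the town mask", {
  r <- random_raster(64, 64, cell_size = 100, seed = 10)
  m <- make_masks(r, border_band = 0, town_count = 3, town_radius = 600,
                  seed = 3)
  expect_true(any(m$town_mask))
  expect_true(all(m$raster$grid[m$town_mask] == 7L))
  expect_identical(m$raster$grid[!m$town_mask], r$grid[!m$town_mask])
})

test_that("sighting pool is uniform, seeded and sized as requested", {
  r <- random_raster(256, 256, cell_size = 100, seed = 20)
  expect_equal(nrow(generate_sighting_pool(r, 0)), 0)
  a <- generate_sighting_pool(r, 500, seed = 21)
  b <- generate_sighting_pool(r, 500, seed = 21)
  expect_identical(a, b)
  big <- generate_sighting_pool(r, 10000, seed = 22)
  bins <- table(cut(big$x, breaks = seq(0, 25600, length.out = 5)),
                cut(-big$y, breaks = seq(0, 25600, length.out = 5)))
  expect_gt(stats::chisq.test(as.vector(bins))$p.value, 0.001)
})

test_that("rasters and point sets round-trip through their text formats", {
  r <- random_raster(12, 17, cell_size = 30, seed = 30)
  r$origin <- c(1000, 2000)
  path <- withr::local_tempfile(fileext = ".txt")
  write_raster_txt(r, path)
  r2 <- read_raster_txt(path)
  expect_identical(r2$grid, r$grid)
  expect_equal(r2$cell_size, r$cell_size)
  expect_equal(r2$origin, r$origin)
  pts <- labeled_points(c(1.5, 2.5), c(-3, -4), label = c(1L, 0L))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_points_csv(pts, csv)
  back <- read_points_csv(csv)
  expect_equal(back$x, pts$x)
  expect_equal(back$label, pts$label)
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_points_geojson(pts, gj)
  parsed <- jsonlite::read_json(gj)
  expect_equal(parsed$type, "FeatureCollection")
  expect_length(parsed$features, 2)
  expect_equal(unlist(parsed$features[[1]]$geometry$coordinates),
               c(1.5, -3))
})
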