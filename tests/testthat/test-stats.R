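test_that("U statistic matches closed forms and pair enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$U, 2)
  expect_equal(mann_whitney_u(c(1, 3), c(2, 4))$U, 1)
  for (s in 1:20) {
    xy <- withr::with_seed(s, {
      list(x = sample(1:6, sample(2:8, 1), TRUE),
           y = sample(1:6, sample(2:8, 1), TRUE))
    })
    got <- mann_whitney_u(xy$x, xy$y)
    expect_equal(got$U, oracle_u(xy$x, xy$y))
    # complement identity
    expect_equal(got$U + mann_whitney_u(xy$y, xy$x)$U,
                 length(xy$x) * length(xy$y))
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact p agrees with wilcox.test on tie-free small samples", {
  for (s in 1:20) {
    xy <- withr::with_seed(s, list(x = stats::rnorm(5), y = stats::rnorm(6)))
    got <- mann_whitney_u(xy$x, xy$y)
    expect_equal(got$method, "exact")
    ref <- stats::wilcox.test(xy$x, xy$y, exact = TRUE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks wilcox.test with ties", {
  for (s in 1:10) {
    xy <- withr::with_seed(s, {
      list(x = sample(1:10, 25, TRUE), y = sample(1:10, 30, TRUE))
    })
    got <- mann_whitney_u(xy$x, xy$y)
    expect_equal(got$method, "normal")
    ref <- suppressWarnings(
      stats::wilcox.test(xy$x, xy$y, exact = FALSE, correct = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("exact and normal p agree closely at n1 = n2 = 6", {
  diffs <- vapply(1:200, function(s) {
    xy <- withr::with_seed(s, list(x = stats::rnorm(6), y = stats::rnorm(6)))
    exact <- mann_whitney_u(xy$x, xy$y)$p_value
    u <- oracle_u(xy$x, xy$y)
    z <- (abs(u - 18) - 0.5) / sqrt(36 * 13 / 12)
    approx <- 2 * stats::pnorm(-max(z, 0))
    abs(exact - min(approx, 1))
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
})

test_that("normality gate behaves on known distributions", {
  normal_p <- vapply(1:10, function(s) {
    normality_test(withr::with_seed(s, stats::rnorm(500)))$p_value
  }, numeric(1))
  expect_gte(sum(normal_p > 0.05), 9)
  expo_p <- vapply(1:10, function(s) {
    normality_test(withr::with_seed(s, stats::rexp(200)))$p_value
  }, numeric(1))
  expect_gte(sum(expo_p < 0.01), 9)
  expect_error(normality_test(rep(1, 10)), "constant")
  expect_error(normality_test(1:2), "3 <= n")
})

test_that("diversity comparison gates between t and Mann-Whitney", {
  x <- withr::with_seed(1, stats::rnorm(100, 1.5, 0.3))
  y <- withr::with_seed(2, stats::rnorm(100, 1.5, 0.3))
  same <- compare_diversity(x, y)
  expect_true(same$p_value >= 0 && same$p_value <= 1)
  expect_equal(same$test_used, "t")
  skewed <- compare_diversity(withr::with_seed(3, stats::rexp(80)),
                              withr::with_seed(4, stats::rexp(80)))
  expect_equal(skewed$test_used, "mann_whitney")
  expect_warning(
    const <- compare_diversity(rep(1, 10), withr::with_seed(5, stats::rnorm(10))),
    "constant")
  expect_equal(const$test_used, "mann_whitney")
})

test_that("a planted diversity shift is detected with high power", {
  for (s in 1:3) {
    base <- withr::with_seed(s, stats::rnorm(100, 1.2, 0.3))
    up <- withr::with_seed(s + 50, stats::rnorm(100, 1.7, 0.3))
    res <- compare_diversity(up, base)
    expect_lt(res$p_value, 0.001)
    expect_equal(res$direction, "presence")
  }
})

test_that("group order only flips the direction, not the conclusion", {
  x <- withr::with_seed(6, stats::rnorm(40, 2, 0.4))
  y <- withr::with_seed(7, stats::rnorm(40, 1.6, 0.4))
  ab <- compare_diversity(x, y)
  ba <- compare_diversity(y, x)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  expect_equal(ab$direction, "presence")
  expect_equal(ba$direction, "absence")
})

test_that("per-scale diversity tables carry one row per buffer spec", {
  r <- random_raster(64, 64, cell_size = 100, seed = 8)
  pts <- generate_sighting_pool(r, 30, seed = 9)
  pts$label <- rep(c(1L, 0L), 15)
  ft <- build_feature_table(r, pts, disc_specs(c(500, 1000, 2000)))
  tab <- diversity_by_scale(ft)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(tab$test_used %in% c("t", "mann_whitney")))
})

test_that("NMDS recovers low stress for two-gradient compositions", {
  for (s in 1:3) {
    ord <- nmds_ordination(gradient_compositions(60, seed = s), seed = s)
    expect_lt(ord$stress, 0.10)
    expect_equal(ncol(ord$points), 2)
    expect_true(all(is.finite(ord$points)))
  }
})

test_that("NMDS rejects degenerate inputs and bounds stress", {
  dup <- tibble::as_tibble(as.data.frame(
    matrix(rep(c(1, 2, 3, 4, 0, 0, 0, 0), each = 10), 10,
           dimnames = list(NULL, names(landuse_classes)))))
  expect_error(nmds_ordination(dup, seed = 1), "identical")
  ok <- nmds_ordination(gradient_compositions(30, seed = 9), seed = 9)
  expect_gte(ok$stress, 0)
  expect_lte(ok$stress, 1)
})
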