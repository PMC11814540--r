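# Synthetic tabular fixtures, built in code at test time.

# checkerboard-free random raster: iid cell codes (no autocorrelation)
random_raster <- function(nr, nc, cell_size = 30, seed = 1,
                          codes = 1:8) {
  withr::with_seed(seed, {
    landuse_raster(matrix(sample(codes, nr * nc, replace = TRUE), nr, nc),
                   cell_size)
  })
}

# tabular class-area frame whose label is a (possibly noisy) threshold on
# water area; other columns are uninformative
threshold_features <- function(n, noise_sd = 0, flip = integer(0),
                               seed = 1) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(abs(stats::rnorm(n * 8)) * 1e5, n, 8))
    names(df) <- names(landuse_classes)
    lab <- as.integer(df$water + stats::rnorm(n, 0, noise_sd * 1e5) >
                        stats::median(df$water))
    if (length(flip)) lab[flip] <- 1L - lab[flip]
    df$label <- lab
    df
  })
}

# pure-noise frame: labels independent of all features
noise_features <- function(n, seed = 1) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(stats::rnorm(n * 8), n, 8))
    names(df) <- names(landuse_classes)
    df$label <- rep(0:1, length.out = n)
    df
  })
}

# compositions driven by two latent gradients (for ordination recovery)
gradient_compositions <- function(n, seed = 1, decay = 4) {
  withr::with_seed(seed, {
    lat <- cbind(stats::runif(n), stats::runif(n))
    centers <- cbind(stats::runif(8), stats::runif(8))
    comp <- t(apply(lat, 1, function(z) {
      exp(-decay * ((z[1] - centers[, 1])^2 + (z[2] - centers[, 2])^2))
    }))
    colnames(comp) <- names(landuse_classes)
    tibble::as_tibble(as.data.frame(comp))
  })
}

# reduced model config used throughout the tests
test_model_config <- function(seed = 1, n_models = 10L, n_trees = 50L) {
  model_config(n_trees = n_trees, n_models = n_models, seed = seed)
}
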