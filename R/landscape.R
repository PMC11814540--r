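#' Specify a planted scale-specific habitat preference
#'
#' The generator's ground truth: presences are placed with an acceptance
#' probability that increases logistically with the proportion of
#' `focal_class` cover inside `focal_radius` of the candidate site. The
#' proportion is standardised against the landscape-wide candidate
#' distribution, so `strength` is a log-odds slope per standard deviation of
#' focal cover and is comparable across landscapes.
#'
#' @param focal_class Class code 1--8 (or name from [landuse_classes]).
#' @param focal_radius Radius in metres at which the preference acts.
#' @param strength Selection slope, dimensionless, >= 0. `strength = 0` makes
#'   presence placement uniform over valid cells.
#' @param baseline_rate Acceptance probability at average focal cover
#'   (default 0.5).
#' @return A `preference_spec` list.
#' @export
preference_spec <- function(focal_class, focal_radius, strength,
                            baseline_rate = 0.5) {
  if (is.character(focal_class)) focal_class <- landuse_classes[[focal_class]]
  focal_class <- as.integer(focal_class)
  stopifnot(focal_class >= 1L, focal_class <= 8L,
            focal_radius > 0, strength >= 0,
            baseline_rate > 0, baseline_rate < 1)
  structure(list(focal_class = focal_class, focal_radius = focal_radius,
                 strength = strength, baseline_rate = baseline_rate),
            class = "preference_spec")
}

# Smooth iid N(0,1) noise with a separable Gaussian kernel (row-normalised,
# truncated at 3 sigma), then restandardise. sigma in cells.
smooth_gaussian_field <- function(n_rows, n_cols, sigma) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma <= 0) return(z)
  band <- function(n) {
    k <- outer(seq_len(n), seq_len(n), function(i, j) {
      d <- i - j
      ifelse(abs(d) <= 3 * sigma, exp(-d^2 / (2 * sigma^2)), 0)
    })
    k / rowSums(k)
  }
  s <- band(n_rows) %*% z %*% t(band(n_cols))
  (s - mean(s)) / stats::sd(s)
}

#' Generate a synthetic categorical land-use landscape
#'
#' One independent spatially autocorrelated Gaussian field is generated per
#' land-use class; each cell takes the class whose shifted field is largest,
#' with the per-class shifts calibrated iteratively so the realised class
#' proportions match `class_mix`. This yields an interlocking patch mosaic
#' (a neutral landscape) in which the spatial structure of each class is
#' independent of every other class's field.
#'
#' @param n_rows,n_cols Grid extent in cells.
#' @param cell_size Cell side in metres (default 100).
#' @param class_mix Numeric length-8 vector of target class proportions in
#'   legend order ([landuse_classes]); must sum to 1.
#' @param patchiness Spatial correlation length in metres (>= `cell_size`);
#'   the Gaussian smoothing scale of the class fields.
#' @param seed Integer seed; the raster is a pure function of the arguments.
#' @return A [landuse_raster()] with origin `(0, 0)` at the top-left corner.
#' @export
generate_landscape <- function(n_rows, n_cols, cell_size = 100,
                               class_mix = default_class_mix(),
                               patchiness = 1000, seed = 1L) {
  if (n_rows < 1 || n_cols < 1) stop("grid extent must be positive", call. = FALSE)
  if (length(class_mix) != 8L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-9) {
    stop("`class_mix` must be 8 non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (patchiness < cell_size) stop("`patchiness` must be >= cell_size", call. = FALSE)
  sigma <- patchiness / cell_size
  withr::with_seed(seed, {
    active <- which(class_mix > 0)
    if (length(active) == 1L) {
      grid <- matrix(active, n_rows, n_cols)
      return(landuse_raster(grid, cell_size))
    }
    fields <- vapply(seq_len(8L), function(k) {
      if (k %in% active) as.vector(smooth_gaussian_field(n_rows, n_cols, sigma))
      else rep(-Inf, n_rows * n_cols)
    }, numeric(n_rows * n_cols))
    # calibrate additive shifts so argmax hits class_mix; damped fixed point
    shift <- rep(0, 8L)
    n <- n_rows * n_cols
    for (it in seq_len(120L)) {
      cls <- max.col(sweep(fields[, active, drop = FALSE], 2L,
                           shift[active], "+"), ties.method = "first")
      realized <- tabulate(cls, nbins = length(active)) / n
      err <- class_mix[active] - realized
      if (max(abs(err)) < 0.002) break
      shift[active] <- shift[active] + (2.5 / sqrt(it)) * err
    }
    grid <- matrix(active[cls], n_rows, n_cols)
    landuse_raster(grid, cell_size)
  })
}

#' Default land-use class mix
#'
#' A broadly continental-scale composition: cropland- and forest-dominated
#' with modest water, wetland and impervious fractions.
#'
#' @return Named numeric vector over the eight classes, summing to 1.
#' @export
default_class_mix <- function() {
  stats::setNames(c(0.20, 0.25, 0.05, 0.20, 0.08, 0.10, 0.05, 0.07),
                  names(landuse_classes))
}

# closure drawing uniform random points over non-nodata cells (continuous
# within the cell), optionally excluding cells where `exclude` is TRUE
valid_point_sampler <- function(raster, exclude = NULL) {
  valid <- raster$grid != 0L
  if (!is.null(exclude)) valid <- valid & !exclude
  idx <- which(valid)
  if (length(idx) == 0L) stop("no valid cells to sample from", call. = FALSE)
  nr <- nrow(raster$grid)
  cs <- raster$cell_size
  x0 <- raster$origin[1]; y0 <- raster$origin[2]
  function(n) {
    pick <- idx[sample.int(length(idx), n, replace = TRUE)]
    row <- (pick - 1L) %% nr + 1L
    col <- (pick - 1L) %/% nr + 1L
    list(
      x = x0 + (col - 1L) * cs + stats::runif(n) * cs,
      y = y0 - ((row - 1L) * cs + stats::runif(n) * cs)
    )
  }
}

sample_valid_points <- function(raster, n, exclude = NULL) {
  valid_point_sampler(raster, exclude)(n)
}

# proportion of focal-class cover among non-nodata cells within radius
focal_proportion <- function(raster, x, y, focal_class, radius) {
  counts <- buffer_class_counts(raster, x, y, c(0, radius))
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  counts[1, focal_class] / tot
}

#' Place presence points with a planted preference
#'
#' Rejection sampling: candidate locations are uniform over valid cells and
#' accepted with probability
#' `plogis(qlogis(baseline_rate) + strength * z)`, where `z` is the
#' candidate's focal-class cover proportion inside `focal_radius`,
#' standardised by the mean and SD of that proportion over a seeded probe
#' sample of the valid region. Accepted points must also keep
#' `min_spacing` metres from every previously accepted point, a desk-scale
#' analogue of keeping colony records spatially independent.
#'
#' @param raster A [landuse_raster()].
#' @param pref A [preference_spec()].
#' @param n_points Number of presences (>= 1).
#' @param min_spacing Minimum pairwise distance in metres.
#' @param seed Integer seed.
#' @param exclude Optional logical grid of cells presences must avoid
#'   (e.g. a border band, for comparability with constrained pseudoabsences).
#' @param n_probe Probe sample size for standardising focal cover (default 400).
#' @param budget_factor Proposals allowed per requested point before
#'   declaring infeasibility (default 1000).
#' @return Labelled points tibble, `label = 1`, `source = "synthetic-presence"`.
#' @export
place_presences <- function(raster, pref, n_points, min_spacing = 0,
                            seed = 1L, exclude = NULL, n_probe = 400L,
                            budget_factor = 1000L) {
  stopifnot(inherits(pref, "preference_spec"), n_points >= 1)
  withr::with_seed(seed, {
    draw <- valid_point_sampler(raster, exclude)
    # standardisation of focal cover over the valid region
    pr <- draw(n_probe)
    pz <- vapply(seq_len(n_probe), function(i) {
      focal_proportion(raster, pr$x[i], pr$y[i], pref$focal_class,
                       pref$focal_radius)
    }, numeric(1))
    pz <- pz[is.finite(pz)]
    pbar <- mean(pz)
    psd <- stats::sd(pz)
    if (!is.finite(psd) || psd == 0) psd <- 1
    ax <- numeric(0); ay <- numeric(0)
    budget <- as.integer(budget_factor) * n_points
    tries <- 0L
    spacing_rejects <- 0L
    while (length(ax) < n_points && tries < budget) {
      tries <- tries + 1L
      cand <- draw(1L)
      if (min_spacing > 0 && length(ax) > 0 &&
          min((cand$x - ax)^2 + (cand$y - ay)^2) < min_spacing^2) {
        spacing_rejects <- spacing_rejects + 1L
        next
      }
      p <- focal_proportion(raster, cand$x, cand$y, pref$focal_class,
                            pref$focal_radius)
      if (!is.finite(p)) next
      z <- (p - pbar) / psd
      acc <- stats::plogis(stats::qlogis(pref$baseline_rate) +
                             pref$strength * z)
      if (stats::runif(1) < acc) {
        ax <- c(ax, cand$x); ay <- c(ay, cand$y)
      }
    }
    if (length(ax) < n_points) {
      stop(sprintf(paste0(
        "could not place %d presences within %d proposals; ",
        "binding constraint: %s (%.1f%% of proposals rejected by spacing)"),
        n_points, budget,
        if (spacing_rejects > tries / 2) "min_spacing" else "preference acceptance",
        100 * spacing_rejects / max(tries, 1L)), call. = FALSE)
    }
    labeled_points(ax, ay, label = 1L, source = "synthetic-presence",
                   id = paste0("p_", seq_len(n_points)))
  })
}

#' Border and town masks
#'
#' Builds (a) a border mask flagging every cell whose centre lies within
#' `border_band` metres of the domain edge and (b) a town mask that is the
#' union of `town_count` randomly centred discs of radius `town_radius`,
#' whose non-nodata cells are forced to class 7 (impervious) in the returned
#' raster. Towns stand in for the large settlements that pseudoabsence
#' sampling must avoid.
#'
#' @param raster A [landuse_raster()].
#' @param border_band Metres; must be less than half the smaller domain side.
#' @param town_count Number of town discs (>= 0).
#' @param town_radius Town disc radius in metres.
#' @param seed Integer seed for town centres.
#' @return List with elements `raster` (towns stamped in), `border_mask` and
#'   `town_mask` (logical grids sharing the raster extent).
#' @export
make_masks <- function(raster, border_band, town_count = 0L,
                       town_radius = 1000, seed = 1L) {
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  w <- nc * raster$cell_size; h <- nr * raster$cell_size
  if (border_band >= min(w, h) / 2) {
    stop("`border_band` exhausts the domain (must be < half the smaller side)",
         call. = FALSE)
  }
  cx <- cell_center_x(raster, seq_len(nc))
  cy <- cell_center_y(raster, seq_len(nr))
  x0 <- raster$origin[1]; y0 <- raster$origin[2]
  dist_edge_x <- pmin(cx - x0, x0 + w - cx)
  dist_edge_y <- pmin(y0 - cy, cy - (y0 - h))
  border_mask <- outer(dist_edge_y, dist_edge_x, pmin) < border_band
  town_mask <- matrix(FALSE, nr, nc)
  if (town_count > 0L) {
    centers <- withr::with_seed(seed, sample_valid_points(raster, town_count))
    for (t in seq_len(town_count)) {
      d2 <- outer((cy - centers$y[t])^2, (cx - centers$x[t])^2, "+")
      town_mask <- town_mask | (d2 < town_radius^2)
    }
    stamp <- town_mask & raster$grid != 0L
    raster$grid[stamp] <- 7L
  }
  list(raster = raster, border_mask = border_mask, town_mask = town_mask)
}

#' Generate a synthetic sighting pool
#'
#' Uniform random points over the non-nodata cells, standing in for a large
#' set of species sighting records around which pseudoabsences must keep
#' their distance.
#'
#' @param raster A [landuse_raster()].
#' @param n_sightings Number of points (>= 0).
#' @param seed Integer seed.
#' @return Labelled points tibble with `label = "sighting"`.
#' @export
generate_sighting_pool <- function(raster, n_sightings, seed = 1L) {
  stopifnot(n_sightings >= 0)
  if (n_sightings == 0L) {
    return(labeled_points(numeric(0), numeric(0), label = character(0),
                          source = character(0), id = character(0)))
  }
  pts <- withr::with_seed(seed, sample_valid_points(raster, n_sightings))
  labeled_points(pts$x, pts$y, label = "sighting",
                 source = "synthetic-sighting",
                 id = paste0("s_", seq_len(n_sightings)))
}
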