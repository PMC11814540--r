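#' Pseudoabsence sampling constraints
#'
#' The exclusion rules the negative class must satisfy: a minimum distance
#' from every species sighting, exclusion of a border band (so land-use
#' information around a point is complete), and avoidance of large towns.
#' Defaults follow the study design scaled to a desk-size synthetic domain:
#' 500 candidates, 100 drawn per replicate.
#'
#' @param min_sighting_dist Metres; candidates must be at least this far from
#'   every sighting (study rule: 5 km).
#' @param border_dist Metres; candidates must be outside the border band of
#'   this width (study rule: 100 km from national borders, scaled down here).
#' @param avoid_towns Logical; exclude the town mask.
#' @param n_candidates Candidate pool size (study: 500).
#' @param n_draw Negatives drawn per replicate (study: 100).
#' @return A `constraint_spec` list.
#' @export
constraint_spec <- function(min_sighting_dist = 2500, border_dist = 5000,
                            avoid_towns = TRUE, n_candidates = 500L,
                            n_draw = 100L) {
  stopifnot(min_sighting_dist >= 0, border_dist >= 0,
            n_draw <= n_candidates, n_candidates >= 1)
  structure(list(min_sighting_dist = min_sighting_dist,
                 border_dist = border_dist,
                 avoid_towns = isTRUE(avoid_towns),
                 n_candidates = as.integer(n_candidates),
                 n_draw = as.integer(n_draw)),
            class = "constraint_spec")
}

# cell-binned spatial index over sightings for fast minimum-distance checks;
# exact: any sighting within `dist` of a query point lies in the 3x3
# neighbourhood of the query's bin when bins have side >= dist
sighting_index <- function(sightings, dist) {
  if (dist <= 0 || nrow(sightings) == 0L) return(NULL)
  side <- dist
  bx <- floor(sightings$x / side)
  by <- floor(sightings$y / side)
  split(seq_len(nrow(sightings)), paste(bx, by))
}

near_sighting <- function(index, sightings, dist, x, y) {
  if (is.null(index)) return(FALSE)
  side <- dist
  bx <- floor(x / side); by <- floor(y / side)
  for (dxb in -1:1) for (dyb in -1:1) {
    ids <- index[[paste(bx + dxb, by + dyb)]]
    if (!is.null(ids) &&
        min((sightings$x[ids] - x)^2 + (sightings$y[ids] - y)^2) < dist^2) {
      return(TRUE)
    }
  }
  FALSE
}

#' Sample the pseudoabsence candidate pool
#'
#' Rejection sampling of `n_candidates` points, uniform over the part of the
#' domain that satisfies every active constraint: non-nodata cells, at least
#' `min_sighting_dist` from every sighting, outside the border band, and
#' (optionally) outside towns. A per-candidate land-use summary (the class of
#' the cell under the point) is attached as column `landuse`; the tally of
#' rejections per constraint is attached as attribute `"rejections"`.
#'
#' @param raster A [landuse_raster()].
#' @param sightings Labelled points tibble (may be empty).
#' @param masks Mask list from [make_masks()] (uses `border_mask`,
#'   `town_mask`); pass `NULL` for no masks.
#' @param spec A [constraint_spec()].
#' @param seed Integer seed.
#' @param budget_factor Proposals allowed per requested candidate before
#'   declaring infeasibility (default 1000).
#' @return Labelled points tibble with `label = 0`,
#'   `source = "pseudoabsence-candidate"` and a `landuse` column.
#' @export
sample_candidates <- function(raster, sightings, masks, spec, seed = 1L,
                              budget_factor = 1000L) {
  stopifnot(inherits(spec, "constraint_spec"))
  idx <- sighting_index(sightings, spec$min_sighting_dist)
  withr::with_seed(seed, {
    draw <- valid_point_sampler(raster)
    n <- spec$n_candidates
    budget <- budget_factor * n
    ax <- numeric(0); ay <- numeric(0); cls <- integer(0)
    rej <- c(sighting = 0L, border = 0L, town = 0L)
    tries <- 0L
    while (length(ax) < n && tries < budget) {
      tries <- tries + 1L
      cand <- draw(1L)
      cell <- point_cell(raster, cand$x, cand$y)
      if (!is.null(masks) &&
          masks$border_mask[cell$row, cell$col]) {
        rej["border"] <- rej["border"] + 1L
        next
      }
      if (spec$avoid_towns && !is.null(masks) &&
          masks$town_mask[cell$row, cell$col]) {
        rej["town"] <- rej["town"] + 1L
        next
      }
      if (near_sighting(idx, sightings, spec$min_sighting_dist,
                        cand$x, cand$y)) {
        rej["sighting"] <- rej["sighting"] + 1L
        next
      }
      ax <- c(ax, cand$x); ay <- c(ay, cand$y)
      cls <- c(cls, raster$grid[cell$row, cell$col])
    }
    if (length(ax) < n) {
      binding <- names(rej)[which.max(rej)]
      stop(sprintf(paste0(
        "candidate sampling infeasible: %d/%d accepted after %d proposals; ",
        "binding constraint '%s' excluded %.1f%% of proposals"),
        length(ax), n, budget, binding, 100 * max(rej) / tries),
        call. = FALSE)
    }
    out <- labeled_points(ax, ay, label = 0L,
                          source = "pseudoabsence-candidate",
                          id = paste0("a_", seq_len(n)))
    out$landuse <- names(landuse_classes)[cls]
    attr(out, "rejections") <- rej
    out
  })
}

#' Draw negatives from the candidate pool
#'
#' A simple random sample without replacement of `n_draw` candidates.
#'
#' @param candidates Candidate pool from [sample_candidates()].
#' @param n_draw Sample size (<= pool size).
#' @param seed Integer seed.
#' @return Labelled points tibble with `label = 0`.
#' @export
draw_negatives <- function(candidates, n_draw, seed = 1L) {
  if (n_draw > nrow(candidates)) {
    stop("`n_draw` exceeds the candidate pool size", call. = FALSE)
  }
  if (n_draw == 0L) return(candidates[0, ])
  withr::with_seed(seed, {
    candidates[sort(sample.int(nrow(candidates), n_draw)), ]
  })
}

#' Repeated balanced re-draws of the negative class
#'
#' `n_reps` independent draws of `n_draw` candidates, each without
#' replacement within the draw; the repetition across draws (not
#' within-draw replacement) is the mechanism that balances sampling error,
#' and downstream consumers average model results over the replicates.
#'
#' @param candidates Candidate pool.
#' @param n_draw Draw size.
#' @param n_reps Number of replicates (>= 1; default 10).
#' @param seed Integer master seed; replicate `i` uses a sub-seed derived
#'   from `(seed, i)`.
#' @return List of `n_reps` labelled-points tibbles.
#' @export
balanced_resample <- function(candidates, n_draw, n_reps = 10L, seed = 1L) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(i) {
    draw_negatives(candidates, n_draw, seed = derive_seed(seed, paste0("rep", i)))
  })
}
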