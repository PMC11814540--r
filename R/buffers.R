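#' Circular and annular buffer specifications
#'
#' A buffer is the half-open annulus `inner <= d < outer` around a point
#' (`inner = 0` gives a disc). The half-open convention makes neighbouring
#' rings an exact partition of the enclosing disc: per class,
#' `disc(0, r2) = disc(0, r1) + ring(r1, r2)` cell for cell.
#'
#' @param inner Inner radius in metres (0 for a disc).
#' @param outer Outer radius in metres (> `inner`).
#' @return A `buffer_spec` list.
#' @export
buffer_spec <- function(inner, outer) {
  if (!(inner >= 0 && outer > inner)) {
    stop("need 0 <= inner < outer", call. = FALSE)
  }
  structure(list(inner = as.numeric(inner), outer = as.numeric(outer)),
            class = "buffer_spec")
}

#' @rdname buffer_spec
#' @param x A `buffer_spec`.
#' @param ... Unused.
#' @export
format.buffer_spec <- function(x, ...) {
  if (x$inner == 0) sprintf("disc_%gkm", x$outer / 1000)
  else sprintf("ring_%g-%gkm", x$inner / 1000, x$outer / 1000)
}

#' @export
print.buffer_spec <- function(x, ...) {
  cat("<buffer_spec>", format(x), "\n")
  invisible(x)
}

#' Default buffer radius sweep
#'
#' The thirteen disc radii of the multi-scale analysis: 0.5, 1, 2, ..., 10,
#' 15 and 20 km.
#'
#' @return Numeric vector of radii in metres.
#' @export
default_radii_m <- function() {
  c(500, 1000, 2000, 3000, 4000, 5000, 6000, 7000,
    8000, 9000, 10000, 15000, 20000)
}

#' @rdname default_radii_m
#' @param radii Radii in metres.
#' @return `disc_specs()`: a list of disc [buffer_spec()]s.
#' @export
disc_specs <- function(radii = default_radii_m()) {
  lapply(radii, function(r) buffer_spec(0, r))
}

# Count cells per annulus per class around one point. `edges` is an
# increasing vector of radii; ring j is [edges[j], edges[j+1]). Membership is
# by cell centre. Returns a (length(edges)-1) x 8 count matrix; attribute
# "covered" holds the in-grid non-nodata cell count per ring, attribute
# "ingrid" the in-grid cell count (nodata included).
buffer_class_counts <- function(raster, x, y, edges) {
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  cs <- raster$cell_size
  k <- length(edges) - 1L
  rmax <- edges[k + 1L]
  cells <- point_cell(raster, x, y)
  span <- ceiling(rmax / cs) + 1L
  # window rows/cols even if the point's own cell is outside the grid
  ctr_row <- (raster$origin[2] - y) / cs + 0.5
  ctr_col <- (x - raster$origin[1]) / cs + 0.5
  i0 <- max(1L, floor(ctr_row - span)); i1 <- min(nr, ceiling(ctr_row + span))
  j0 <- max(1L, floor(ctr_col - span)); j1 <- min(nc, ceiling(ctr_col + span))
  out <- matrix(0L, k, 8L,
                dimnames = list(NULL, names(landuse_classes)))
  covered <- integer(k); ingrid <- integer(k)
  if (i0 <= i1 && j0 <= j1) {
    dy2 <- (cell_center_y(raster, i0:i1) - y)^2
    dx2 <- (cell_center_x(raster, j0:j1) - x)^2
    d <- sqrt(outer(dy2, dx2, "+"))
    ring <- findInterval(d, edges, left.open = FALSE)
    ring[d >= rmax] <- 0L  # beyond the outermost edge
    codes <- raster$grid[i0:i1, j0:j1]
    sel <- ring >= 1L
    ingrid <- tabulate(ring[sel], nbins = k)
    seldata <- sel & codes > 0L
    if (any(seldata)) {
      counts <- tabulate((ring[seldata] - 1L) * 8L + codes[seldata],
                         nbins = 8L * k)
      out <- matrix(counts, k, 8L, byrow = TRUE,
                    dimnames = list(NULL, names(landuse_classes)))
    }
    covered <- as.integer(rowSums(out))
  }
  attr(out, "covered") <- covered
  attr(out, "ingrid") <- ingrid
  out
}

#' Land-use class areas inside one buffer
#'
#' Area of class *k* is the number of cells of that class whose centre `c`
#' satisfies `inner <= dist(c, point) < outer`, times the cell area. Buffers
#' may overhang the domain edge; the overhang contributes nothing and its
#' fraction of the ideal annulus area is attached as attribute
#' `"overhang_fraction"`.
#'
#' @param raster A [landuse_raster()].
#' @param point Numeric length-2 `(x, y)` in metres, inside the raster extent.
#' @param spec A [buffer_spec()].
#' @return Named numeric length-8 vector of areas in square metres.
#' @export
extract_buffer_areas <- function(raster, point, spec) {
  stopifnot(inherits(spec, "buffer_spec"))
  if (!point_in_extent(raster, point[1], point[2])) {
    stop("point lies outside the raster extent", call. = FALSE)
  }
  counts <- buffer_class_counts(raster, point[1], point[2],
                                c(spec$inner, spec$outer))
  areas <- counts[1, ] * raster$cell_size^2
  ideal <- pi * (spec$outer^2 - spec$inner^2)
  covered_area <- attr(counts, "ingrid")[1] * raster$cell_size^2
  attr(areas, "overhang_fraction") <- max(0, 1 - covered_area / ideal)
  areas
}

#' Build the point-by-buffer feature table
#'
#' One row per (point, buffer spec): the eight class areas in square metres
#' plus the per-row Shannon diversity index. Rows are ordered by input point
#' order, then by spec outer (then inner) radius. Points whose overhang at
#' the largest spec exceeds 50% are flagged in the `edge_flag` column.
#'
#' @param raster A [landuse_raster()].
#' @param points Labelled points tibble (`id`, `x`, `y`, `label`).
#' @param specs List of [buffer_spec()]s.
#' @return A tibble with columns `point_id`, `label`, `inner_m`, `outer_m`,
#'   the eight class areas, `shannon` and `edge_flag`.
#' @export
build_feature_table <- function(raster, points, specs) {
  if (nrow(points) == 0L || length(specs) == 0L) {
    stop("need at least one point and one buffer spec", call. = FALSE)
  }
  ord <- order(vapply(specs, `[[`, numeric(1), "outer"),
               vapply(specs, `[[`, numeric(1), "inner"))
  specs <- specs[ord]
  edges <- sort(unique(c(
    vapply(specs, `[[`, numeric(1), "inner"),
    vapply(specs, `[[`, numeric(1), "outer")
  )))
  spec_lo <- vapply(specs, function(s) match(s$inner, edges), integer(1))
  spec_hi <- vapply(specs, function(s) match(s$outer, edges) - 1L, integer(1))
  ns <- length(specs)
  np <- nrow(points)
  rows <- vector("list", np)
  all_zero <- FALSE
  for (i in seq_len(np)) {
    if (!point_in_extent(raster, points$x[i], points$y[i])) {
      stop(sprintf("point '%s' lies outside the raster extent", points$id[i]),
           call. = FALSE)
    }
    counts <- buffer_class_counts(raster, points$x[i], points$y[i], edges)
    ingrid <- attr(counts, "ingrid")
    areas <- matrix(0, ns, 8L)
    overh <- numeric(ns)
    for (s in seq_len(ns)) {
      rng <- spec_lo[s]:spec_hi[s]
      areas[s, ] <- colSums(counts[rng, , drop = FALSE]) * raster$cell_size^2
      ideal <- pi * (specs[[s]]$outer^2 - specs[[s]]$inner^2)
      overh[s] <- max(0, 1 - sum(ingrid[rng]) * raster$cell_size^2 / ideal)
    }
    shan <- apply(areas, 1L, function(a) {
      if (sum(a) <= 0) NA_real_ else shannon_index(a)
    })
    if (anyNA(shan)) all_zero <- TRUE
    rows[[i]] <- tibble::tibble(
      point_id = points$id[i],
      label = rep(points$label[i], ns),
      inner_m = vapply(specs, `[[`, numeric(1), "inner"),
      outer_m = vapply(specs, `[[`, numeric(1), "outer"),
      tibble::as_tibble(stats::setNames(as.data.frame(areas),
                                        names(landuse_classes))),
      shannon = shan,
      edge_flag = overh[ns] > 0.5
    )
  }
  if (all_zero) {
    warning("some buffers contain no data cells; their areas are 0 and ",
            "shannon is NA", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Shannon diversity index of a class-area vector
#'
#' `H = -sum(p_k log p_k)` over the classes with positive area, where
#' `p_k = area_k / sum(areas)`. Natural logarithm (nats) by default, so
#' `0 <= H <= log(8)` for eight classes.
#'
#' @param areas Non-negative numeric vector of class areas; must not be all
#'   zero.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return The diversity index, a single number.
#' @export
shannon_index <- function(areas, base = exp(1)) {
  if (any(areas < 0) || anyNA(areas)) {
    stop("`areas` must be non-negative and complete", call. = FALSE)
  }
  tot <- sum(areas)
  if (tot <= 0) stop("Shannon index undefined for an all-zero area vector",
                     call. = FALSE)
  p <- areas[areas > 0] / tot
  -sum(p * log(p, base = base))
}

#' Persist a feature table as CSV
#'
#' Areas are written in square metres with two decimals, matching the
#' documented long format.
#'
#' @param features Feature table from [build_feature_table()].
#' @param path File path.
#' @export
write_features_csv <- function(features, path) {
  out <- features
  for (nm in names(landuse_classes)) out[[nm]] <- round(out[[nm]], 2)
  out$shannon <- round(out$shannon, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
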