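#' Land-use class legend
#'
#' The eight land-use classes used throughout the package, in legend order.
#' Grid cells carry the integer codes 1--8; 0 marks nodata.
#'
#' @format Named integer vector mapping class name to code.
#' @export
landuse_classes <- c(
  cropland = 1L, forest = 2L, shrub = 3L, grassland = 4L,
  water = 5L, barren = 6L, impervious = 7L, wetland = 8L
)

#' Construct a categorical land-use raster
#'
#' A minimal planar raster: an integer matrix of class codes plus cell size
#' and the planar coordinates of the top-left corner. All geometry in the
#' package is planar metres; there is no geodesy.
#'
#' @param grid Integer matrix of codes in `0:8` (0 = nodata). Row 1 is the
#'   top of the domain.
#' @param cell_size Cell side length in metres (> 0).
#' @param origin Numeric length-2, planar metres `(x0, y0)` of the top-left
#'   cell corner. `x` increases to the right, `y` decreases downwards.
#' @return An object of class `landuse_raster`.
#' @export
landuse_raster <- function(grid, cell_size, origin = c(0, 0)) {
  if (!is.matrix(grid) || nrow(grid) < 1L || ncol(grid) < 1L) {
    stop("`grid` must be a matrix with positive extent", call. = FALSE)
  }
  storage.mode(grid) <- "integer"
  if (anyNA(grid) || any(grid < 0L | grid > 8L)) {
    stop("grid codes must all lie in 0..8 (0 = nodata)", call. = FALSE)
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number (metres)", call. = FALSE)
  }
  structure(
    list(grid = grid, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "landuse_raster"
  )
}

#' @export
print.landuse_raster <- function(x, ...) {
  prop <- raster_class_proportions(x)
  cat(sprintf("<landuse_raster> %d x %d cells, %g m cells (%.1f x %.1f km)\n",
              nrow(x$grid), ncol(x$grid), x$cell_size,
              ncol(x$grid) * x$cell_size / 1000,
              nrow(x$grid) * x$cell_size / 1000))
  cat("class proportions (of non-nodata cells):\n")
  print(round(prop, 3))
  invisible(x)
}

#' Realised class proportions of a raster
#'
#' @param raster A [landuse_raster()].
#' @return Named numeric vector over the eight classes, proportions of
#'   non-nodata cells (all zero if the raster is entirely nodata).
#' @export
raster_class_proportions <- function(raster) {
  stopifnot(inherits(raster, "landuse_raster"))
  counts <- tabulate(raster$grid, nbins = 8L)
  total <- sum(counts)
  p <- if (total > 0) counts / total else rep(0, 8)
  stats::setNames(p, names(landuse_classes))
}

# planar coordinates of cell centers for row/col index vectors
cell_center_x <- function(raster, col) raster$origin[1] + (col - 0.5) * raster$cell_size
cell_center_y <- function(raster, row) raster$origin[2] - (row - 0.5) * raster$cell_size

# row/col of the cell containing planar point (x, y); NA outside the grid
point_cell <- function(raster, x, y) {
  col <- floor((x - raster$origin[1]) / raster$cell_size) + 1
  row <- floor((raster$origin[2] - y) / raster$cell_size) + 1
  bad <- col < 1 | col > ncol(raster$grid) | row < 1 | row > nrow(raster$grid)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

point_in_extent <- function(raster, x, y) {
  x0 <- raster$origin[1]; y0 <- raster$origin[2]
  x >= x0 & x <= x0 + ncol(raster$grid) * raster$cell_size &
    y <= y0 & y >= y0 - nrow(raster$grid) * raster$cell_size
}

#' Write / read a raster as a plain-text grid
#'
#' Three header lines (`nrows ncols`, `cell_size`, `origin x y`) followed by
#' one whitespace-separated row of integer codes per grid row. Lossless for
#' this container and diff-friendly.
#'
#' @param raster A [landuse_raster()].
#' @param path File path.
#' @return `write_raster_txt()` returns `path` invisibly; `read_raster_txt()`
#'   returns a [landuse_raster()].
#' @export
write_raster_txt <- function(raster, path) {
  stopifnot(inherits(raster, "landuse_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("nrows %d ncols %d", nrow(raster$grid), ncol(raster$grid)),
    sprintf("cell_size %.10g", raster$cell_size),
    sprintf("origin %.10g %.10g", raster$origin[1], raster$origin[2])
  ), con)
  utils::write.table(raster$grid, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster_txt
#' @export
read_raster_txt <- function(path) {
  header <- readLines(path, n = 3L)
  dims <- as.integer(strsplit(header[1], "\\s+")[[1]][c(2, 4)])
  cell <- as.numeric(strsplit(header[2], "\\s+")[[1]][2])
  orig <- as.numeric(strsplit(header[3], "\\s+")[[1]][2:3])
  grid <- as.matrix(utils::read.table(path, skip = 3L))
  dimnames(grid) <- NULL
  stopifnot(nrow(grid) == dims[1], ncol(grid) == dims[2])
  landuse_raster(grid, cell, orig)
}

#' Labelled point sets
#'
#' Points are kept as a tibble with columns `id`, `x`, `y`, `label`
#' (`1` presence, `0` pseudoabsence, `"sighting"`) and `source`. These helpers
#' build and round-trip that layout.
#'
#' @param x,y Planar coordinates in metres.
#' @param label Point labels (recycled).
#' @param source Provenance tag (recycled).
#' @param id Optional ids; defaults to `1:n` prefixed by label.
#' @return A tibble of labelled points.
#' @export
labeled_points <- function(x, y, label, source = "heronscape", id = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(id)) id <- paste0(rep_len(as.character(label), n), "_", seq_len(n))
  if (anyDuplicated(id)) stop("point ids must be unique", call. = FALSE)
  tibble::tibble(
    id = as.character(id), x = as.numeric(x), y = as.numeric(y),
    label = rep_len(label, n), source = rep_len(as.character(source), n)
  )
}

#' @rdname labeled_points
#' @param points A labelled-points tibble.
#' @param path File path.
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname labeled_points
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' @rdname labeled_points
#' @export
write_points_geojson <- function(points, path) {
  features <- lapply(seq_len(nrow(points)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x[i], points$y[i])),
      properties = list(id = points$id[i],
                        label = as.character(points$label[i]),
                        source = points$source[i])
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
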