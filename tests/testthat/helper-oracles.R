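# Independent brute-force oracles. These deliberately use the slowest,
# most literal formulation of each quantity and share no code with the
# package implementation they check.

# all-cells double loop, cell-centre membership in [inner, outer)
oracle_buffer_areas <- function(raster, point, inner, outer) {
  areas <- stats::setNames(numeric(8), names(landuse_classes))
  cs <- raster$cell_size
  for (i in seq_len(nrow(raster$grid))) {
    for (j in seq_len(ncol(raster$grid))) {
      code <- raster$grid[i, j]
      if (code == 0L) next
      cx <- raster$origin[1] + (j - 0.5) * cs
      cy <- raster$origin[2] - (i - 0.5) * cs
      d <- sqrt((cx - point[1])^2 + (cy - point[2])^2)
      if (d >= inner && d < outer) areas[code] <- areas[code] + cs^2
    }
  }
  areas
}

# two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# pairwise U for the first group
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) u <- u + 1 else if (xi == yj) u <- u + 0.5
  }
  u
}

# count of cells whose centre is within `band` metres of the domain edge
oracle_border_count <- function(raster, band) {
  cs <- raster$cell_size
  nr <- nrow(raster$grid); nc <- ncol(raster$grid)
  w <- nc * cs; h <- nr * cs
  n <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      cx <- (j - 0.5) * cs
      cy <- (i - 0.5) * cs
      if (min(cx, w - cx, cy, h - cy) < band) n <- n + 1L
    }
  }
  n
}
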