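#' Mann--Whitney U test
#'
#' The statistic is the pair count for the first group,
#' `U = sum over (i, j) of [x_i > y_j] + 0.5 * [x_i == y_j]`, so
#' `U + U' = n1 * n2`. For `n1 + n2 <= 12` the two-sided p-value is computed
#' by exact enumeration of all group assignments of the combined sample
#' (ties handled naturally); otherwise by the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return List `U`, `p_value`, `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(xs, ys) {
    d <- outer(xs, ys, "-")
    sum(d > 0) + 0.5 * sum(d == 0)
  }
  u <- u_stat(x, y)
  if (n1 + n2 <= 12L) {
    pooled <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2L, function(ix) u_stat(pooled[ix], pooled[-ix]))
    center <- n1 * n2 / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-9)
    return(list(U = u, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  r <- rank(c(x, y))
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "normal"))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-max(z, 0))
  list(U = u, p_value = min(p, 1), method = "normal")
}

#' Shapiro--Wilk normality check
#'
#' Thin, argument-checked wrapper used as the gate in
#' [compare_diversity()].
#'
#' @param values Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return List `W`, `p_value`.
#' @export
normality_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop("normality test needs 3 <= n <= 5000 finite values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    stop("normality test undefined for a constant sample", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' Compare landscape diversity between presences and pseudoabsences
#'
#' Normality-gated two-sample comparison of Shannon indices: if both groups
#' pass the Shapiro--Wilk gate at `alpha_normality`, a Welch two-sample
#' t-test is used; otherwise the Mann--Whitney U test. Constant
#' (degenerate) groups fall through to Mann--Whitney with a warning. Tests
#' are two-sided; `direction` reports which group is the more diverse
#' (by mean on the t path, by median on the U path).
#'
#' @param shannon_presence,shannon_absence Numeric vectors of per-point
#'   Shannon indices (>= 3 values each).
#' @param alpha_normality Gate level (default 0.05).
#' @return A `diversity_test` list: `test_used` (`"t"`/`"mann_whitney"`),
#'   `statistic`, `p_value`, `direction`, group means and medians, and the
#'   gate p-values.
#' @export
compare_diversity <- function(shannon_presence, shannon_absence,
                              alpha_normality = 0.05) {
  xp <- shannon_presence[is.finite(shannon_presence)]
  xa <- shannon_absence[is.finite(shannon_absence)]
  if (length(xp) < 3L || length(xa) < 3L) {
    stop("need at least 3 finite values per group", call. = FALSE)
  }
  degenerate <- stats::sd(xp) == 0 || stats::sd(xa) == 0
  if (degenerate) {
    warning("constant group supplied; falling back to Mann-Whitney",
            call. = FALSE)
    gate_p <- c(NA_real_, NA_real_)
    normal <- FALSE
  } else {
    gate_p <- c(normality_test(xp)$p_value, normality_test(xa)$p_value)
    normal <- all(gate_p > alpha_normality)
  }
  if (normal) {
    tt <- stats::t.test(xp, xa)  # Welch
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    used <- "t"
    direction <- if (mean(xp) > mean(xa)) "presence"
                 else if (mean(xp) < mean(xa)) "absence" else "none"
  } else {
    mw <- mann_whitney_u(xp, xa)
    statistic <- mw$U
    p <- mw$p_value
    used <- "mann_whitney"
    mp <- stats::median(xp); ma <- stats::median(xa)
    direction <- if (mp > ma) "presence" else if (mp < ma) "absence" else "none"
  }
  structure(list(
    test_used = used, statistic = statistic, p_value = p,
    direction = direction,
    mean_presence = mean(xp), mean_absence = mean(xa),
    median_presence = stats::median(xp), median_absence = stats::median(xa),
    normality_p = gate_p
  ), class = "diversity_test")
}

#' @export
print.diversity_test <- function(x, ...) {
  cat(sprintf("<diversity_test> %s: statistic %.4g, p %.4g (%s more diverse)\n",
              x$test_used, x$statistic, x$p_value, x$direction))
  invisible(x)
}

#' Per-scale diversity test table
#'
#' Runs [compare_diversity()] at every buffer spec of a feature table,
#' comparing presence (`label == 1`) against pseudoabsence (`label == 0`)
#' Shannon indices.
#'
#' @param features Feature table with a `shannon` column.
#' @param alpha_normality Gate level passed through.
#' @return Tibble `scale`, `inner_m`, `outer_m`, `statistic`, `p`,
#'   `test_used`, `direction`.
#' @export
diversity_by_scale <- function(features, alpha_normality = 0.05) {
  key <- unique(features[, c("inner_m", "outer_m")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    sub <- features[features$inner_m == key$inner_m[i] &
                      features$outer_m == key$outer_m[i], ]
    res <- compare_diversity(sub$shannon[sub$label == 1L],
                             sub$shannon[sub$label == 0L],
                             alpha_normality)
    tibble::tibble(
      scale = format(buffer_spec(key$inner_m[i], key$outer_m[i])),
      inner_m = key$inner_m[i], outer_m = key$outer_m[i],
      statistic = res$statistic, p = res$p_value,
      test_used = res$test_used, direction = res$direction
    )
  })
  do.call(rbind, rows)
}

#' NMDS ordination of buffer land-use composition
#'
#' Nonmetric multidimensional scaling (via [vegan::metaMDS()]) of the
#' Bray--Curtis dissimilarities between row-normalised class-area
#' proportions, from multiple random starts. Stress is monotone-regression
#' stress-1 in `[0, 1]`; by the usual rule of thumb a configuration with
#' stress below 0.2 is considered interpretable.
#'
#' @param features Feature table restricted to one scale (or any tibble with
#'   the eight class-area columns; rows with zero total area are dropped with
#'   a warning).
#' @param n_dims Ordination dimensionality (default 2).
#' @param seed Integer seed for the random starts.
#' @param trymax Maximum random starts (default 20).
#' @return An `ordination` list: `points` (n x `n_dims` coordinates),
#'   `stress`, `dissimilarity = "bray"`, `converged`.
#' @export
nmds_ordination <- function(features, n_dims = 2L, seed = 1L, trymax = 20L) {
  m <- as.matrix(as.data.frame(features)[, names(landuse_classes)])
  tot <- rowSums(m)
  if (any(tot <= 0)) {
    warning("dropping rows with zero total area", call. = FALSE)
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (nrow(m) < 4L) stop("need at least 4 points with data", call. = FALSE)
  prop <- m / tot
  if (max(stats::dist(prop)) == 0) {
    stop("all rows identical: dissimilarities are degenerate", call. = FALSE)
  }
  fit <- withr::with_seed(seed, {
    vegan::metaMDS(prop, distance = "bray", k = n_dims, trymax = trymax,
                   autotransform = FALSE, trace = 0, wascores = FALSE)
  })
  structure(list(
    points = fit$points, stress = fit$stress,
    dissimilarity = "bray", converged = isTRUE(fit$converged)
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> NMDS (%s), %d points, stress %.3f%s\n",
              x$dissimilarity, nrow(x$points), x$stress,
              if (x$converged) ", converged" else ""))
  invisible(x)
}
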