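#' Random-forest ensemble configuration
#'
#' Each scale is modelled by `n_models` independently seeded random forests
#' of `n_trees` trees on the eight class-area features of that scale alone.
#' With `sampling = "subsample70"` every tree is grown on a 70% row
#' subsample drawn without replacement, so each tree's out-of-bag (OOB) set
#' is exactly 30% of the samples; `sampling = "bootstrap"` restores the
#' classic bootstrap (~36.8% OOB).
#'
#' @param n_trees Trees per forest (default 500).
#' @param n_models Forests per scale (default 100).
#' @param oob_fraction Fraction of rows held out per tree (default 0.30).
#' @param sampling `"subsample70"` (without replacement, default) or
#'   `"bootstrap"`.
#' @param importance `"permutation"` (OOB mean decrease in accuracy,
#'   default) or `"impurity"`.
#' @param seed Integer master seed; forest `i` is seeded from `(seed, i)`.
#' @return A `model_config` list.
#' @export
model_config <- function(n_trees = 500L, n_models = 100L,
                         oob_fraction = 0.30,
                         sampling = c("subsample70", "bootstrap"),
                         importance = c("permutation", "impurity"),
                         seed = 1L) {
  sampling <- match.arg(sampling)
  importance <- match.arg(importance)
  stopifnot(n_trees >= 1, n_models >= 1,
            oob_fraction > 0, oob_fraction < 1)
  structure(list(n_trees = as.integer(n_trees),
                 n_models = as.integer(n_models),
                 oob_fraction = oob_fraction, sampling = sampling,
                 importance = importance, seed = as.integer(seed)),
            class = "model_config")
}

# rows of the feature table for one buffer spec, as a modelling frame
spec_frame <- function(features, spec) {
  rows <- features$inner_m == spec$inner & features$outer_m == spec$outer
  if (!any(rows)) {
    stop(sprintf("feature table has no rows for %s", format(spec)),
         call. = FALSE)
  }
  df <- as.data.frame(features[rows, c("label", names(landuse_classes))])
  df$label <- factor(df$label, levels = c(0L, 1L))
  attr(df, "point_id") <- features$point_id[rows]
  df
}

#' Fit the per-scale random-forest ensemble
#'
#' Fits `n_models` forests on the eight class-area features of one buffer
#' spec; per-repeat accuracy is `1 -` the OOB misclassification rate under
#' majority vote. The repeat with the highest accuracy (first among ties)
#' supplies the reported variable importances, normalised to sum to 1.
#'
#' @param features Feature table from [build_feature_table()], or a data
#'   frame already restricted to one spec (columns `label` + class areas),
#'   in which case `spec` may be `NULL`.
#' @param spec A [buffer_spec()] identifying the rows to model.
#' @param config A [model_config()].
#' @return A `scale_ensemble` list: `spec`, `accuracies` (length
#'   `n_models`), `max`/`mean`/`min`, `best_index`, `importances`
#'   (raw, per repeat = best only), `best_importances` (normalised
#'   8-vector), `seeds`.
#' @export
fit_scale_ensemble <- function(features, spec = NULL,
                               config = model_config()) {
  df <- if (!is.null(spec)) spec_frame(features, spec) else {
    d <- as.data.frame(features)
    d$label <- factor(d$label, levels = c(0L, 1L))
    d
  }
  tab <- table(df$label)
  if (any(tab == 0L)) stop("both classes must be present", call. = FALSE)
  if (any(tab < 10L)) stop("need at least 10 rows per class", call. = FALSE)
  seeds <- vapply(seq_len(config$n_models),
                  function(i) derive_seed(config$seed, paste0("model", i)),
                  numeric(1))
  replace <- config$sampling == "bootstrap"
  frac <- if (replace) 1 else 1 - config$oob_fraction
  fit_one <- function(i, importance) {
    ranger::ranger(
      dependent.variable.name = "label", data = df,
      num.trees = config$n_trees,
      replace = replace, sample.fraction = frac,
      importance = importance,
      seed = seeds[i], num.threads = 1L,
      respect.unordered.factors = FALSE, verbose = FALSE
    )
  }
  acc <- vapply(seq_len(config$n_models),
                function(i) 1 - fit_one(i, "none")$prediction.error,
                numeric(1))
  best <- which.max(acc)  # first among ties
  # same seed => identical forest; refit only the best repeat with importance
  raw_imp <- ranger::importance(fit_one(best, config$importance))
  imp <- pmax(raw_imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / length(imp), length(imp)), names(raw_imp))
  structure(list(
    spec = spec, accuracies = acc,
    max = max(acc), mean = mean(acc), min = min(acc),
    best_index = best, best_importances = imp,
    raw_best_importances = raw_imp, seeds = seeds,
    n = nrow(df)
  ), class = "scale_ensemble")
}

#' @export
print.scale_ensemble <- function(x, ...) {
  lab <- if (is.null(x$spec)) "custom frame" else format(x$spec)
  cat(sprintf("<scale_ensemble> %s: mean acc %.3f (min %.3f, max %.3f) over %d models\n",
              lab, x$mean, x$min, x$max, length(x$accuracies)))
  invisible(x)
}

#' Summarise accuracy across scales
#'
#' One row per ensemble with maximum, mean and minimum OOB accuracy; the
#' scale of effect is the spec with the highest mean accuracy (ties broken
#' towards the smallest outer radius and reported in the `tie` attribute).
#'
#' @param results List of `scale_ensemble` objects.
#' @return A tibble `scale`, `inner_m`, `outer_m`, `max_acc`, `mean_acc`,
#'   `min_acc` with attributes `best` (row index of the argmax) and `tie`.
#' @export
summarize_scales <- function(results) {
  if (length(results) == 0L) stop("no ensembles to summarise", call. = FALSE)
  tb <- tibble::tibble(
    scale = vapply(results, function(r) format(r$spec), character(1)),
    inner_m = vapply(results, function(r) r$spec$inner, numeric(1)),
    outer_m = vapply(results, function(r) r$spec$outer, numeric(1)),
    max_acc = vapply(results, `[[`, numeric(1), "max"),
    mean_acc = vapply(results, `[[`, numeric(1), "mean"),
    min_acc = vapply(results, `[[`, numeric(1), "min")
  )
  top <- max(tb$mean_acc)
  cand <- which(tb$mean_acc == top)
  best <- cand[which.min(tb$outer_m[cand])]
  attr(tb, "best") <- best
  attr(tb, "tie") <- length(cand) > 1L
  tb
}

#' Variable importance of the best repeat
#'
#' Importances of the single highest-accuracy repeat of an ensemble,
#' normalised to sum to 1 and ranked, with class names in legend order.
#'
#' @param result A `scale_ensemble`.
#' @return A tibble `variable`, `importance`, `rank` sorted by rank.
#' @export
variable_importance <- function(result) {
  if (!inherits(result, "scale_ensemble")) {
    stop("`result` must be a fitted scale_ensemble", call. = FALSE)
  }
  imp <- result$best_importances
  tb <- tibble::tibble(
    variable = names(imp),
    importance = as.numeric(imp)
  )
  tb$rank <- rank(-tb$importance, ties.method = "first")
  tb[order(tb$rank), ]
}

#' Pearson correlation matrix of the class-area features at one scale
#'
#' @param features Feature table, restricted via `spec` (or a plain data
#'   frame of the eight area columns if `spec` is `NULL`).
#' @param spec A [buffer_spec()], optional as in [fit_scale_ensemble()].
#' @return 8x8 symmetric correlation matrix; unit diagonal; entries
#'   involving a zero-variance column are `NA`.
#' @export
pearson_matrix <- function(features, spec = NULL) {
  m <- if (!is.null(spec)) {
    as.matrix(spec_frame(features, spec)[, names(landuse_classes)])
  } else {
    as.matrix(as.data.frame(features)[, names(landuse_classes)])
  }
  if (nrow(m) < 3L) stop("need at least 3 rows", call. = FALSE)
  r <- suppressWarnings(stats::cor(m))
  degenerate <- apply(m, 2L, stats::sd) == 0
  r[degenerate, ] <- NA_real_
  r[, degenerate] <- NA_real_
  diag(r)[!degenerate] <- 1
  r
}
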