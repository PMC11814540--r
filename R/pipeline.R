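#' Derive a stage seed from a master seed
#'
#' Deterministic 31-bit hash of `(master_seed, label)`; adding a new stage
#' never perturbs another stage's random stream.
#'
#' @param master_seed Integer master seed.
#' @param label Character stage label.
#' @return An integer seed in `[1, 2^31 - 20)`.
#' @export
derive_seed <- function(master_seed, label) {
  m <- 2147483629
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(as.character(label))) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

#' Default pipeline configuration
#'
#' A demonstration-scale configuration of every stage: a 256 x 256 cell
#' landscape of 100 m cells (25.6 km on a side), a planted water preference
#' at 1 km, reduced ensembles, and the full 13-radius sweep. All values can
#' be overridden from a YAML file via [validate_config()].
#'
#' @return A nested `pipeline_config` list.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    landscape = list(
      n_rows = 256L, n_cols = 256L, cell_size = 100,
      class_mix = unname(default_class_mix()),
      patchiness = 500,
      town_count = 4L, town_radius = 1200
    ),
    presence = list(
      n_points = 60L, min_spacing = 1500,
      focal_class = "water", focal_radius = 1000,
      strength = 5, baseline_rate = 0.5
    ),
    sightings = list(n_sightings = 150L),
    pseudoabsence = list(
      min_sighting_dist = 500, border_dist = 2000,
      avoid_towns = TRUE, n_candidates = 500L, n_draw = 60L,
      n_reps = 10L
    ),
    features = list(radii_m = default_radii_m()),
    model = list(
      n_trees = 100L, n_models = 20L, oob_fraction = 0.30,
      sampling = "subsample70", importance = "permutation"
    ),
    screen = list(
      deletion_counts = c(1L, 5L, 10L, 25L, 50L), reps_per_k = 5L,
      rings_m = list(c(1000, 2000), c(6000, 8000)),
      enabled = TRUE
    ),
    stats = list(alpha_normality = 0.05, nmds_radius_m = 1000)
  ), class = "pipeline_config")
}

#' Study-scale pipeline configuration
#'
#' The full synthetic study conditions: a 512 x 512 cell landscape of 100 m
#' cells (51.2 km on a side) with a planted water preference at 1 km
#' (selection slope 5), 100 presences against 100 pseudoabsences drawn from
#' a 500-candidate pool, a sighting pool whose exclusion discs remove about
#' a third of the domain (mirroring the sparse-relative-to-domain sighting
#' regime of continental data), and reduced ensembles of 20 forests x 100
#' trees per scale across the 13-radius sweep.
#'
#' @param seed Master seed.
#' @param screen Enable the deletion screen stage (default `FALSE`; the
#'   screen is usually run separately on the annular scales).
#' @return A `pipeline_config`.
#' @export
study_config <- function(seed = 1L, screen = FALSE) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$landscape$n_rows <- 512L
  cfg$landscape$n_cols <- 512L
  cfg$landscape$town_count <- 6L
  cfg$landscape$town_radius <- 1500
  cfg$presence$n_points <- 100L
  cfg$presence$min_spacing <- 2000
  cfg$sightings$n_sightings <- 200L
  cfg$pseudoabsence$min_sighting_dist <- 1000
  cfg$pseudoabsence$border_dist <- 5000
  cfg$pseudoabsence$n_draw <- 100L
  cfg$screen$enabled <- isTRUE(screen)
  cfg
}

config_schema <- function() {
  lapply(default_config(), function(block) {
    if (is.list(block) && !is.null(names(block))) names(block) else NULL
  })
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a nested list), merges it over
#' [default_config()], rejects unknown keys and range-checks every
#' parameter. All problems are reported together.
#'
#' @param config Path to a YAML file, or a nested list of overrides.
#' @return A validated `pipeline_config`; errors list every violation.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  stopifnot(is.list(config))
  base <- unclass(default_config())
  errors <- character(0)
  schema <- config_schema()
  unknown_blocks <- setdiff(names(config), names(base))
  if (length(unknown_blocks)) {
    errors <- c(errors, paste0("unknown config block(s): ",
                               paste(unknown_blocks, collapse = ", ")))
  }
  for (blk in intersect(names(config), names(base))) {
    if (is.null(schema[[blk]])) { base[[blk]] <- config[[blk]]; next }
    unknown <- setdiff(names(config[[blk]]), schema[[blk]])
    if (length(unknown)) {
      errors <- c(errors, paste0("unknown key(s) in '", blk, "': ",
                                 paste(unknown, collapse = ", ")))
    }
    for (key in intersect(names(config[[blk]]), schema[[blk]])) {
      base[[blk]][[key]] <- config[[blk]][[key]]
    }
  }
  cfg <- base
  # normalise YAML-style nested lists to plain vectors
  cfg$landscape$class_mix <- as.numeric(unlist(cfg$landscape$class_mix))
  cfg$features$radii_m <- as.numeric(unlist(cfg$features$radii_m))
  cfg$screen$deletion_counts <- as.integer(unlist(cfg$screen$deletion_counts))
  cfg$screen$rings_m <- lapply(cfg$screen$rings_m,
                               function(r) as.numeric(unlist(r)))
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1,
      "'seed' must be a single integer")
  chk(cfg$landscape$n_rows >= 16 && cfg$landscape$n_cols >= 16,
      "'landscape': grid must be at least 16 x 16")
  chk(length(cfg$landscape$class_mix) == 8 &&
        abs(sum(cfg$landscape$class_mix) - 1) < 1e-9 &&
        all(cfg$landscape$class_mix >= 0),
      "'landscape$class_mix' must be 8 proportions summing to 1")
  chk(cfg$landscape$patchiness >= cfg$landscape$cell_size,
      "'landscape$patchiness' must be >= cell_size")
  chk(cfg$presence$n_points >= 1, "'presence$n_points' must be >= 1")
  chk(cfg$presence$strength >= 0, "'presence$strength' must be >= 0")
  chk(cfg$pseudoabsence$n_draw <= cfg$pseudoabsence$n_candidates,
      "'pseudoabsence': n_draw must be <= n_candidates")
  chk(cfg$pseudoabsence$border_dist <
        min(cfg$landscape$n_rows, cfg$landscape$n_cols) *
        cfg$landscape$cell_size / 2,
      "'pseudoabsence$border_dist' exhausts the domain")
  chk(all(unlist(cfg$features$radii_m) > 0),
      "'features$radii_m' must be positive radii in metres")
  chk(cfg$model$n_trees >= 1 && cfg$model$n_models >= 1,
      "'model': n_trees and n_models must be >= 1")
  chk(cfg$model$oob_fraction > 0 && cfg$model$oob_fraction < 1,
      "'model$oob_fraction' must be in (0, 1)")
  chk(all(unlist(cfg$screen$deletion_counts) <= 50),
      "'screen$deletion_counts' must not exceed 50")
  chk(cfg$stats$nmds_radius_m %in% cfg$features$radii_m,
      "'stats$nmds_radius_m' must be one of features$radii_m")
  if (length(errors)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' One call from synthetic landscape to report: simulate the landscape,
#' masks, sighting pool and presences; sample constrained pseudoabsences;
#' extract multi-scale buffer features; fit per-scale random-forest
#' ensembles and pick the scale of effect; run the deletion-based outlier
#' screen on the configured annular scales; and compare landscape diversity
#' between the classes, with an NMDS ordination. Every stage seed is derived
#' from the master seed, so the run (and every CSV it writes) is a pure
#' function of the configuration.
#'
#' @param config A `pipeline_config` (see [validate_config()]).
#' @param out_dir Output directory (created if needed); `NULL` writes no
#'   files.
#' @return A `run_report` list with per-stage status, the file manifest and
#'   the headline results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  manifest <- character(0)
  emit <- function(writer, obj, name) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, name)
    writer(obj, path)
    manifest <<- c(manifest, name)
  }
  stage_status <- list()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste0("FAILED at stage '", name, "': ",
                          conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    stage_status[[name]] <<- "ok"
    res
  }

  ## simulate ----------------------------------------------------------
  sim <- run_stage("simulate", {
    ls_cfg <- cfg$landscape
    raster <- generate_landscape(
      ls_cfg$n_rows, ls_cfg$n_cols, ls_cfg$cell_size,
      class_mix = ls_cfg$class_mix, patchiness = ls_cfg$patchiness,
      seed = derive_seed(cfg$seed, "landscape")
    )
    masks <- make_masks(raster, border_band = cfg$pseudoabsence$border_dist,
                        town_count = ls_cfg$town_count,
                        town_radius = ls_cfg$town_radius,
                        seed = derive_seed(cfg$seed, "towns"))
    raster <- masks$raster
    sightings <- generate_sighting_pool(
      raster, cfg$sightings$n_sightings,
      seed = derive_seed(cfg$seed, "sightings"))
    pref <- preference_spec(cfg$presence$focal_class,
                            cfg$presence$focal_radius,
                            cfg$presence$strength,
                            cfg$presence$baseline_rate)
    presences <- place_presences(
      raster, pref, cfg$presence$n_points,
      min_spacing = cfg$presence$min_spacing,
      seed = derive_seed(cfg$seed, "presences"),
      exclude = masks$border_mask | masks$town_mask)
    list(raster = raster, masks = masks, sightings = sightings,
         presences = presences, pref = pref)
  })
  emit(write_raster_txt, sim$raster, "landscape.txt")
  emit(write_points_csv, sim$presences, "presences.csv")
  emit(write_points_csv, sim$sightings, "sightings.csv")

  ## pseudoabsence -----------------------------------------------------
  pa <- run_stage("pseudoabs", {
    spec <- constraint_spec(
      min_sighting_dist = cfg$pseudoabsence$min_sighting_dist,
      border_dist = cfg$pseudoabsence$border_dist,
      avoid_towns = cfg$pseudoabsence$avoid_towns,
      n_candidates = cfg$pseudoabsence$n_candidates,
      n_draw = cfg$pseudoabsence$n_draw)
    candidates <- sample_candidates(
      sim$raster, sim$sightings, sim$masks, spec,
      seed = derive_seed(cfg$seed, "candidates"))
    negatives <- draw_negatives(candidates, spec$n_draw,
                                seed = derive_seed(cfg$seed, "negatives"))
    list(spec = spec, candidates = candidates, negatives = negatives)
  })
  emit(write_points_csv, pa$candidates, "candidates.csv")
  emit(write_points_csv, pa$negatives, "negatives.csv")

  ## features ----------------------------------------------------------
  feats <- run_stage("features", {
    specs <- disc_specs(cfg$features$radii_m)
    if (isTRUE(cfg$screen$enabled)) {
      specs <- c(specs, lapply(cfg$screen$rings_m,
                               function(r) buffer_spec(r[1], r[2])))
    }
    pts <- rbind(sim$presences[, c("id", "x", "y", "label", "source")],
                 pa$negatives[, c("id", "x", "y", "label", "source")])
    build_feature_table(sim$raster, pts, specs)
  })
  emit(write_features_csv, feats, "features.csv")

  ## model -------------------------------------------------------------
  mod <- run_stage("model", {
    mcfg <- model_config(cfg$model$n_trees, cfg$model$n_models,
                         cfg$model$oob_fraction, cfg$model$sampling,
                         cfg$model$importance,
                         seed = derive_seed(cfg$seed, "model"))
    specs <- disc_specs(cfg$features$radii_m)
    ensembles <- lapply(specs, function(s) fit_scale_ensemble(feats, s, mcfg))
    summary <- summarize_scales(ensembles)
    best <- attr(summary, "best")
    focus_r <- intersect(c(500, 1000, 6000,
                           ensembles[[best]]$spec$outer),
                         cfg$features$radii_m)
    focus <- match(focus_r, vapply(specs, `[[`, numeric(1), "outer"))
    importance <- do.call(rbind, lapply(focus, function(i) {
      vi <- variable_importance(ensembles[[i]])
      vi$scale <- format(specs[[i]])
      vi[, c("scale", "variable", "importance", "rank")]
    }))
    pearson <- lapply(focus, function(i) pearson_matrix(feats, specs[[i]]))
    names(pearson) <- vapply(focus, function(i) format(specs[[i]]),
                             character(1))
    list(ensembles = ensembles, summary = summary, best = best,
         importance = importance, pearson = pearson, config = mcfg)
  })
  emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
       mod$summary, "scale_summary.csv")
  emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
       mod$importance, "importance.csv")
  for (nm in names(mod$pearson)) {
    emit(function(x, p) utils::write.csv(round(x, 5), p),
         mod$pearson[[nm]], paste0("pearson_", nm, ".csv"))
  }

  ## screen ------------------------------------------------------------
  scr <- if (isTRUE(cfg$screen$enabled)) run_stage("screen", {
    sched <- deletion_schedule(unlist(cfg$screen$deletion_counts),
                               cfg$screen$reps_per_k,
                               seed = derive_seed(cfg$seed, "screen"))
    lapply(cfg$screen$rings_m, function(r) {
      spec <- buffer_spec(r[1], r[2])
      res <- deletion_screen(feats, spec, sched, mod$config)
      list(scale = format(spec), screen = res, trend = trend_test(res))
    })
  }) else NULL
  if (!is.null(scr)) {
    long <- do.call(rbind, lapply(scr, function(s) {
      tab <- s$screen$table
      tibble::tibble(scale = s$scale, k = tab$k, rep = tab$rep,
                     mean_acc = tab$mean_acc,
                     deleted_ids = vapply(tab$deleted_ids, paste,
                                          character(1), collapse = ";"))
    }))
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
         long, "screen.csv")
  }

  ## stats -------------------------------------------------------------
  st <- run_stage("stats", {
    discs <- feats[feats$inner_m == 0, ]
    diversity <- diversity_by_scale(discs, cfg$stats$alpha_normality)
    nm_rows <- discs[discs$outer_m == cfg$stats$nmds_radius_m, ]
    ord <- nmds_ordination(nm_rows, seed = derive_seed(cfg$seed, "nmds"))
    coords <- tibble::tibble(
      point_id = nm_rows$point_id[rowSums(
        as.matrix(nm_rows[, names(landuse_classes)])) > 0],
      tibble::as_tibble(stats::setNames(as.data.frame(ord$points),
                                        paste0("nmds", seq_len(ncol(ord$points)))))
    )
    list(diversity = diversity, ordination = ord, coords = coords)
  })
  emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
       st$diversity, "diversity_tests.csv")
  emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
       st$coords, "nmds_coords.csv")

  ## report ------------------------------------------------------------
  best_row <- mod$summary[mod$best, ]
  best_imp <- mod$importance[mod$importance$scale == best_row$scale, ]
  report <- structure(list(
    package_version = as.character(utils::packageVersion("heronscape")),
    seed = cfg$seed,
    stages = stage_status,
    manifest = manifest,
    headline = list(
      best_scale = best_row$scale,
      best_scale_outer_m = best_row$outer_m,
      best_scale_mean_acc = best_row$mean_acc,
      best_scale_max_acc = best_row$max_acc,
      top_variable_best_scale = best_imp$variable[best_imp$rank == 1],
      diversity_all_significant = all(st$diversity$p < 0.05),
      diversity_max_p = max(st$diversity$p),
      nmds_stress = st$ordination$stress,
      screen = if (is.null(scr)) NULL else lapply(scr, function(s) {
        list(scale = s$scale, delta = s$screen$delta,
             slope = s$trend$slope, slope_p = s$trend$p_value,
             classification = s$trend$classification)
      })
    ),
    config = unclass(cfg)
  ), class = "run_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- c(manifest, "run_report.json")
  }
  report$simulation <- sim
  report$pseudoabsence <- pa
  report$features <- feats
  report$model <- mod
  report$screen <- scr
  report$stats <- st
  report
}

#' @export
print.run_report <- function(x, ...) {
  h <- x$headline
  cat("<run_report> multi-scale colony-site selection pipeline\n")
  cat(sprintf("  best scale: %s (mean OOB acc %.3f, max %.3f)\n",
              h$best_scale, h$best_scale_mean_acc, h$best_scale_max_acc))
  cat(sprintf("  top variable there: %s\n", h$top_variable_best_scale))
  cat(sprintf("  diversity tests: all p < 0.05: %s (max p %.4g)\n",
              h$diversity_all_significant, h$diversity_max_p))
  cat(sprintf("  NMDS stress: %.3f\n", h$nmds_stress))
  for (s in h$screen) {
    cat(sprintf("  screen %s: delta %+.3f, slope %.2g (%s)\n",
                s$scale, s$delta, s$slope, s$classification))
  }
  invisible(x)
}
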