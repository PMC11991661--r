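#' Pipeline configuration
#'
#' Collects every tunable setting of the end-to-end analysis with defaults
#' matching the standard protocol: 0.1-degree occurrence thinning, a
#' 25-record species floor, a 0.8 absolute-correlation variable cutoff, 1000
#' pseudo-absences per species, 75/25 train/test splits with 10 replicates,
#' and a 0.7 TSS ensemble cutoff with TSS weights. Every random stage derives
#' its own seed from `seed` plus the stage and species names.
#'
#' @param thin_cell Thinning cell in degrees.
#' @param min_records Minimum records per species.
#' @param cor_cutoff Absolute-correlation variable-selection cutoff.
#' @param n_pseudo Pseudo-absences per species.
#' @param split_fraction Training fraction.
#' @param replicates Train/test replicates per learner.
#' @param learners Learner ids from [learner_registry()].
#' @param tss_cutoff Ensemble TSS inclusion cutoff.
#' @param sre_q SRE tail quantile.
#' @param importance_shuffles Permutations per (run, variable).
#' @param jenks_max_exact Exact-DP size cap for suitability-tier breaks.
#' @param seed Master integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(thin_cell = 0.1, min_records = 25,
                            cor_cutoff = 0.8, n_pseudo = 1000,
                            split_fraction = 0.75, replicates = 10,
                            learners = c("SRE", "RF", "MAXENT", "GAM",
                                         "FDA", "ANN"),
                            tss_cutoff = 0.7, sre_q = 0.025,
                            importance_shuffles = 3,
                            jenks_max_exact = 4000, seed = 1) {
  structure(list(
    thin_cell = thin_cell, min_records = min_records,
    cor_cutoff = cor_cutoff, n_pseudo = n_pseudo,
    split_fraction = split_fraction, replicates = replicates,
    learners = learners, tss_cutoff = tss_cutoff, sre_q = sre_q,
    importance_shuffles = importance_shuffles,
    jenks_max_exact = jenks_max_exact, seed = seed
  ), class = "pipeline_config")
}

# fit + evaluate all learner x replicate runs for one labeled table
fit_species_runs <- function(pts, variables, config, species) {
  registry <- learner_registry(config$learners)
  splits <- make_splits(pts$label, config$split_fraction, config$replicates,
                        seed = derive_seed(config$seed, "split", species))
  models <- list()
  evals <- list()
  k <- 0
  for (lid in names(registry)) {
    for (sp_idx in seq_along(splits)) {
      s <- splits[[sp_idx]]
      k <- k + 1
      seed_fit <- derive_seed(config$seed, "fit", species, lid, s$replicate)
      model <- if (lid == "SRE") {
        m <- fit_sre(pts[s$train, , drop = FALSE], q = config$sre_q,
                     variables = variables)
        m$replicate <- s$replicate
        m
      } else {
        fit_learner(registry[[lid]], pts[s$train, , drop = FALSE], variables,
                    replicate = s$replicate, seed = seed_fit)
      }
      models[[k]] <- model
      evals[[k]] <- evaluate_run(model, pts[s$test, , drop = FALSE])
    }
  }
  list(models = models, evals = dplyr::bind_rows(evals), splits = splits,
       points = pts)
}

# held-out ensemble skill: per replicate, weighted mean of that replicate's
# member predictions on its own test rows, then averaged over replicates
evaluate_ensemble <- function(ensemble, splits, pts) {
  per_rep <- purrr::map_dfr(splits, function(s) {
    rows <- which(ensemble$members$replicate == s$replicate)
    if (length(rows) == 0) return(NULL)
    w <- ensemble$members$weight[rows]
    w <- w / sum(w)
    test <- pts[s$test, , drop = FALSE]
    acc <- rep(0, nrow(test))
    for (i in seq_along(rows))
      acc <- acc + w[i] * score_points(ensemble$models[[rows[i]]], test)
    opt <- optimize_threshold(acc, test$label, "tss")
    m <- threshold_metrics(confusion_counts(acc, test$label, opt$threshold))
    tibble::tibble(replicate = s$replicate, tss = m$tss, kappa = m$kappa,
                   auc = auc_score(acc, test$label))
  })
  tibble::tibble(
    species = ensemble$species,
    tss = mean(per_rep$tss), kappa = mean(per_rep$kappa),
    auc = mean(per_rep$auc), n_replicates = nrow(per_rep)
  )
}

species_importance <- function(ensemble, pts, variables, config) {
  per_run <- purrr::imap_dfr(ensemble$models, function(model, i) {
    run <- paste(model$learner, model$replicate, sep = "_")
    tibble::tibble(
      run = run, variable = variables,
      importance = purrr::map_dbl(variables, function(v) {
        permutation_importance(
          model, pts, v, shuffles = config$importance_shuffles,
          seed = derive_seed(config$seed, "imp", ensemble$species, run, v)
        )
      })
    )
  })
  # one weight per distinct run, in first-appearance order
  runs <- unique(per_run$run)
  wt <- ensemble$members$weight[
    match(runs, paste(ensemble$members$learner, ensemble$members$replicate,
                      sep = "_"))
  ]
  dplyr::mutate(ensemble_importance(per_run, wt),
                species = ensemble$species, .before = 1)
}

#' Run the full ensemble SDM and stacked-richness analysis
#'
#' Executes every stage on in-memory inputs: occurrence cleaning, variable
#' selection, pseudo-absence sampling, replicated multi-learner fitting and
#' evaluation, TSS-weighted ensembling, variable importance, projection to
#' every scenario, occurrence-anchored binarization, richness stacking and
#' classification, spherical area accounting, Jenks suitability tiers, and
#' centroid migration. Fully deterministic given `config$seed`.
#'
#' @param occurrences Occurrence tibble (`species`, `longitude`, `latitude`).
#' @param stacks Named list of [climate_stack()]s; must contain `current`,
#'   plus one entry per future scenario.
#' @param config A [pipeline_config()].
#' @param project Set `FALSE` to stop after ensemble evaluation and variable
#'   importance (no maps, areas or centroids).
#' @return An `sdm_run` list; see the individual components' documentation.
#' @export
run_pipeline <- function(occurrences, stacks, config = pipeline_config(),
                         project = TRUE) {
  stopifnot("current" %in% names(stacks))
  current <- stacks$current

  cleaning <- clean_occurrences(occurrences, cell = config$thin_cell,
                                minimum = config$min_records)
  occ <- cleaning$kept
  species_list <- sort(unique(occ$species))
  if (length(species_list) == 0)
    stop("pipeline aborted at occurrence cleaning: no species retained",
         call. = FALSE)

  corr <- correlation_matrix(current)
  variables <- select_variables(corr, cutoff = config$cor_cutoff)

  evaluations <- list(); ens_eval <- list(); importance <- list()
  ensembles <- list(); suitability <- list(); binaries <- list()
  tiers <- list(); centroids <- list(); thresholds <- list()

  for (sp in species_list) {
    occ_sp <- dplyr::filter(occ, .data$species == sp)
    pa <- sample_pseudo_absences(current, occ_sp, n = config$n_pseudo,
                                 seed = derive_seed(config$seed, "pa", sp))
    pts_raw <- dplyr::bind_rows(
      dplyr::mutate(occ_sp[, c("longitude", "latitude")], label = 1),
      dplyr::mutate(pa, label = 0)
    )
    pts <- extract_at_points(current, pts_raw)
    runs <- fit_species_runs(pts, variables, config, sp)
    evaluations[[sp]] <- dplyr::mutate(runs$evals, species = sp, .before = 1)
    ensemble <- tryCatch(
      build_ensemble(runs$models, runs$evals, cutoff = config$tss_cutoff,
                     species = sp),
      error = function(e) {
        stop(sprintf("pipeline aborted at ensemble stage for '%s': %s",
                     sp, conditionMessage(e)), call. = FALSE)
      }
    )
    ensembles[[sp]] <- ensemble
    ens_eval[[sp]] <- evaluate_ensemble(ensemble, runs$splits, pts)
    importance[[sp]] <- species_importance(ensemble, pts, variables, config)

    if (!project) next

    maps <- purrr::imap(stacks, ~ ensemble_predict(ensemble, .x, scenario = .y))
    suitability[[sp]] <- maps
    th <- occurrence_threshold(maps$current, occ_sp)
    thresholds[[sp]] <- tibble::tibble(species = sp, threshold = th)
    binaries[[sp]] <- purrr::map(maps, binarize, threshold = th)
    cur_vals <- maps$current$values[current$mask]
    if (length(unique(cur_vals)) >= 4) {
      brk <- jenks_breaks(cur_vals, 4, max_exact = config$jenks_max_exact,
                          seed = derive_seed(config$seed, "jenks", sp))
      tiers[[sp]] <- purrr::map(maps, classify_suitability_tiers, breaks = brk)
    } else {
      # near-binary ensemble output (e.g. a single envelope member) cannot
      # support four tiers; tier maps are omitted for this species
      message(sprintf("tiers skipped for '%s': fewer than 4 distinct values", sp))
    }
    centroids[[sp]] <- purrr::map_dfr(binaries[[sp]], range_centroid)
  }

  out <- list(
    config = config,
    cleaning = cleaning$report,
    dropped_species = cleaning$dropped,
    correlation = corr,
    variables = variables,
    evaluations = dplyr::bind_rows(evaluations),
    ensembles = ensembles,
    ensemble_evaluation = dplyr::bind_rows(ens_eval),
    importance = dplyr::bind_rows(importance)
  )

  if (project) {
    richness <- purrr::map(names(stacks), function(scen) {
      stack_richness(purrr::map(binaries, ~ .x[[scen]]))
    })
    names(richness) <- names(stacks)
    categories <- purrr::map(richness, classify_richness)
    areas <- purrr::map_dfr(categories, category_areas)
    all_centroids <- dplyr::bind_rows(centroids)
    out <- c(out, list(
      suitability = suitability,
      binaries = binaries,
      tiers = tiers,
      thresholds = dplyr::bind_rows(thresholds),
      richness = richness,
      richness_categories = categories,
      areas = areas,
      area_summary = area_change_summary(areas),
      centroids = all_centroids,
      migration = centroid_migration(all_centroids)
    ))
  }
  structure(out, class = "sdm_run")
}

#' @export
print.sdm_run <- function(x, ...) {
  cat(sprintf("<sdm_run> %d species, %d run evaluations, variables: %s\n",
              length(x$ensembles), nrow(x$evaluations),
              paste(x$variables, collapse = ", ")))
  if (!is.null(x$area_summary)) {
    cat("Area summary (suitable km^2 by scenario):\n")
    print(as.data.frame(x$area_summary), row.names = FALSE)
  }
  invisible(x)
}

#' Write the tabular outputs of a run to a directory
#'
#' CSV tables (cleaning report, evaluations, ensemble evaluation, importance,
#' thresholds, areas, centroids, migration) plus a YAML manifest recording
#' the configuration and master seed. Tables are written deterministically:
#' rerunning an identical configuration reproduces the files byte-for-byte.
#'
#' @param run An `sdm_run`.
#' @param dir Output directory.
#' @param rasters Also write suitability/binary/richness ASCII grids.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir, rasters = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 12))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  wr(run$cleaning, "cleaning_report.csv")
  wr(run$evaluations, "evaluations.csv")
  wr(run$ensemble_evaluation, "ensemble_evaluation.csv")
  wr(run$importance, "importance.csv")
  if (!is.null(run$areas)) {
    wr(run$thresholds, "thresholds.csv")
    wr(run$areas, "richness_areas.csv")
    wr(run$area_summary, "area_summary.csv")
    wr(run$centroids, "centroids.csv")
    wr(run$migration, "migration.csv")
  }
  cfg <- unclass(run$config)
  yaml::write_yaml(list(config = cfg, variables = as.character(run$variables)),
                   file.path(dir, "manifest.yml"))
  if (rasters && !is.null(run$richness)) {
    for (scen in names(run$richness))
      write_ascii_grid(run$richness[[scen]]$values, run$richness[[scen]]$grid,
                       file.path(dir, sprintf("richness_%s.asc", scen)))
  }
  invisible(dir)
}
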