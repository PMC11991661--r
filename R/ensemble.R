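#' Select runs for ensemble membership by TSS cutoff
#'
#' @param evals Evaluation tibble (one row per learner x replicate, as built
#'   from [evaluate_run()]), with columns `learner`, `replicate`, `tss`,
#'   `valid`.
#' @param cutoff TSS cutoff (default 0.7); a run with TSS exactly at the
#'   cutoff is included.
#' @return The rows of `evals` passing the cutoff.
#' @export
select_runs <- function(evals, cutoff = 0.7) {
  if (nrow(evals) < 1) stop("no runs to select from", call. = FALSE)
  keep <- dplyr::filter(evals, .data$valid, !is.na(.data$tss),
                        .data$tss >= cutoff)
  if (nrow(keep) == 0)
    stop(sprintf("no ensemble: no run reached TSS >= %g", cutoff),
         call. = FALSE)
  keep
}

#' Build a TSS-weighted ensemble from fitted runs
#'
#' Members are the learner x replicate runs whose held-out TSS meets the
#' cutoff; each member's weight is its TSS divided by the members' TSS sum,
#' so weights are positive and sum to one.
#'
#' @param models List of `sdm_fit` objects, one per run.
#' @param evals Matching evaluation tibble (same order as `models`).
#' @param cutoff TSS inclusion cutoff (default 0.7).
#' @param species Species label.
#' @return An `sdm_ensemble` object.
#' @export
build_ensemble <- function(models, evals, cutoff = 0.7, species = "species") {
  stopifnot(length(models) == nrow(evals))
  keep_rows <- which(evals$valid & !is.na(evals$tss) & evals$tss >= cutoff)
  if (length(keep_rows) == 0)
    stop(sprintf("no ensemble: no run reached TSS >= %g for %s",
                 cutoff, species), call. = FALSE)
  members <- evals[keep_rows, , drop = FALSE]
  members$weight <- members$tss / sum(members$tss)
  structure(list(species = species, cutoff = cutoff,
                 members = members, models = models[keep_rows]),
            class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf("<sdm_ensemble> %s: %d member run(s), TSS cutoff %g\n",
              x$species, nrow(x$members), x$cutoff))
  print(dplyr::count(x$members, .data$learner))
  invisible(x)
}

#' Tidy the member table of an ensemble
#'
#' @param x An `sdm_ensemble`.
#' @param ... Unused.
#' @return Tibble of member runs: learner, replicate, threshold, tss, kappa,
#'   auc, weight.
#' @exportS3Method generics::tidy
#' @export
tidy.sdm_ensemble <- function(x, ...) {
  dplyr::select(x$members, "learner", "replicate", "threshold",
                "tss", "kappa", "auc", "weight")
}

#' One-row summary of an ensemble
#'
#' @param x An `sdm_ensemble`.
#' @param ... Unused.
#' @return Tibble: species, n_members, cutoff, mean member TSS/AUC.
#' @exportS3Method generics::glance
#' @export
glance.sdm_ensemble <- function(x, ...) {
  tibble::tibble(
    species = x$species, n_members = nrow(x$members), cutoff = x$cutoff,
    mean_member_tss = mean(x$members$tss),
    mean_member_auc = mean(x$members$auc)
  )
}

#' Ensemble suitability projection
#'
#' Per-cell TSS-weighted mean of the member runs' predictions; a convex
#' combination, so every cell lies within the members' prediction range.
#'
#' @param ensemble An `sdm_ensemble`.
#' @param stack A [climate_stack()].
#' @param scenario Scenario label on the output.
#' @return A [suitability_map()].
#' @export
ensemble_predict <- function(ensemble, stack, scenario = "current") {
  lin <- which(stack$mask)
  vars <- ensemble$models[[1]]$variables
  newdata <- tibble::as_tibble(purrr::map(stack$layers[vars], ~ .x[lin]))
  acc <- rep(0, length(lin))
  for (i in seq_along(ensemble$models)) {
    acc <- acc + ensemble$members$weight[i] *
      score_points(ensemble$models[[i]], newdata)
  }
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[lin] <- clip01(acc)
  suitability_map(stack$grid, vals, species = ensemble$species,
                  scenario = scenario)
}

#' Ensemble scores for a point table
#'
#' @param ensemble An `sdm_ensemble`.
#' @param newdata Tibble with the member variables.
#' @return Numeric scores in `[0, 1]` (TSS-weighted member mean).
#' @export
ensemble_score <- function(ensemble, newdata) {
  acc <- rep(0, nrow(newdata))
  for (i in seq_along(ensemble$models)) {
    acc <- acc + ensemble$members$weight[i] *
      score_points(ensemble$models[[i]], newdata)
  }
  clip01(acc)
}

#' Permutation importance of one variable for one model
#'
#' Importance is `1 - r`, with `r` the Pearson correlation between the
#' model's predictions on the data and its predictions after permuting the
#' variable's column, averaged over seeded permutations and truncated to
#' `[0, 1]`. A model whose predictions ignore the variable scores 0.
#'
#' @param model An `sdm_fit`.
#' @param data Point tibble with the model's variables.
#' @param variable Variable to permute.
#' @param shuffles Number of permutations (default 3).
#' @param seed Integer seed.
#' @return Importance in `[0, 1]`; 0 (with a `degenerate` attribute) when the
#'   reference predictions are constant.
#' @export
permutation_importance <- function(model, data, variable, shuffles = 3,
                                   seed = 1) {
  stopifnot(variable %in% names(data), shuffles >= 1)
  data <- tibble::as_tibble(data)
  ref <- score_points(model, data)
  if (stats::sd(ref) < 1e-12) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  vals <- purrr::map_dbl(seq_len(shuffles), function(s) {
    set.seed(derive_seed(seed, "perm", variable, s))
    perm <- data
    perm[[variable]] <- sample(perm[[variable]])
    shuffled <- score_points(model, perm)
    if (stats::sd(shuffled) < 1e-12) return(1)
    1 - stats::cor(ref, shuffled)
  })
  clip01(mean(vals))
}

#' Weighted-superposition ensemble variable importance
#'
#' Per-variable: the ensemble-weight-weighted sum of the member runs'
#' permutation importances, normalized to percentages summing to 100 — the
#' per-species row of a variable-contribution table.
#'
#' @param per_run Tibble with columns `run` (or `learner`/`replicate`),
#'   `variable`, `importance`, one row per run x variable.
#' @param weights Numeric vector of run weights, one per distinct run, in the
#'   order the runs first appear in `per_run`.
#' @return Tibble: `variable`, `importance` (weighted, raw), `percent`.
#' @export
ensemble_importance <- function(per_run, weights) {
  per_run <- tibble::as_tibble(per_run)
  if (!"run" %in% names(per_run))
    per_run$run <- paste(per_run$learner, per_run$replicate, sep = "_")
  runs <- unique(per_run$run)
  stopifnot(length(weights) == length(runs))
  w <- stats::setNames(weights / sum(weights), runs)
  out <- per_run |>
    dplyr::mutate(w = w[.data$run]) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(importance = sum(.data$w * .data$importance),
                     .groups = "drop")
  total <- sum(out$importance)
  if (total < 1e-12) {
    warning("all importances zero; reporting uniform percentages",
            call. = FALSE)
    out$percent <- 100 / nrow(out)
  } else {
    out$percent <- 100 * out$importance / total
  }
  out
}
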