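#' Confusion counts at a threshold
#'
#' A row is predicted positive iff `score >= threshold` (closed lower bound,
#' the convention used throughout the package).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 observed labels, same length.
#' @param threshold Decision threshold.
#' @return Tibble with one row: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  pred <- scores >= threshold
  tibble::tibble(
    tp = sum(pred & labels == 1),
    fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1),
    tn = sum(!pred & labels == 0)
  )
}

#' Threshold-dependent accuracy metrics
#'
#' Sensitivity, specificity, the true skill statistic
#' (TSS = sensitivity + specificity - 1) and Cohen's Kappa from a confusion
#' table. Kappa uses observed agreement `p_o = (tp + tn)/n` and chance
#' agreement `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`.
#'
#' @param counts One-row tibble or list with `tp`, `fp`, `fn`, `tn`.
#' @return Tibble: `sensitivity`, `specificity`, `tss`, `kappa`; all NA with
#'   a warning when a class is absent.
#' @export
threshold_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  if ((tp + fn) == 0 || (tn + fp) == 0) {
    warning("metrics undefined: one class absent", call. = FALSE)
    return(tibble::tibble(sensitivity = NA_real_, specificity = NA_real_,
                          tss = NA_real_, kappa = NA_real_))
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - p_e) < 1e-15) 0 else (p_o - p_e) / (1 - p_e)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 tss = sens + spec - 1, kappa = kappa)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random presence outscores a random absence; ties count
#' one half. Threshold-free.
#'
#' @inheritParams confusion_counts
#' @return AUC in `[0, 1]`; NA with a warning when only one class is present.
#' @export
auc_score <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    warning("AUC undefined: one class absent", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Threshold maximizing a threshold-dependent metric
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' scores plus just-below-minimum and just-above-maximum extremes; the lowest
#' maximizing threshold is returned.
#'
#' @inheritParams confusion_counts
#' @param metric `"tss"` or `"kappa"`.
#' @return List: `threshold`, `value`, and `degenerate` (TRUE when all scores
#'   are equal, leaving a single candidate).
#' @export
optimize_threshold <- function(scores, labels, metric = c("tss", "kappa")) {
  metric <- match.arg(metric)
  if (length(unique(labels)) < 2)
    stop("both classes required to optimize a threshold", call. = FALSE)
  s <- sort(unique(scores))
  degenerate <- length(s) == 1
  cand <- if (degenerate) s else {
    c(s[1] - 1e-9, (s[-1] + s[-length(s)]) / 2, s[length(s)] + 1e-9)
  }
  vals <- purrr::map_dbl(cand, function(th) {
    threshold_metrics(confusion_counts(scores, labels, th))[[metric]]
  })
  best <- which.max(vals) # which.max returns the first (lowest threshold) tie
  list(threshold = cand[best], value = vals[best], degenerate = degenerate)
}

#' Evaluate a fitted model on a held-out point table
#'
#' Scores the test rows, optimizes the TSS threshold on them, and records
#' threshold, TSS, Kappa and AUC — one row of the per-run evaluation table.
#'
#' @param model An `sdm_fit`.
#' @param test Labeled point tibble with both classes.
#' @return One-row tibble: `learner`, `replicate`, `threshold`, `tss`,
#'   `kappa`, `auc`, `valid` (FALSE when the split was degenerate).
#' @export
evaluate_run <- function(model, test) {
  test <- tibble::as_tibble(test)
  if (length(unique(test$label)) < 2) {
    return(tibble::tibble(learner = model$learner, replicate = model$replicate,
                          threshold = NA_real_, tss = NA_real_,
                          kappa = NA_real_, auc = NA_real_, valid = FALSE))
  }
  scores <- score_points(model, test)
  opt <- optimize_threshold(scores, test$label, "tss")
  m <- threshold_metrics(confusion_counts(scores, test$label, opt$threshold))
  tibble::tibble(
    learner = model$learner, replicate = model$replicate,
    threshold = opt$threshold, tss = m$tss, kappa = m$kappa,
    auc = auc_score(scores, test$label), valid = TRUE
  )
}
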