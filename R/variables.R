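#' Pairwise Pearson correlation matrix of a climate stack
#'
#' Correlations are computed over all valid (masked-in) cells, with no
#' species conditioning. A layer that is constant over the extent has
#' undefined correlations; those entries are set to NA and the layer is
#' reported in the `constant` attribute rather than propagating NaN.
#'
#' @param stack A [climate_stack()] with at least two layers and three valid
#'   cells.
#' @return A symmetric numeric matrix with unit diagonal, layer names on both
#'   dimensions, and attribute `constant` naming any constant layers.
#' @export
correlation_matrix <- function(stack) {
  if (length(stack$layers) < 2) stop("need at least 2 layers", call. = FALSE)
  vals <- purrr::map(stack$layers, ~ .x[stack$mask])
  if (length(vals[[1]]) < 3) stop("need at least 3 valid cells", call. = FALSE)
  m <- do.call(cbind, vals)
  sds <- apply(m, 2, stats::sd)
  constant <- colnames(m)[sds < 1e-12]
  r <- suppressWarnings(stats::cor(m))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- 1
  attr(r, "constant") <- constant
  r
}

#' Drop one member of each highly correlated variable pair
#'
#' Iteratively finds the remaining pair with the largest absolute Pearson
#' correlation; while that exceeds `cutoff`, the pair member with the lower
#' importance score is dropped; ties are broken by dropping the
#' lexicographically later name. The returned set always satisfies
#' `max |r| <= cutoff` (asserted).
#'
#' If no ranking is supplied, importance defaults to the inverse of a
#' variable's mean absolute correlation with all other variables, i.e. the
#' variable more entangled overall is dropped first.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param cutoff Absolute-correlation cutoff in (0, 1); default 0.8 (a pair
#'   is broken only when `|r| > cutoff`).
#' @param ranking Optional named numeric vector of importance scores covering
#'   all variables; higher = more important (kept).
#' @return Character vector of kept variable names, in original order, with
#'   attribute `dropped` listing removals in drop order.
#' @export
select_variables <- function(corr, cutoff = 0.8, ranking = NULL) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)", call. = FALSE)
  vars <- colnames(corr)
  if (is.null(ranking)) {
    off <- abs(corr)
    diag(off) <- NA
    ranking <- 1 / rowMeans(off, na.rm = TRUE)
  }
  miss <- setdiff(vars, names(ranking))
  if (length(miss))
    stop(sprintf("ranking missing variable(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  keep <- vars
  dropped <- character()
  repeat {
    sub <- abs(corr[keep, keep, drop = FALSE])
    diag(sub) <- 0
    sub[is.na(sub)] <- 0
    mx <- max(sub)
    if (mx <= cutoff) break
    ij <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    drop <- if (ranking[[a]] < ranking[[b]]) a
            else if (ranking[[b]] < ranking[[a]]) b
            else max(a, b) # ranking tie: drop the lexicographically later name
    keep <- setdiff(keep, drop)
    dropped <- c(dropped, drop)
    if (length(keep) == 1) break
  }
  sub <- abs(corr[keep, keep, drop = FALSE]); diag(sub) <- 0
  stopifnot(max(sub, na.rm = TRUE) <= cutoff)
  out <- vars[vars %in% keep]
  attr(out, "dropped") <- dropped
  out
}
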