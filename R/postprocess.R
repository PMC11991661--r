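#' Occurrence-anchored binarization threshold
#'
#' The species' threshold is the mean ensemble suitability at its occurrence
#' records minus one sample (n-1) standard deviation, clamped to `[0, 1]`.
#' It is computed once on the current-period map and reused for future
#' scenarios, which have no occurrence truth of their own.
#'
#' @param suit A [suitability_map()].
#' @param occ Occurrence tibble for the species (`longitude`, `latitude`).
#' @return Threshold in `[0, 1]`.
#' @export
occurrence_threshold <- function(suit, occ) {
  stack1 <- climate_stack(suit$grid, list(.s = suit$values))
  vals <- extract_at_points(stack1, occ)$.s
  if (length(vals) < 2)
    stop("need at least 2 occurrence records in valid cells (SD undefined)",
         call. = FALSE)
  clip01(mean(vals) - stats::sd(vals))
}

#' Binarize a suitability map
#'
#' A valid cell is suitable (1) iff its suitability is at or above the
#' threshold; the closed lower bound keeps the zero-spread threshold case
#' (threshold equal to every occurrence value) sensible.
#'
#' @param suit A [suitability_map()].
#' @param threshold Threshold in `[0, 1]`.
#' @return A [binary_map()] recording `threshold_used`.
#' @export
binarize <- function(suit, threshold) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  vals <- ifelse(is.na(suit$values), NA_real_,
                 as.numeric(suit$values >= threshold))
  binary_map(suit$grid, vals, species = suit$species,
             scenario = suit$scenario, threshold_used = threshold)
}

#' Stack binary species maps into a richness map
#'
#' @param maps List of [binary_map()]s on one shared grid.
#' @return A `richness_map`: per-cell count of species predicted present,
#'   with the contributing species names attached.
#' @export
stack_richness <- function(maps) {
  stopifnot(length(maps) >= 1)
  grid <- maps[[1]]$grid
  for (m in maps) {
    if (!grids_identical(m$grid, grid))
      stop(sprintf("binary map for '%s' is not aligned", m$species),
           call. = FALSE)
  }
  counts <- Reduce(`+`, purrr::map(maps, function(m) {
    v <- m$values
    v[is.na(v)] <- 0
    v
  }))
  valid <- Reduce(`|`, purrr::map(maps, ~ !is.na(.x$values)))
  counts[!valid] <- NA_real_
  structure(list(grid = grid, values = counts,
                 species = purrr::map_chr(maps, "species"),
                 scenario = maps[[1]]$scenario),
            class = "richness_map")
}

richness_levels <- c("none", "low", "medium", "high", "hotspot")
tier_levels <- c("unsuitable", "low", "medium", "high")

#' Classify a richness map into four richness categories
#'
#' Integer species counts partition as: 0 none, 1-3 low, 4-6 medium, 7-9
#' high, 10 or more hotspot. (The field convention labels the classes
#' "1-3", "3-6", "6-9", ">9"; counts are integers, so the boundaries 3, 6
#' and 9 belong to the lower class.)
#'
#' @param rich A `richness_map`.
#' @return A `category_map` with levels none/low/medium/high/hotspot.
#' @export
classify_richness <- function(rich) {
  v <- rich$values
  if (any(v < 0, na.rm = TRUE)) stop("negative species count", call. = FALSE)
  cat <- matrix(NA_character_, nrow(v), ncol(v))
  ok <- !is.na(v)
  cat[ok] <- richness_levels[pmin(floor((v[ok] + 2) / 3), 4) + 1]
  structure(list(grid = rich$grid, values = cat, levels = richness_levels,
                 scenario = rich$scenario, kind = "richness"),
            class = "category_map")
}

#' Fisher-Jenks natural breaks
#'
#' Exact dynamic-programming solution minimizing total within-class sum of
#' squared deviations over `k` classes. For more than `max_exact` values a
#' seeded random subsample of that size is used (the optimization is then
#' near-exact rather than exact).
#'
#' @param values Numeric vector.
#' @param k Number of classes.
#' @param max_exact Largest n solved exactly (default 5000).
#' @param seed Seed for the subsample fallback.
#' @return `k - 1` ascending break values, each the midpoint between the last
#'   value of a class and the first value of the next; classification by
#'   "value >= break goes to the upper class" reproduces the optimal classes.
#' @examples
#' jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)  # 6.5
#' @export
jenks_breaks <- function(values, k, max_exact = 5000, seed = 1) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < k)
    stop(sprintf("need at least %d distinct values for %d classes", k, k),
         call. = FALSE)
  if (length(values) > max_exact) {
    set.seed(seed)
    values <- sample(values, max_exact)
    # keep enough distinct values after subsampling
    if (length(unique(values)) < k)
      stop("subsample lost distinct values; raise max_exact", call. = FALSE)
  }
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  ssq <- function(i, j) { # within-class SSQ of x[i..j]
    s <- cs[j + 1] - cs[i]
    q <- cs2[j + 1] - cs2[i]
    q - s^2 / (j - i + 1)
  }
  # dp[c, j]: min total SSQ splitting x[1..j] into c classes
  dp <- matrix(Inf, k, n)
  back <- matrix(NA_integer_, k, n)
  for (j in 1:n) dp[1, j] <- ssq(1, j)
  if (k > 1) {
    for (c in 2:k) {
      for (j in c:n) {
        for (i in c:j) { # class c = x[i..j]
          v <- dp[c - 1, i - 1] + ssq(i, j)
          if (v < dp[c, j]) { dp[c, j] <- v; back[c, j] <- i }
        }
      }
    }
  }
  starts <- integer(k)
  j <- n
  for (c in k:2) {
    starts[c] <- back[c, j]
    j <- starts[c] - 1
  }
  starts[1] <- 1
  breaks <- purrr::map_dbl(2:k, function(c) {
    (x[starts[c] - 1] + x[starts[c]]) / 2
  })
  attr(breaks, "total_ssq") <- dp[k, n]
  breaks
}

#' Classify a suitability map into tiers by ascending breaks
#'
#' Four tiers (unsuitable / low / medium / high) from three ascending break
#' values; intervals are half-open with a value exactly at a break going to
#' the upper class, and the top interval closed above at 1. Breaks are
#' normally the Jenks breaks of the current-scenario map, reused for future
#' scenarios of the same species.
#'
#' @param suit A [suitability_map()].
#' @param breaks Numeric vector of 3 ascending break values.
#' @return A `category_map` with levels unsuitable/low/medium/high.
#' @export
classify_suitability_tiers <- function(suit, breaks) {
  if (length(breaks) != 3 || is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be 3 strictly ascending values", call. = FALSE)
  v <- suit$values
  cat <- matrix(NA_character_, nrow(v), ncol(v))
  ok <- !is.na(v)
  idx <- findInterval(v[ok], breaks) + 1 # value == break -> upper class
  cat[ok] <- tier_levels[idx]
  structure(list(grid = suit$grid, values = cat, levels = tier_levels,
                 scenario = suit$scenario, species = suit$species,
                 kind = "tiers"),
            class = "category_map")
}

#' Spherical areas per category
#'
#' Sums exact spherical cell areas (see [cell_area_km2()]) per category;
#' cells count fully (no partial-cell clipping at mask edges).
#'
#' @param cat A `category_map`.
#' @return Tibble: `scenario`, `category` (all declared levels, zero rows
#'   included), `area_km2`, `percent` (of total valid area; sums to 100).
#' @export
category_areas <- function(cat) {
  areas <- cell_area_matrix(cat$grid)
  ok <- !is.na(cat$values)
  tb <- tibble::tibble(category = cat$values[ok], area = areas[ok]) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(area_km2 = sum(.data$area), .groups = "drop")
  out <- tibble::tibble(category = factor(cat$levels, levels = cat$levels)) |>
    dplyr::left_join(dplyr::mutate(tb, category = factor(.data$category,
                                                         levels = cat$levels)),
                     by = "category") |>
    dplyr::mutate(area_km2 = dplyr::coalesce(.data$area_km2, 0))
  total <- sum(out$area_km2)
  out$percent <- if (total > 0) 100 * out$area_km2 / total else 0
  dplyr::mutate(out, scenario = cat$scenario %||% NA_character_,
                .before = 1)
}

#' Compare category areas across scenarios
#'
#' Takes a category-area table spanning several scenarios (rows as produced
#' by [category_areas()], or any tibble with `scenario`, `category`,
#' `area_km2`) and returns per-scenario totals plus absolute and percent
#' changes versus a reference scenario. Categories named `none` or
#' `unsuitable` are excluded from the totals, which therefore measure total
#' suitable/occupied area.
#'
#' @param areas Tibble with `scenario`, `category`, `area_km2`.
#' @param reference Reference scenario name (default `"current"`).
#' @return Tibble: `scenario`, `total_km2`, `delta_km2`, `delta_percent`
#'   (change relative to the reference total).
#' @export
area_change_summary <- function(areas, reference = "current") {
  areas <- tibble::as_tibble(areas)
  stopifnot(all(c("scenario", "category", "area_km2") %in% names(areas)))
  totals <- areas |>
    dplyr::filter(!.data$category %in% c("none", "unsuitable")) |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(total_km2 = sum(.data$area_km2), .groups = "drop")
  if (!reference %in% totals$scenario)
    stop(sprintf("reference scenario '%s' not present", reference),
         call. = FALSE)
  ref <- totals$total_km2[totals$scenario == reference]
  dplyr::mutate(totals,
                delta_km2 = .data$total_km2 - ref,
                delta_percent = 100 * (.data$total_km2 - ref) / ref)
}
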