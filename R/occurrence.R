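#' Read an occurrence CSV
#'
#' Expects columns `species`, `longitude`, `latitude` and optionally `source`;
#' UTF-8, one header row.
#'
#' @param path CSV file path.
#' @return An occurrence tibble.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("species", "longitude", "latitude")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("occurrence CSV missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(abs(df$longitude) > 180) || any(abs(df$latitude) > 90))
    stop("coordinates outside WGS84 bounds", call. = FALSE)
  tibble::as_tibble(df)
}

#' Thin occurrences to one record per grid cell
#'
#' Retains at most one record per species per `cell`-degree grid cell. The
#' thinning grid is anchored at (0, 0): a record falls in cell
#' `(floor(longitude/cell), floor(latitude/cell))`. Records are first sorted
#' on (longitude, latitude, source) so the result is independent of input
#' order; within a cell the first record after sorting is kept.
#'
#' @param occ Occurrence tibble (`species`, `longitude`, `latitude`, ...).
#' @param cell Thinning cell size in degrees (default 0.1).
#' @return Thinned occurrence tibble.
#' @examples
#' occ <- tibble::tibble(species = "a",
#'                       longitude = c(110.01, 110.09, 110.11),
#'                       latitude = c(25.02, 25.08, 25.02))
#' nrow(thin_by_grid(occ, 0.1))  # 2: the first two share a 0.1-degree cell
#' @export
thin_by_grid <- function(occ, cell = 0.1) {
  if (cell <= 0) stop("cell must be > 0", call. = FALSE)
  occ <- tibble::as_tibble(occ)
  if (nrow(occ) == 0) return(occ)
  ord <- if ("source" %in% names(occ)) {
    order(occ$longitude, occ$latitude, occ$source)
  } else {
    order(occ$longitude, occ$latitude)
  }
  occ <- occ[ord, , drop = FALSE]
  occ |>
    dplyr::mutate(.cx = floor(.data$longitude / cell),
                  .cy = floor(.data$latitude / cell)) |>
    dplyr::distinct(.data$species, .data$.cx, .data$.cy, .keep_all = TRUE) |>
    dplyr::select(-".cx", -".cy")
}

#' Drop species with too few records
#'
#' @param occ Occurrence tibble (typically already thinned).
#' @param minimum Minimum record count; species with `n >= minimum` are kept
#'   (exactly `minimum` records is kept; this mirrors the convention that a
#'   26-record species survives a 25-record floor).
#' @return A list with `kept` (occurrence tibble), `dropped` (character
#'   vector of dropped species), and `report` (tibble: species, n_records,
#'   kept flag).
#' @export
filter_min_records <- function(occ, minimum = 25) {
  stopifnot(minimum >= 1)
  occ <- tibble::as_tibble(occ)
  report <- occ |>
    dplyr::count(.data$species, name = "n_records") |>
    dplyr::mutate(kept = .data$n_records >= minimum) |>
    dplyr::arrange(.data$species)
  keep <- report$species[report$kept]
  list(
    kept = dplyr::filter(occ, .data$species %in% keep),
    dropped = report$species[!report$kept],
    report = report
  )
}

#' Clean an occurrence table: thin, then filter
#'
#' Convenience wrapper applying [thin_by_grid()] then [filter_min_records()],
#' returning a cleaning report that accounts for records lost at each step.
#'
#' @inheritParams thin_by_grid
#' @inheritParams filter_min_records
#' @return List with `kept`, `dropped`, and `report` (species, n_raw,
#'   n_thinned, kept).
#' @export
clean_occurrences <- function(occ, cell = 0.1, minimum = 25) {
  occ <- tibble::as_tibble(occ)
  raw_n <- dplyr::count(occ, .data$species, name = "n_raw")
  thinned <- thin_by_grid(occ, cell)
  res <- filter_min_records(thinned, minimum)
  report <- raw_n |>
    dplyr::left_join(dplyr::rename(res$report, n_thinned = "n_records"),
                     by = "species") |>
    dplyr::arrange(.data$species)
  list(kept = res$kept, dropped = res$dropped, report = report)
}
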