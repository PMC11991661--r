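#' Grid specification for a geographic (WGS84) raster
#'
#' A `grid_spec` describes a regular longitude/latitude grid with square cells
#' (equal angular resolution in both axes), cell-center registration, and a
#' nodata sentinel. It is the shared geometry object for every map container
#' in the package.
#'
#' The cell-assignment convention used everywhere (thinning, extraction,
#' occurrence placement) is: a point `(x, y)` belongs to column
#' `floor((x - west)/resolution) + 1` and row `floor((north - y)/resolution) + 1`,
#' so the west and north edges of a cell are inclusive and the east and south
#' edges belong to the neighbouring cell.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param west,south Coordinates of the outer west/south grid edges, decimal
#'   degrees.
#' @param resolution Cell size in decimal degrees (square cells).
#' @param nodata_value Sentinel written to disk for missing cells.
#' @return A `grid_spec` object.
#' @examples
#' g <- grid_spec(10, 20, west = 100, south = 20, resolution = 0.5)
#' g$east   # 110
#' g$north  # 25
#' @export
grid_spec <- function(n_rows, n_cols, west, south, resolution,
                      nodata_value = -9999) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  if (resolution <= 0) stop("resolution must be > 0", call. = FALSE)
  east <- west + n_cols * resolution
  north <- south + n_rows * resolution
  g <- structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      west = west, south = south, east = east, north = north,
      resolution = resolution, nodata_value = nodata_value
    ),
    class = "grid_spec"
  )
  validate_grid_spec(g)
  g
}

validate_grid_spec <- function(g) {
  if (g$east <= g$west || g$north <= g$south)
    stop("grid extent is empty (east <= west or north <= south)", call. = FALSE)
  if (abs((g$east - g$west) / g$resolution - g$n_cols) > 1e-9)
    stop("extent width is not an integer multiple of resolution", call. = FALSE)
  if (abs((g$north - g$south) / g$resolution - g$n_rows) > 1e-9)
    stop("extent height is not an integer multiple of resolution", call. = FALSE)
  invisible(g)
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d rows x %d cols @ %g deg  lon [%g, %g]  lat [%g, %g]\n",
    x$n_rows, x$n_cols, x$resolution, x$west, x$east, x$south, x$north
  ))
  invisible(x)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$west - b$west) < tol && abs(a$south - b$south) < tol &&
    abs(a$resolution - b$resolution) < tol
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return A tibble with `row`, `col`, `longitude`, `latitude` for every cell,
#'   in row-major order (row 1 = northernmost).
#' @export
cell_centers <- function(grid) {
  lon <- grid$west + (seq_len(grid$n_cols) - 0.5) * grid$resolution
  lat <- grid$north - (seq_len(grid$n_rows) - 0.5) * grid$resolution
  tidyr::expand_grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols)) |>
    dplyr::mutate(longitude = lon[.data$col], latitude = lat[.data$row])
}

# row/col for points; NA where outside the grid. West/north edges inclusive.
point_to_cell <- function(grid, longitude, latitude) {
  col <- floor((longitude - grid$west) / grid$resolution) + 1
  row <- floor((grid$north - latitude) / grid$resolution) + 1
  # points exactly on the north edge (row 0 impossible) / west edge handled by
  # floor; points on the south or east outer edge fall outside.
  bad <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Build a climate stack from named layer matrices
#'
#' A `climate_stack` holds co-registered 2D climate layers on one grid plus the
#' joint valid mask (cells valid in every layer). Matrices are oriented with
#' row 1 at the northern edge.
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices, each `n_rows x n_cols`.
#' @param mask Optional logical matrix of study-extent cells; defaults to all
#'   cells finite in every layer.
#' @return A `climate_stack`.
#' @export
climate_stack <- function(grid, layers, mask = NULL) {
  if (length(layers) < 1) stop("at least one layer required", call. = FALSE)
  nm <- names(layers)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    stop("layers must have unique non-empty names", call. = FALSE)
  for (v in nm) {
    d <- dim(layers[[v]])
    if (is.null(d) || d[1] != grid$n_rows || d[2] != grid$n_cols)
      stop(sprintf("layer '%s' does not match the grid dimensions", v),
           call. = FALSE)
  }
  finite <- Reduce(`&`, lapply(layers, is.finite))
  if (is.null(mask)) mask <- finite else mask <- mask & finite
  # enforce identical nodata pattern across layers
  layers <- lapply(layers, function(m) { m[!mask] <- NA_real_; m })
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  cat(sprintf("<climate_stack> %d layer(s): %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(x$grid)
  cat(sprintf("  valid cells: %d / %d\n", sum(x$mask), length(x$mask)))
  invisible(x)
}

layer_names <- function(stack) names(stack$layers)

#' Per-species continuous suitability map
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix in `[0, 1]` on valid cells, NA elsewhere.
#' @param species Species name.
#' @param scenario Scenario label, e.g. `"current"`, `"SSP126"`, `"SSP585"`.
#' @return A `suitability_map`.
#' @export
suitability_map <- function(grid, values, species, scenario = "current") {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  v <- values[is.finite(values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("suitability values must lie in [0, 1]", call. = FALSE)
  structure(list(grid = grid, values = values, species = species,
                 scenario = scenario),
            class = "suitability_map")
}

#' Per-species binary (presence/absence) map
#'
#' @inheritParams suitability_map
#' @param values Matrix of 0/1 on valid cells, NA elsewhere.
#' @param threshold_used Suitability threshold that produced the map.
#' @return A `binary_map`.
#' @export
binary_map <- function(grid, values, species, scenario = "current",
                       threshold_used = NA_real_) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  v <- values[is.finite(values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("binary map values must be 0/1", call. = FALSE)
  structure(list(grid = grid, values = values, species = species,
                 scenario = scenario, threshold_used = threshold_used),
            class = "binary_map")
}

#' Extract layer values at points
#'
#' Maps each point to its containing cell (west/north edge inclusive) and
#' returns the cell values of every layer. Points outside the grid or in
#' nodata cells are dropped with a warning reporting the count.
#'
#' @param stack A [climate_stack()].
#' @param points A data frame with `longitude` and `latitude` columns; other
#'   columns (e.g. `label`) are carried through.
#' @return A tibble: the carried-through point columns plus one column per
#'   layer, only for points falling in valid cells.
#' @export
extract_at_points <- function(stack, points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("longitude", "latitude") %in% names(points)))
  idx <- point_to_cell(stack$grid, points$longitude, points$latitude)
  inside <- !is.na(idx$row)
  lin <- cbind(idx$row[inside], idx$col[inside])
  valid <- stack$mask[lin]
  n_dropped <- sum(!inside) + sum(!valid)
  if (n_dropped > 0)
    warning(sprintf("%d point(s) outside the grid or in nodata cells were dropped",
                    n_dropped), call. = FALSE)
  out <- points[inside, , drop = FALSE][valid, , drop = FALSE]
  lin <- lin[valid, , drop = FALSE]
  for (v in layer_names(stack)) out[[v]] <- stack$layers[[v]][lin]
  out
}

#' Spherical area of the cells in one grid row
#'
#' Area of a lon/lat cell on the sphere: `R^2 * dlambda * (sin(phi_top) -
#' sin(phi_bottom))` with `R = 6371.0088` km (IUGG mean radius) and `dlambda`
#' the resolution in radians. All cells in a row share one area.
#'
#' @param grid A [grid_spec()].
#' @param row_index 1-based row index (row 1 is the northernmost).
#' @return Cell area in km^2.
#' @export
cell_area_km2 <- function(grid, row_index) {
  if (any(row_index < 1 | row_index > grid$n_rows))
    stop("row_index out of range", call. = FALSE)
  phi_top <- (grid$north - (row_index - 1) * grid$resolution) * pi / 180
  phi_bot <- phi_top - grid$resolution * pi / 180
  earth_radius_km^2 * (grid$resolution * pi / 180) * (sin(phi_top) - sin(phi_bot))
}

earth_radius_km <- 6371.0088

# matrix of per-cell areas (rows share a value)
cell_area_matrix <- function(grid) {
  matrix(cell_area_km2(grid, seq_len(grid$n_rows)),
         nrow = grid$n_rows, ncol = grid$n_cols)
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values, northernmost row first. Values are written with enough digits to
#' round-trip single precision.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, digits = 9) {
  stopifnot(nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10f", grid$west),
    sprintf("yllcorner %.10f", grid$south),
    sprintf("cellsize %.10f", grid$resolution),
    sprintf("NODATA_value %g", grid$nodata_value)
  ), con)
  v <- values
  v[!is.finite(v)] <- grid$nodata_value
  writeLines(apply(v, 1, function(r) paste(signif(r, digits), collapse = " ")),
             con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return A list with `grid` (a [grid_spec()]) and `values` (matrix, nodata
#'   as NA, row 1 = north).
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  grid <- grid_spec(hdr$nrows, hdr$ncols, west = hdr$xllcorner,
                    south = hdr$yllcorner, resolution = hdr$cellsize,
                    nodata_value = hdr$nodata_value)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != grid$n_rows * grid$n_cols)
    stop(sprintf("corrupt ASCII grid: expected %d values, found %d",
                 grid$n_rows * grid$n_cols, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  m[m == grid$nodata_value] <- NA_real_
  list(grid = grid, values = m)
}

#' Read a set of aligned ASCII-grid rasters as a climate stack
#'
#' @param paths Character vector of ASCII-grid files, one per layer.
#' @param names Layer names, same length and order as `paths`.
#' @return A [climate_stack()]; errors if any file's grid geometry differs
#'   from the first.
#' @export
read_raster_stack <- function(paths, names) {
  stopifnot(length(paths) == length(names), length(paths) >= 1)
  first <- read_ascii_grid(paths[1])
  layers <- stats::setNames(vector("list", length(paths)), names)
  layers[[1]] <- first$values
  if (length(paths) > 1) {
    for (i in 2:length(paths)) {
      r <- read_ascii_grid(paths[i])
      if (!grids_identical(r$grid, first$grid))
        stop(sprintf("raster '%s' is not aligned with '%s'",
                     paths[i], paths[1]), call. = FALSE)
      layers[[i]] <- r$values
    }
  }
  climate_stack(first$grid, layers)
}

#' Write every layer of a stack as ASCII grids
#'
#' @param stack A [climate_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Tibble of layer names and file paths, invisibly.
#' @export
write_raster_stack <- function(stack, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(layer_names(stack), function(v) {
    p <- file.path(dir, paste0(prefix, v, ".asc"))
    write_ascii_grid(stack$layers[[v]], stack$grid, p)
    p
  })
  invisible(tibble::tibble(layer = layer_names(stack), path = paths))
}

#' Turn a map into a tibble of cell values
#'
#' Long-format view of any grid container, used by the plotting methods and
#' convenient for dplyr summaries.
#'
#' @param map A `suitability_map`, `binary_map`, `richness_map`,
#'   `category_map`, or bare matrix plus grid.
#' @param grid Required when `map` is a bare matrix.
#' @return Tibble with `row`, `col`, `longitude`, `latitude`, `value` (valid
#'   cells only).
#' @export
map_to_tibble <- function(map, grid = NULL) {
  if (is.matrix(map)) {
    stopifnot(!is.null(grid))
    values <- map
  } else {
    grid <- map$grid
    values <- map$values
  }
  cc <- cell_centers(grid)
  cc$value <- values[cbind(cc$row, cc$col)]
  dplyr::filter(cc, !is.na(.data$value))
}
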