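#' Virtual species with a Gaussian (bell-shaped) niche
#'
#' The truth surface used by the benchmark: suitability of a cell is
#' `exp(-0.5 * sum_v ((x_v - mu_v) / sigma_v)^2)` over the niche variables,
#' so it lies in (0, 1] and reaches 1 exactly where every variable sits at its
#' optimum. Gaussian responses are the standard choice in virtual-species
#' studies: smooth, unimodal, and with closed-form spot checks.
#'
#' @param name Species name.
#' @param niche Named list, one entry per niche variable, each a numeric
#'   vector `c(mu = optimum, sigma = tolerance)` in layer units.
#' @param prevalence_target Optional fraction of the extent intended to be
#'   suitable (informational; recorded, not enforced).
#' @return A `virtual_species` object.
#' @examples
#' sp <- virtual_species("sp1", list(Bio4 = c(mu = 600, sigma = 60)))
#' @export
virtual_species <- function(name, niche, prevalence_target = NULL) {
  if (length(niche) < 1) stop("at least one niche variable required", call. = FALSE)
  if (is.null(names(niche)) || any(names(niche) == ""))
    stop("niche entries must be named by variable", call. = FALSE)
  for (v in names(niche)) {
    if (!all(c("mu", "sigma") %in% names(niche[[v]])))
      stop(sprintf("niche for '%s' needs mu and sigma", v), call. = FALSE)
    if (niche[[v]][["sigma"]] <= 0)
      stop(sprintf("sigma for '%s' must be > 0", v), call. = FALSE)
  }
  structure(list(name = name, niche = niche,
                 prevalence_target = prevalence_target),
            class = "virtual_species")
}

# box moving-average smoother, window = 2*halfwidth + 1, edge-renormalized
smooth_field <- function(m, halfwidth) {
  h <- floor(halfwidth)
  if (h < 1) return(m)
  box1d <- function(v) {
    n <- length(v)
    cs <- c(0, cumsum(v))
    i <- seq_len(n)
    lo <- pmax(1, i - h)
    hi <- pmin(n, i + h)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, box1d)                # smooth down columns
  t(apply(m, 1, box1d))                  # then along rows
}

#' Generate a synthetic climate stack
#'
#' Each layer is a deterministic large-scale gradient (linear in longitude and
#' latitude) plus spatially smoothed seeded Gaussian noise, rescaled to a
#' stated mean and standard deviation. Designated layer pairs are made
#' correlated at a target Pearson r by mixing standardized fields, so the
#' realized sample correlation matches the target closely.
#'
#' @param grid A [grid_spec()].
#' @param layers Tibble or data frame describing the layers, with columns
#'   `name`, `mean`, `sd`, `grad_lon`, `grad_lat` (gradient in units per
#'   degree). Use [default_layer_table()] for the standard seven bioclimate
#'   layers.
#' @param correlated_pairs Optional list of `list(a =, b =, r =)` entries;
#'   layer `b` is rebuilt to correlate with `a` at Pearson `r`.
#' @param smoothness Moving-average half-width in cells for the noise field
#'   (0 = unsmoothed white noise).
#' @param noise_sd Standard deviation of the noise component relative to the
#'   layer `sd` (the gradient supplies the rest of the variance).
#' @param seed Integer seed; the stack is reproducible given the seed.
#' @return A [climate_stack()].
#' @export
generate_climate_stack <- function(grid, layers = default_layer_table(),
                                   correlated_pairs = list(),
                                   smoothness = 3, noise_sd = 0.5, seed = 1) {
  layers <- tibble::as_tibble(layers)
  stopifnot(all(c("name", "mean", "sd", "grad_lon", "grad_lat") %in% names(layers)))
  for (p in correlated_pairs) {
    if (abs(p$r) >= 1) stop("pair correlation must lie in (-1, 1)", call. = FALSE)
    if (!all(c(p$a, p$b) %in% layers$name))
      stop("correlated pair names not in layer table", call. = FALSE)
  }
  set.seed(seed)
  cc <- cell_centers(grid)
  lon <- matrix(cc$longitude, grid$n_rows, grid$n_cols, byrow = TRUE)
  lat <- matrix(rep(cc$latitude[cc$col == 1], each = grid$n_cols),
                grid$n_rows, grid$n_cols, byrow = TRUE)
  std <- function(m) (m - mean(m)) / stats::sd(as.vector(m))
  # standardized field per layer: gradient + smoothed noise, mixed by noise_sd
  fields <- list()
  for (i in seq_len(nrow(layers))) {
    L <- layers[i, ]
    noise <- smooth_field(matrix(stats::rnorm(grid$n_rows * grid$n_cols),
                                 grid$n_rows, grid$n_cols), smoothness)
    gradient <- L$grad_lon * lon + L$grad_lat * lat
    if (stats::sd(as.vector(gradient)) < 1e-12) {
      f <- std(noise)
    } else {
      f <- sqrt(1 - noise_sd^2) * std(gradient) + noise_sd * std(noise)
    }
    fields[[L$name]] <- std(f)
  }
  for (p in correlated_pairs) {
    # orthogonalize b against a in-sample, then mix at exactly the target r
    va <- as.vector(fields[[p$a]])
    vb <- as.vector(fields[[p$b]])
    resid <- vb - stats::cor(va, vb) * va
    resid <- resid / stats::sd(resid)
    mixed <- p$r * va + sqrt(1 - p$r^2) * resid
    fields[[p$b]] <- std(matrix(mixed, grid$n_rows, grid$n_cols))
  }
  out <- purrr::map2(fields, seq_len(nrow(layers)), function(f, i) {
    layers$mean[i] + layers$sd[i] * f
  })
  names(out) <- layers$name
  climate_stack(grid, out)
}

#' Standard layer table for the seven-variable benchmark
#'
#' Seven layers named after the bioclimatic variables retained by the
#' correlation filter in subtropical-China camellia modeling (Bio2, Bio3,
#' Bio4, Bio5, Bio15, Bio18, Bio19), with magnitudes loosely matching those
#' variables' units. Bio4 rises eastward and Bio19 rises northward in the
#' synthetic world, giving the virtual species geographically banded niches.
#' Gradient directions are deliberately spread (east, north, the two
#' diagonals, and two purely noisy layers) so that no layer pair other than a
#' designated correlated pair approaches the conventional 0.8 selection
#' cutoff; only a gradient's direction matters for the between-layer
#' correlation structure, not its magnitude, because fields are standardized
#' before rescaling.
#'
#' @return A tibble with columns `name`, `mean`, `sd`, `grad_lon`, `grad_lat`.
#' @export
default_layer_table <- function() {
  tibble::tribble(
    ~name,   ~mean, ~sd,  ~grad_lon, ~grad_lat,
    "Bio2",    9,    1.5,   0.08,      0.08,
    "Bio3",   30,    4,     0.25,      0.25,
    "Bio4",  600,  150,    28,         0,
    "Bio5",   30,    3,     0,         0,
    "Bio15",  60,   15,    -1,         1,
    "Bio18", 600,  120,     0,         0,
    "Bio19",  90,   45,     0,         8
  )
}

#' True suitability of a virtual species over a stack
#'
#' @param sp A [virtual_species()].
#' @param stack A [climate_stack()] containing every niche variable.
#' @param scenario Scenario label stored on the result.
#' @return A [suitability_map()] with the closed-form Gaussian-niche truth.
#' @export
virtual_suitability <- function(sp, stack, scenario = "current") {
  missing <- setdiff(names(sp$niche), layer_names(stack))
  if (length(missing))
    stop(sprintf("niche variable(s) not in stack: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  q <- matrix(0, stack$grid$n_rows, stack$grid$n_cols)
  for (v in names(sp$niche)) {
    z <- (stack$layers[[v]] - sp$niche[[v]][["mu"]]) / sp$niche[[v]][["sigma"]]
    q <- q + z^2
  }
  s <- exp(-0.5 * q)
  s[!stack$mask] <- NA_real_
  suitability_map(stack$grid, s, species = sp$name, scenario = scenario)
}

#' Sample presence records proportional to suitability
#'
#' Draws `n` distinct cells without replacement with probability proportional
#' to true suitability and places one record at each cell center, emulating a
#' cleaned (one-record-per-cell) occurrence table.
#'
#' @param truth A [suitability_map()] (the virtual species' truth surface).
#' @param n Number of records.
#' @param seed Integer seed.
#' @return An occurrence tibble with columns `species`, `longitude`,
#'   `latitude`, `source`.
#' @export
sample_occurrences <- function(truth, n, seed = 1) {
  stopifnot(n >= 1)
  cells <- map_to_tibble(truth)
  cells <- dplyr::filter(cells, .data$value > 0)
  if (nrow(cells) < n)
    stop(sprintf("requested %d records but only %d cells with positive suitability",
                 n, nrow(cells)), call. = FALSE)
  set.seed(seed)
  pick <- sample.int(nrow(cells), n, replace = FALSE, prob = cells$value)
  tibble::tibble(
    species = truth$species,
    longitude = cells$longitude[pick],
    latitude = cells$latitude[pick],
    source = "synthetic"
  )
}

#' Deterministic climate shift for a future scenario
#'
#' @param deltas Named numeric vector of additive per-variable shifts (layer
#'   units); unnamed variables shift by 0.
#' @param grad_lon,grad_lat Optional named numeric vectors giving a spatial
#'   gradient of the delta in units per degree longitude/latitude, measured
#'   from the grid's west/south edges; the shift applied at a cell is
#'   `delta + grad_lon * (lon - west) + grad_lat * (lat - south)`.
#' @return A `scenario_shift` object.
#' @export
scenario_shift <- function(deltas = numeric(), grad_lon = numeric(),
                           grad_lat = numeric()) {
  stopifnot(all(is.finite(deltas)), all(is.finite(grad_lon)),
            all(is.finite(grad_lat)))
  structure(list(deltas = deltas, grad_lon = grad_lon, grad_lat = grad_lat),
            class = "scenario_shift")
}

#' Apply a scenario shift to a climate stack
#'
#' @param stack A [climate_stack()].
#' @param shift A [scenario_shift()].
#' @return A new [climate_stack()] with shifted values and unchanged mask.
#' @export
shift_climate <- function(stack, shift) {
  stopifnot(inherits(shift, "scenario_shift"))
  cc <- cell_centers(stack$grid)
  lon <- matrix(cc$longitude, stack$grid$n_rows, stack$grid$n_cols, byrow = TRUE)
  lat <- matrix(rep(cc$latitude[cc$col == 1], each = stack$grid$n_cols),
                stack$grid$n_rows, stack$grid$n_cols, byrow = TRUE)
  layers <- stack$layers
  for (v in layer_names(stack)) {
    d <- if (v %in% names(shift$deltas)) shift$deltas[[v]] else 0
    gl <- if (v %in% names(shift$grad_lon)) shift$grad_lon[[v]] else 0
    ga <- if (v %in% names(shift$grad_lat)) shift$grad_lat[[v]] else 0
    if (d != 0 || gl != 0 || ga != 0)
      layers[[v]] <- layers[[v]] + d + gl * (lon - stack$grid$west) +
        ga * (lat - stack$grid$south)
  }
  climate_stack(stack$grid, layers, mask = stack$mask)
}

#' Default virtual-species benchmark configuration
#'
#' Five well-sampled species (200 presences each) with two-variable Gaussian
#' niches on Bio4 (eastward-increasing) and Bio19 (northward-increasing),
#' plus one under-sampled species (20 records) that the minimum-record filter
#' is expected to drop. Future scenarios add a positive shift to Bio4, which
#' moves every species' climatic optimum westward — larger under the
#' high-emission scenario — giving the benchmark a known range-change
#' direction.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param n_presence Presences per well-sampled species.
#' @return A named list understood by [make_benchmark()].
#' @export
default_benchmark_config <- function(n_rows = 150, n_cols = 150,
                                     n_presence = 200) {
  grid <- grid_spec(n_rows, n_cols, west = 100, south = 20, resolution = 0.1)
  optima_bio4 <- c(450, 520, 590, 660, 730)
  optima_bio19 <- c(60, 120, 85, 105, 75)
  species <- purrr::map(1:5, function(i) {
    virtual_species(
      sprintf("virtual_sp%02d", i),
      niche = list(Bio4 = c(mu = optima_bio4[i], sigma = 20),
                   Bio19 = c(mu = optima_bio19[i], sigma = 12))
    )
  })
  rare <- virtual_species("virtual_rare",
                          niche = list(Bio4 = c(mu = 560, sigma = 20),
                                       Bio19 = c(mu = 95, sigma = 12)))
  list(
    grid = grid,
    layers = default_layer_table(),
    correlated_pairs = list(list(a = "Bio2", b = "Bio3", r = 0.9)),
    smoothness = 3,
    noise_sd = 0.55,
    species = species,
    rare_species = rare,
    n_presence = n_presence,
    n_presence_rare = 20,
    shifts = list(
      SSP126 = scenario_shift(deltas = c(Bio4 = 60)),
      SSP585 = scenario_shift(deltas = c(Bio4 = 160))
    )
  )
}

#' Generate the full synthetic benchmark bundle
#'
#' One call producing everything the pipeline consumes: the current climate
#' stack, shifted future stacks, the virtual species list, their truth maps,
#' and a pooled occurrence table (including the under-sampled species that
#' exercises the minimum-record filter). Fully deterministic given `seed`.
#'
#' @param config A list as returned by [default_benchmark_config()].
#' @param seed Master integer seed.
#' @return A list with elements `stacks` (named list of climate stacks:
#'   current plus one per shift scenario), `species`, `truth` (named list of
#'   truth [suitability_map()]s per scenario), `occurrences` (tibble),
#'   `config`, `seed`.
#' @export
make_benchmark <- function(config = default_benchmark_config(), seed = 1) {
  required <- c("grid", "layers", "species", "n_presence", "shifts")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop(sprintf("benchmark config missing field(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  stack <- generate_climate_stack(
    config$grid, layers = config$layers,
    correlated_pairs = config$correlated_pairs %||% list(),
    smoothness = config$smoothness %||% 3,
    noise_sd = config$noise_sd %||% 0.5,
    seed = derive_seed(seed, "climate")
  )
  stacks <- c(list(current = stack),
              purrr::imap(config$shifts, ~ shift_climate(stack, .x)))
  all_species <- config$species
  n_per <- rep(config$n_presence, length(all_species))
  if (!is.null(config$rare_species)) {
    all_species <- c(all_species, list(config$rare_species))
    n_per <- c(n_per, config$n_presence_rare %||% 20)
  }
  truth <- purrr::imap(stacks, function(st, scen) {
    purrr::map(config$species, virtual_suitability, stack = st,
               scenario = scen) |>
      stats::setNames(purrr::map_chr(config$species, "name"))
  })
  occ <- purrr::map2_dfr(all_species, n_per, function(sp, n) {
    sample_occurrences(virtual_suitability(sp, stack), n,
                       seed = derive_seed(seed, "occ", sp$name))
  })
  list(stacks = stacks, species = config$species, truth = truth,
       occurrences = occ, config = config, seed = seed)
}

#' Write a benchmark bundle to disk
#'
#' Rasters as ASCII grids, occurrences and truth summaries as CSV, and a YAML
#' manifest recording the seed and scalar parameters, so a run can be
#' reproduced from the files alone.
#'
#' @param bundle Result of [make_benchmark()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (scen in names(bundle$stacks))
    write_raster_stack(bundle$stacks[[scen]], file.path(dir, scen))
  utils::write.csv(bundle$occurrences, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  g <- bundle$config$grid
  manifest <- list(
    seed = bundle$seed,
    grid = list(n_rows = g$n_rows, n_cols = g$n_cols, west = g$west,
                south = g$south, resolution = g$resolution),
    species = purrr::map(bundle$species, function(sp) {
      list(name = sp$name, niche = purrr::map(sp$niche, as.list))
    }),
    scenarios = names(bundle$stacks)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
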