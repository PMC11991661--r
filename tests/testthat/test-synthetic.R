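flat_layers <- function() {
  # no gradients: isolates the noise/correlation machinery
  tibble::tibble(name = c("L1", "L2", "L3"), mean = 0, sd = 1,
                 grad_lon = 0, grad_lat = 0)
}

test_that("climate generation is deterministic and hits correlation targets", {
  g <- grid_spec(150, 150, west = 100, south = 20, resolution = 0.1)
  pairs <- list(list(a = "L1", b = "L2", r = 0.95))
  s1 <- generate_climate_stack(g, flat_layers(), pairs, smoothness = 2, seed = 5)
  s2 <- generate_climate_stack(g, flat_layers(), pairs, smoothness = 2, seed = 5)
  expect_identical(s1$layers, s2$layers)
  r12 <- cor(as.vector(s1$layers$L1), as.vector(s1$layers$L2))
  expect_gte(r12, 0.85)
  expect_lte(r12, 1.0)
  expect_error(
    generate_climate_stack(g, flat_layers(),
                           list(list(a = "L1", b = "L2", r = 1.2))),
    "correlation"
  )
})

test_that("unsmoothed uncorrelated layers are near-independent", {
  g <- grid_spec(150, 150, west = 100, south = 20, resolution = 0.1)
  s <- generate_climate_stack(g, flat_layers(), list(), smoothness = 0,
                              noise_sd = 1, seed = 8)
  expect_lt(abs(cor(as.vector(s$layers$L1), as.vector(s$layers$L3))), 0.1)
})

test_that("Gaussian-niche suitability matches its closed form", {
  g <- toy_grid(n = 2, res = 1)
  mk <- function(a, b) climate_stack(g, list(
    V1 = matrix(a, 2, 2), V2 = matrix(b, 2, 2)
  ))
  sp <- virtual_species("v", list(V1 = c(mu = 10, sigma = 2),
                                  V2 = c(mu = 0, sigma = 1)))
  expect_equal(virtual_suitability(sp, mk(10, 0))$values[1, 1], 1.0)
  expect_equal(virtual_suitability(sp, mk(12, 0))$values[1, 1], exp(-0.5))
  expect_equal(virtual_suitability(sp, mk(12, 1))$values[1, 1], exp(-1))
  expect_error(virtual_suitability(sp, climate_stack(g, list(V1 = matrix(1, 2, 2)))),
               "V2")
})

test_that("truth suitability ignores non-niche layers", {
  st <- toy_stack()
  sp <- virtual_species("v", list(A = c(mu = 104, sigma = 2)))
  s1 <- virtual_suitability(sp, st)
  extra <- climate_stack(st$grid, c(st$layers,
                                    list(D = matrix(0, 10, 10))))
  expect_equal(virtual_suitability(sp, extra)$values, s1$values)
})

test_that("one-variable truth is suitable exactly on an interval of layer values", {
  st <- toy_stack()
  sp <- virtual_species("v", list(A = c(mu = 104, sigma = 2)))
  s <- virtual_suitability(sp, st)
  for (th in c(0.2, 0.5, 0.9)) {
    suitable_vals <- st$layers$A[s$values >= th]
    unsuitable_vals <- st$layers$A[s$values < th]
    hi <- 104 + 2 * sqrt(-2 * log(th))
    lo <- 104 - 2 * sqrt(-2 * log(th))
    expect_true(all(suitable_vals >= lo - 1e-9 & suitable_vals <= hi + 1e-9))
    expect_true(all(unsuitable_vals < lo | unsuitable_vals > hi))
  }
})

test_that("occurrence sampling is uniform under uniform truth", {
  g <- toy_grid(n = 10, res = 0.1)
  tr <- suitability_map(g, matrix(0.5, 10, 10), "u")
  counts <- integer(100)
  for (i in 1:500) {
    occ <- sample_occurrences(tr, 1, seed = i)
    idx <- sdmstack:::point_to_cell(g, occ$longitude, occ$latitude)
    cell <- (idx$col - 1L) * g$n_rows + idx$row
    counts[cell] <- counts[cell] + 1
  }
  expect_gt(suppressWarnings(chisq.test(counts)$p.value), 0.01)
})

test_that("occurrence sampling concentrates on suitable cells", {
  g <- toy_grid(n = 10, res = 0.1)
  set.seed(3)
  vals <- matrix(runif(100), 10, 10)
  tr <- suitability_map(g, vals, "v")
  occ <- sample_occurrences(tr, 30, seed = 4)
  st1 <- climate_stack(g, list(s = vals))
  expect_gt(mean(extract_at_points(st1, occ)$s), mean(vals))

  # all mass in one cell -> the single draw lands there
  one <- matrix(0, 10, 10); one[4, 7] <- 1
  occ1 <- sample_occurrences(suitability_map(g, one, "p"), 1, seed = 1)
  ext <- extract_at_points(climate_stack(g, list(s = one)), occ1)
  expect_equal(ext$s, 1)
  expect_error(sample_occurrences(suitability_map(g, one, "p"), 2, seed = 1),
               "positive suitability")
})

test_that("climate shifts are exact and move the truth centroid as designed", {
  st <- toy_stack()
  expect_equal(shift_climate(st, scenario_shift())$layers, st$layers)
  sh <- shift_climate(st, scenario_shift(deltas = c(A = 2)))
  expect_equal(mean(sh$layers$A) - mean(st$layers$A), 2)
  expect_equal(sh$layers$B, st$layers$B)

  # A increases eastward; adding value moves the optimum locus west
  sp <- virtual_species("v", list(A = c(mu = 106, sigma = 1.5)))
  cen <- function(stack) {
    s <- virtual_suitability(sp, stack)
    df <- map_to_tibble(s)
    sum(df$longitude * df$value) / sum(df$value)
  }
  shifted <- shift_climate(st, scenario_shift(grad_lon = c(A = 1)))
  expect_lt(cen(shifted), cen(st))
})

test_that("benchmark bundles are reproducible and include a filterable rare species", {
  cfg <- default_benchmark_config(n_rows = 40, n_cols = 40, n_presence = 30)
  b1 <- make_benchmark(cfg, seed = 12)
  b2 <- make_benchmark(cfg, seed = 12)
  expect_identical(b1$occurrences, b2$occurrences)
  counts <- table(b1$occurrences$species)
  expect_equal(unname(counts[["virtual_rare"]]), 20)
  cleaned <- clean_occurrences(b1$occurrences, cell = 0.1, minimum = 25)
  expect_true("virtual_rare" %in% cleaned$dropped)
  expect_error(make_benchmark(list(grid = cfg$grid), seed = 1), "missing field")
})
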