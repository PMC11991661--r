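test_that("occurrence threshold is mean minus sample SD, clamped", {
  g <- toy_grid(n = 3, res = 1)
  vals <- matrix(c(0.2, 0.4, 0.6, 0.8, 0.8, 0.8, 0.05, 0.05, 0.05), 3, 3,
                 byrow = TRUE)  # row 1 northernmost
  suit <- suitability_map(g, vals, "s")
  cc <- cell_centers(g)
  pick <- function(cells) {
    cc[cells, ] |> dplyr::select(longitude, latitude)
  }
  # cells holding 0.2, 0.4, 0.6 (column 1) -> mean 0.4, sd 0.2 -> 0.2
  expect_equal(occurrence_threshold(suit, pick(1:3)), 0.2)
  # constant suitability 0.8 -> SD 0 -> threshold 0.8
  expect_equal(occurrence_threshold(suit, pick(4:6)), 0.8)
  expect_error(occurrence_threshold(suit, pick(1)), "at least 2")

  # mean - SD below zero clamps to 0
  v2 <- matrix(c(0.01, 0.01, 0.45, rep(0.01, 6)), 3, 3, byrow = TRUE)
  s2 <- suitability_map(g, v2, "s")
  expect_equal(occurrence_threshold(s2, pick(1:3)), 0)
})

test_that("binarization uses the closed lower bound and is monotone in threshold", {
  g <- toy_grid(n = 5, res = 0.5)
  set.seed(77)
  vals <- matrix(runif(25), 5, 5)
  suit <- suitability_map(g, vals, "s")
  expect_equal(sum(binarize(suit, 0)$values), 25)
  expect_equal(sum(binarize(suit, max(vals) + 1e-9 + 0)$values), 0)
  b <- binarize(suit, vals[2, 2])
  expect_equal(b$values[2, 2], 1)  # exactly at threshold -> suitable
  expect_equal(b$threshold_used, vals[2, 2])
  counts <- sapply(seq(0, 1, length.out = 100), function(th) {
    sum(binarize(suit, th)$values)
  })
  expect_true(all(diff(counts) <= 0))
  expect_error(binarize(suit, 1.5), "threshold")
})

test_that("richness stacking equals an independent per-cell tally", {
  g <- toy_grid(n = 6, res = 0.5)
  set.seed(31)
  mats <- purrr::map(1:5, ~ matrix(rbinom(36, 1, 0.4), 6, 6))
  maps <- purrr::imap(mats, ~ binary_map(g, .x, species = paste0("s", .y)))
  rich <- stack_richness(maps)
  expect_equal(rich$values, Reduce(`+`, mats))
  expect_true(all(rich$values <= 5))
  one <- stack_richness(maps[1])
  expect_equal(one$values, mats[[1]])
  allones <- stack_richness(purrr::map(1:15, ~ binary_map(g, matrix(1, 6, 6), "x")))
  expect_equal(unique(as.vector(allones$values)), 15)
  g2 <- toy_grid(n = 6, res = 0.25)
  expect_error(stack_richness(list(maps[[1]], binary_map(g2, matrix(0, 6, 6), "y"))),
               "aligned")
})

test_that("richness categories partition integer counts at 3/6/9", {
  g <- grid_spec(1, 12, west = 0, south = 0, resolution = 1)
  rich <- structure(list(grid = g, values = matrix(0:11, 1, 12),
                         species = letters[1:11], scenario = "current"),
                    class = "richness_map")
  cat <- classify_richness(rich)
  expect_equal(as.vector(cat$values),
               c("none", rep("low", 3), rep("medium", 3), rep("high", 3),
                 "hotspot", "hotspot"))
  rich$values[1, 1] <- -1
  expect_error(classify_richness(rich), "negative")
})

test_that("Jenks breaks equal exhaustive-partition optima", {
  b <- jenks_breaks(c(1, 2, 3, 10, 11, 12), 2)
  expect_gt(b, 3)
  expect_lt(b, 10)
  # perfectly separated clusters are recovered
  b3 <- jenks_breaks(c(1, 1.1, 5, 5.1, 9, 9.2), 3)
  expect_equal(length(b3), 2)
  expect_true(b3[1] > 1.1 && b3[1] < 5 && b3[2] > 5.1 && b3[2] < 9)

  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 10), 2)
    if (length(unique(x)) < k) next
    breaks <- jenks_breaks(x, k)
    expect_equal(attr(breaks, "total_ssq"), brute_jenks_ssq(x, k),
                 tolerance = 1e-9)
  }
  expect_error(jenks_breaks(c(1, 1, 1), 2), "distinct")
})

test_that("suitability tiers follow half-open intervals with breaks in the upper class", {
  g <- grid_spec(1, 6, west = 0, south = 0, resolution = 1)
  suit <- suitability_map(g, matrix(c(0.1, 0.25, 0.4, 0.5, 0.75, 0.9), 1, 6), "s")
  tiers <- classify_suitability_tiers(suit, c(0.25, 0.5, 0.75))
  expect_equal(as.vector(tiers$values),
               c("unsuitable", "low", "low", "medium", "high", "high"))
  expect_error(classify_suitability_tiers(suit, c(0.5, 0.25, 0.75)),
               "ascending")
  # tier areas equal a per-cell recount
  areas <- category_areas(tiers)
  recount <- sapply(c("unsuitable", "low", "medium", "high"), function(lv) {
    sum(cell_area_km2(g, 1) * (tiers$values == lv))
  })
  expect_equal(areas$area_km2, unname(recount))
})

test_that("category areas conserve the total and percents sum to 100", {
  g <- toy_grid(n = 8, res = 0.5)
  set.seed(19)
  counts <- matrix(sample(0:12, 64, replace = TRUE), 8, 8)
  rich <- structure(list(grid = g, values = counts, species = letters[1:12],
                         scenario = "current"), class = "richness_map")
  areas <- category_areas(classify_richness(rich))
  expect_equal(sum(areas$percent), 100, tolerance = 0.01)
  expect_equal(sum(areas$area_km2), sum(sdmstack:::cell_area_matrix(g)),
               tolerance = 1e-9)
  # all cells one category
  uni <- structure(list(grid = g, values = matrix(2, 8, 8), species = "a",
                        scenario = "x"), class = "richness_map")
  ua <- category_areas(classify_richness(uni))
  expect_equal(ua$area_km2[ua$category == "low"], sum(sdmstack:::cell_area_matrix(g)))
})

test_that("adding a species never lowers a cell's richness category", {
  g <- toy_grid(n = 6, res = 0.5)
  set.seed(23)
  mats <- purrr::map(1:8, ~ matrix(rbinom(36, 1, 0.5), 6, 6))
  maps <- purrr::imap(mats, ~ binary_map(g, .x, species = paste0("s", .y)))
  ord <- function(cat) {
    matrix(match(cat$values, cat$levels), 6, 6)
  }
  o7 <- ord(classify_richness(stack_richness(maps[1:7])))
  o8 <- ord(classify_richness(stack_richness(maps[1:8])))
  expect_true(all(o8 >= o7))
})
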