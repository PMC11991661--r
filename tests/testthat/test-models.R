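test_that("pseudo-absences avoid presence cells, are uniform, and reproducible", {
  g <- toy_grid(n = 20, res = 0.1)
  st <- climate_stack(g, list(A = matrix(1, 20, 20)))
  cc <- cell_centers(g)
  pres <- cc[sample.int(400, 50), ] |>
    dplyr::select(longitude, latitude)
  p1 <- sample_pseudo_absences(st, pres, n = 100, seed = 5)
  p2 <- sample_pseudo_absences(st, pres, n = 100, seed = 5)
  expect_identical(p1, p2)
  # no pseudo-absence shares a cell with a presence
  key <- function(df) paste(round(df$longitude, 6), round(df$latitude, 6))
  expect_length(intersect(key(p1), key(pres)), 0)

  # forced outcome: only n cells remain eligible
  pres_most <- cc[1:396, ] |> dplyr::select(longitude, latitude)
  forced <- sample_pseudo_absences(st, pres_most, n = 4, seed = 1)
  expect_setequal(key(forced), key(cc[397:400, ]))
  expect_error(sample_pseudo_absences(st, pres_most, n = 5, seed = 1),
               "eligible")
})

test_that("pseudo-absence draws are uniform over eligible cells", {
  set.seed(99)
  g <- toy_grid(n = 20, res = 0.1)
  st <- climate_stack(g, list(A = matrix(1, 20, 20)))
  cc <- cell_centers(g)
  pres <- cc[sample.int(400, 50), ] |> dplyr::select(longitude, latitude)
  counts <- integer(400)
  for (i in 1:3000) {
    p <- sample_pseudo_absences(st, pres, n = 1, seed = i)
    idx <- sdmstack:::point_to_cell(g, p$longitude, p$latitude)
    cell <- (idx$col - 1L) * 20L + idx$row
    counts[cell] <- counts[cell] + 1
  }
  pres_idx <- sdmstack:::point_to_cell(g, pres$longitude, pres$latitude)
  pres_cells <- (pres_idx$col - 1L) * 20L + pres_idx$row
  expect_equal(sum(counts[pres_cells]), 0)
  eligible <- counts[-pres_cells]
  expect_gt(suppressWarnings(chisq.test(eligible)$p.value), 0.01)
})

test_that("splits hold the training fraction exactly and stratify by class", {
  labels <- rep(c(1, 0), c(40, 60))
  splits <- make_splits(labels, fraction = 0.75, replicates = 10, seed = 3)
  expect_length(splits, 10)
  for (s in splits) {
    expect_length(s$train, 75)
    expect_length(s$test, 25)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), 1:100)
    n_pres_train <- sum(labels[s$train] == 1)
    expect_lte(abs(n_pres_train - 30), 1)
  }
  s1 <- make_splits(labels, replicates = 1, seed = 7)
  s2 <- make_splits(labels, replicates = 1, seed = 7)
  expect_identical(s1, s2)
  expect_error(make_splits(labels, fraction = 1.2), "fraction")
  expect_error(make_splits(rep(1, 4)), "at least 8")
})

test_that("SRE envelopes equal hand-computed quantile intervals", {
  train <- tibble::tibble(label = rep(1, 10), V = 1:10)
  m0 <- fit_sre(train, q = 0)
  expect_equal(m0$state$envelope$V, c(1, 10))
  expect_equal(score_points(m0, tibble::tibble(V = c(5, 11, 1, 10))),
               c(1, 0, 1, 1))
  m1 <- fit_sre(train, q = 0.1)
  expect_equal(m1$state$envelope$V, c(1.9, 9.1))  # type-7 linear interpolation
  expect_equal(score_points(m1, tibble::tibble(V = 1.5)), 0)
  # the envelope always contains its own training presences at q = 0
  expect_equal(score_points(m0, train), rep(1, 10))
  expect_error(fit_sre(train, q = 0.5), "q must be")
})

test_that("SRE suitability is monotone non-increasing in q", {
  set.seed(11)
  train <- tibble::tibble(label = 1, V1 = rnorm(50), V2 = rnorm(50))
  probe <- tibble::tibble(V1 = rnorm(200), V2 = rnorm(200))
  qs <- seq(0, 0.45, by = 0.05)
  scores <- sapply(qs, function(q) score_points(fit_sre(train, q = q), probe))
  # raising q never converts unsuitable to suitable
  expect_true(all(diff(t(scores)) <= 0))
})

test_that("stack prediction equals point-wise extraction then scoring", {
  st <- toy_stack()
  set.seed(4)
  train <- tibble::tibble(label = rep(c(1, 0), each = 25),
                          A = c(rnorm(25, 106), rnorm(25, 102)),
                          B = rnorm(50, -57))
  for (lrn in learner_registry(c("SRE", "RF", "GAM"))) {
    model <- fit_learner(lrn, train, c("A", "B"), seed = 2)
    map <- predict_model(model, st)
    pts <- extract_at_points(st, cell_centers(st$grid))
    direct <- score_points(model, pts)
    expect_equal(as.vector(t(map$values)), direct, tolerance = 1e-12)
  }
  model <- fit_learner("CONST", train, c("A", "B"))
  expect_equal(unique(as.vector(predict_model(model, st)$values)), 0.5)
  expect_error(predict_model(model, climate_stack(st$grid,
                                                  list(A = st$layers$A))),
               "missing variable")
})

test_that("every registered learner honors the fit/score contract", {
  set.seed(15)
  train <- toy_points()
  probe <- toy_points(seed = 16)
  for (lrn in learner_registry(c("SRE", "RF", "MAXENT", "GAM", "FDA", "ANN",
                                 "CONST"))) {
    model <- fit_learner(lrn, train, c("x1", "x2"), seed = 9)
    s <- score_points(model, probe)
    expect_length(s, nrow(probe))
    expect_true(all(s >= 0 & s <= 1), info = lrn$id)
    s2 <- score_points(fit_learner(lrn, train, c("x1", "x2"), seed = 9), probe)
    expect_equal(s, s2, info = lrn$id)  # deterministic given the seed
  }
  expect_error(learner_registry("NOPE"), "unknown learner")
})
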