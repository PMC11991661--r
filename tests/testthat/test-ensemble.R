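fake_evals <- function(tss) {
  tibble::tibble(learner = paste0("L", seq_along(tss)),
                 replicate = 1L, threshold = 0.5, tss = tss,
                 kappa = tss, auc = (tss + 1) / 2, valid = TRUE)
}

# stub model scoring a constant
const_model <- function(value, vars = "A") {
  structure(list(learner = paste0("const", value), replicate = 1L,
                 variables = vars, state = list(v = value),
                 predict_fun = function(state, newdata) {
                   rep(state$v, nrow(newdata))
                 }),
            class = "sdm_fit")
}

test_that("run selection applies the TSS cutoff inclusively", {
  evs <- fake_evals(c(0.9, 0.7, 0.69))
  kept <- select_runs(evs, cutoff = 0.7)
  expect_equal(kept$tss, c(0.9, 0.7))
  expect_equal(nrow(select_runs(evs, cutoff = 0.5)), 3)
  expect_error(select_runs(fake_evals(c(0.3, 0.2)), cutoff = 0.7),
               "no ensemble")
})

test_that("ensemble weights are normalized TSS and predictions are their convex mix", {
  g <- toy_grid(n = 4, res = 1)
  st <- climate_stack(g, list(A = matrix(0, 4, 4)))
  models <- list(const_model(1), const_model(0))
  ens <- build_ensemble(models, fake_evals(c(0.9, 0.7)), cutoff = 0.7)
  expect_equal(sum(ens$members$weight), 1)
  expect_equal(ens$members$weight, c(0.9, 0.7) / 1.6)
  pred <- ensemble_predict(ens, st)
  expect_equal(unique(as.vector(pred$values)), 0.9 / 1.6)

  single <- build_ensemble(list(const_model(0.42)), fake_evals(0.8))
  expect_equal(unique(as.vector(ensemble_predict(single, st)$values)), 0.42)

  equal_w <- build_ensemble(models, fake_evals(c(0.8, 0.8)))
  expect_equal(unique(as.vector(ensemble_predict(equal_w, st)$values)), 0.5)
})

test_that("ensemble predictions stay inside the member range and removal is bounded", {
  set.seed(51)
  train <- toy_points()
  models <- purrr::map(c("RF", "GAM", "SRE"), fit_learner,
                       training = train, variables = c("x1", "x2"), seed = 3)
  evs <- fake_evals(c(0.9, 0.8, 0.75))
  ens <- build_ensemble(models, evs, cutoff = 0.7)
  probe <- toy_points(seed = 52)
  member_scores <- sapply(models, score_points, newdata = probe)
  s <- ensemble_score(ens, probe)
  expect_true(all(s >= apply(member_scores, 1, min) - 1e-12))
  expect_true(all(s <= apply(member_scores, 1, max) + 1e-12))

  # dropping member i and renormalizing moves no score by more than
  # w_i * range of member predictions
  for (i in 1:3) {
    sub <- build_ensemble(models[-i], evs[-i, ], cutoff = 0.7)
    delta <- abs(ensemble_score(sub, probe) - s)
    bound <- ens$members$weight[i] *
      (apply(member_scores, 1, max) - apply(member_scores, 1, min))
    expect_true(all(delta <= bound + 1e-9))
  }
})

test_that("tidy and glance summarize ensemble membership", {
  models <- list(const_model(1), const_model(0))
  ens <- build_ensemble(models, fake_evals(c(0.9, 0.7)), species = "spX")
  td <- tidy(ens)
  expect_equal(nrow(td), 2)
  expect_true(all(c("learner", "tss", "weight") %in% names(td)))
  gl <- glance(ens)
  expect_equal(gl$species, "spX")
  expect_equal(gl$n_members, 2)
})

test_that("permutation importance matches a direct Pearson oracle", {
  # identity model on one variable
  ident <- structure(list(learner = "ident", replicate = 1L, variables = "x",
                          state = NULL,
                          predict_fun = function(state, newdata) {
                            sdmstack:::clip01(newdata$x)
                          }),
                     class = "sdm_fit")
  set.seed(61)
  data <- tibble::tibble(x = runif(200), z = runif(200))
  imp <- permutation_importance(ident, data, "x", shuffles = 3, seed = 7)
  oracle <- mean(sapply(1:3, function(s) {
    set.seed(derive_seed(7, "perm", "x", s))
    1 - cor(data$x, sample(data$x))
  }))
  expect_equal(as.numeric(imp), min(1, max(0, oracle)))
  # a variable the model ignores scores zero
  expect_equal(as.numeric(permutation_importance(ident, data, "z", seed = 7)), 0)
  # constant predictions are flagged degenerate
  cm <- const_model(0.5)
  data$A <- 1
  impc <- permutation_importance(cm, data, "A", seed = 1)
  expect_equal(as.numeric(impc), 0)
  expect_true(attr(impc, "degenerate"))
})

test_that("ensemble importance is the weighted superposition, summing to 100", {
  per_run <- tibble::tibble(
    run = rep(c("r1", "r2"), each = 2),
    variable = rep(c("V1", "V2"), 2),
    importance = c(1, 0, 0, 1)
  )
  out <- ensemble_importance(per_run, weights = c(0.5, 0.5))
  expect_equal(out$percent, c(50, 50))
  expect_equal(sum(out$percent), 100, tolerance = 0.01)

  solo <- ensemble_importance(dplyr::filter(per_run, run == "r1"), weights = 1)
  expect_equal(solo$percent, c(100, 0))

  uneven <- ensemble_importance(per_run, weights = c(0.9, 0.1))
  expect_equal(uneven$percent, c(90, 10))
  expect_equal(sum(uneven$percent), 100, tolerance = 0.01)

  zero <- dplyr::mutate(per_run, importance = 0)
  expect_warning(u <- ensemble_importance(zero, weights = c(0.5, 0.5)),
                 "uniform")
  expect_equal(u$percent, c(50, 50))
})
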