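#' Sample pseudo-absence points for a species
#'
#' Draws `n` cells uniformly without replacement from the valid study-extent
#' cells, excluding every cell that contains a presence record of the
#' species, and places one point at each cell center. One pseudo-absence set
#' is drawn per species and shared across learners and replicates.
#'
#' @param stack A [climate_stack()] defining the study extent.
#' @param occ Occurrence tibble for one species (`longitude`, `latitude`).
#' @param n Number of pseudo-absences (default 1000).
#' @param seed Integer seed.
#' @return Tibble with `longitude`, `latitude` and the seed as an attribute.
#' @export
sample_pseudo_absences <- function(stack, occ, n = 1000, seed = 1) {
  grid <- stack$grid
  idx <- point_to_cell(grid, occ$longitude, occ$latitude)
  presence_lin <- (idx$col - 1L) * grid$n_rows + idx$row
  presence_lin <- presence_lin[!is.na(presence_lin)]
  valid_lin <- which(stack$mask)
  eligible <- setdiff(valid_lin, presence_lin)
  if (length(eligible) < n)
    stop(sprintf("only %d eligible cells for %d pseudo-absences",
                 length(eligible), n), call. = FALSE)
  set.seed(seed)
  pick <- if (length(eligible) == n) eligible else sample(eligible, n)
  row <- ((pick - 1L) %% grid$n_rows) + 1L
  col <- ((pick - 1L) %/% grid$n_rows) + 1L
  out <- tibble::tibble(
    longitude = grid$west + (col - 0.5) * grid$resolution,
    latitude = grid$north - (row - 0.5) * grid$resolution
  )
  attr(out, "seed") <- seed
  out
}

#' Replicated stratified train/test splits
#'
#' Each replicate is an independent seeded random partition of the rows,
#' stratified by the 0/1 `labels` so every training set holds the configured
#' fraction of each class (within one row per class).
#'
#' @param labels Vector of 0/1 presence/absence labels, one per row.
#' @param fraction Training fraction (default 0.75).
#' @param replicates Number of replicates (default 10).
#' @param seed Integer seed.
#' @return List of `replicates` splits, each
#'   `list(replicate =, train = row indices, test = row indices)`.
#' @export
make_splits <- function(labels, fraction = 0.75, replicates = 10, seed = 1) {
  n <- length(labels)
  if (n < 8) stop("need at least 8 rows to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  purrr::map(seq_len(replicates), function(r) {
    set.seed(derive_seed(seed, "split", r))
    train <- integer()
    for (cls in unique(labels)) {
      rows <- which(labels == cls)
      k <- round(fraction * length(rows))
      train <- c(train, sample(rows, k))
    }
    train <- sort(train)
    list(replicate = r, train = train, test = setdiff(seq_len(n), train))
  })
}

# ---- learner contract ---------------------------------------------------
# A learner is list(id, fit = function(train, variables, seed) -> state,
# predict = function(state, newdata) -> scores in [0,1]). fit_learner wraps
# the state into an sdm_fit; predict_model routes both point tables and
# climate stacks through the same scoring path.

new_learner <- function(id, fit, predict) {
  structure(list(id = id, fit = fit, predict = predict), class = "sdm_learner")
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Built-in learner registry
#'
#' Six learners behind one contract (fit a labeled point table, score new
#' rows in `[0, 1]`): the native surface range envelope (`SRE`), and five
#' standard classifier analogues — random forest (`RF`), a
#' maximum-entropy-like regularized logistic regression on linear and
#' quadratic features (`MAXENT`), a generalized additive model (`GAM`),
#' linear discriminant analysis standing in for flexible discriminant
#' analysis (`FDA`), and a single-hidden-layer neural network (`ANN`). A
#' degenerate `CONST` learner (constant 0.5) is registered for contract
#' testing only and excluded from default runs.
#'
#' @param ids Learner ids to return (default: the six modeling learners).
#' @return Named list of learner objects.
#' @export
learner_registry <- function(ids = c("SRE", "RF", "MAXENT", "GAM", "FDA", "ANN")) {
  all <- list(
    SRE = new_learner(
      "SRE",
      fit = function(train, variables, seed = 1, q = 0.025) {
        fit_sre(train, q = q, variables = variables)$state
      },
      predict = function(state, newdata) sre_score(state, newdata)
    ),
    RF = new_learner(
      "RF",
      fit = function(train, variables, seed = 1) {
        set.seed(seed)
        fit <- randomForest::randomForest(
          x = as.data.frame(train[, variables, drop = FALSE]),
          y = factor(train$label, levels = c(0, 1)),
          ntree = 300
        )
        list(fit = fit, variables = variables)
      },
      predict = function(state, newdata) {
        clip01(stats::predict(state$fit,
                              as.data.frame(newdata[, state$variables, drop = FALSE]),
                              type = "prob")[, "1"])
      }
    ),
    MAXENT = new_learner(
      "MAXENT",
      fit = function(train, variables, seed = 1) {
        set.seed(seed)
        x <- as.matrix(train[, variables, drop = FALSE])
        x <- cbind(x, x^2)
        colnames(x) <- c(variables, paste0(variables, "_sq"))
        ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
        scl[scl < 1e-12] <- 1
        xs <- scale(x, ctr, scl)
        # near-separable data can leave the smallest lambdas unconverged;
        # cross-validation picks from the converged part of the path
        fit <- suppressWarnings(
          glmnet::cv.glmnet(xs, train$label, family = "binomial",
                            alpha = 1, nfolds = 5)
        )
        list(fit = fit, variables = variables, center = ctr, scale = scl)
      },
      predict = function(state, newdata) {
        x <- as.matrix(newdata[, state$variables, drop = FALSE])
        x <- cbind(x, x^2)
        xs <- scale(x, state$center, state$scale)
        clip01(as.vector(stats::predict(state$fit, xs, s = "lambda.min",
                                        type = "response")))
      }
    ),
    GAM = new_learner(
      "GAM",
      fit = function(train, variables, seed = 1) {
        set.seed(seed)
        form <- stats::as.formula(paste(
          "label ~", paste(sprintf("s(%s, k = 5)", variables), collapse = " + ")
        ))
        # near-separable training data can trip step-failure warnings that do
        # not affect the returned fit
        fit <- suppressWarnings(
          mgcv::gam(form, data = as.data.frame(train),
                    family = stats::binomial(), method = "REML")
        )
        list(fit = fit, variables = variables)
      },
      predict = function(state, newdata) {
        clip01(as.vector(stats::predict(state$fit, as.data.frame(newdata),
                                        type = "response")))
      }
    ),
    FDA = new_learner(
      "FDA",
      fit = function(train, variables, seed = 1) {
        fit <- MASS::lda(
          x = as.data.frame(train[, variables, drop = FALSE]),
          grouping = factor(train$label, levels = c(0, 1))
        )
        list(fit = fit, variables = variables)
      },
      predict = function(state, newdata) {
        p <- stats::predict(state$fit,
                            as.data.frame(newdata[, state$variables, drop = FALSE]))
        clip01(p$posterior[, "1"])
      }
    ),
    ANN = new_learner(
      "ANN",
      fit = function(train, variables, seed = 1) {
        set.seed(seed)
        x <- as.matrix(train[, variables, drop = FALSE])
        ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
        scl[scl < 1e-12] <- 1
        fit <- nnet::nnet(scale(x, ctr, scl), train$label, size = 5,
                          decay = 0.01, maxit = 300, trace = FALSE)
        list(fit = fit, variables = variables, center = ctr, scale = scl)
      },
      predict = function(state, newdata) {
        x <- as.matrix(newdata[, state$variables, drop = FALSE])
        clip01(as.vector(stats::predict(state$fit, scale(x, state$center,
                                                         state$scale))))
      }
    ),
    CONST = new_learner(
      "CONST",
      fit = function(train, variables, seed = 1) list(variables = variables),
      predict = function(state, newdata) rep(0.5, nrow(newdata))
    )
  )
  unknown <- setdiff(ids, names(all))
  if (length(unknown))
    stop(sprintf("unknown learner id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  all[ids]
}

#' Fit the surface range envelope (climate envelope) learner
#'
#' Fits on presence rows only: for each variable the envelope is the
#' empirical `[Q(q), Q(1 - q)]` quantile interval of presence values (linear
#' interpolation, R quantile type 7). A row scores 1 iff every variable lies
#' inside its envelope, else 0. `q = 0.025` gives the conventional 95%
#' climate envelope.
#'
#' @param training Labeled point tibble (`label` 0/1 plus variable columns);
#'   only `label == 1` rows enter the envelope.
#' @param q Tail quantile in `[0, 0.5)`.
#' @param variables Variables to envelope (default: all non-coordinate,
#'   non-label columns).
#' @return An `sdm_fit` with learner id "SRE".
#' @export
fit_sre <- function(training, q = 0.025, variables = NULL) {
  if (q < 0 || q >= 0.5) stop("q must be in [0, 0.5)", call. = FALSE)
  training <- tibble::as_tibble(training)
  if (is.null(variables))
    variables <- setdiff(names(training),
                         c("longitude", "latitude", "label", "species", "source"))
  pres <- training[training$label == 1, , drop = FALSE]
  if (nrow(pres) < 2) stop("need at least 2 presence rows", call. = FALSE)
  env <- purrr::map(variables, function(v) {
    stats::quantile(pres[[v]], c(q, 1 - q), names = FALSE, type = 7)
  })
  names(env) <- variables
  state <- list(envelope = env, variables = variables, q = q)
  structure(list(learner = "SRE", replicate = NA_integer_,
                 variables = variables, state = state,
                 predict_fun = function(state, newdata) sre_score(state, newdata),
                 n_train = nrow(pres)),
            class = "sdm_fit")
}

sre_score <- function(state, newdata) {
  inside <- rep(TRUE, nrow(newdata))
  for (v in state$variables) {
    e <- state$envelope[[v]]
    inside <- inside & newdata[[v]] >= e[1] & newdata[[v]] <= e[2]
  }
  as.numeric(inside)
}

#' Fit any registered learner on a labeled point table
#'
#' @param learner A learner object from [learner_registry()] or a learner id.
#' @param training Labeled point tibble (`label` 0/1 + variable columns).
#' @param variables Predictor variable names.
#' @param replicate Replicate index recorded on the fit.
#' @param seed Integer seed passed to stochastic learners.
#' @return An `sdm_fit` object.
#' @export
fit_learner <- function(learner, training, variables, replicate = NA_integer_,
                        seed = 1) {
  if (is.character(learner)) learner <- learner_registry(learner)[[1]]
  state <- learner$fit(tibble::as_tibble(training), variables, seed = seed)
  structure(list(learner = learner$id, replicate = replicate,
                 variables = variables, state = state,
                 predict_fun = learner$predict,
                 n_train = nrow(training)),
            class = "sdm_fit")
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s (replicate %s) on %s\n", x$learner,
              x$replicate, paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Score new rows with a fitted model
#'
#' @param model An `sdm_fit`.
#' @param newdata Tibble containing the model's variables.
#' @return Numeric scores in `[0, 1]`.
#' @export
score_points <- function(model, newdata) {
  miss <- setdiff(model$variables, names(newdata))
  if (length(miss))
    stop(sprintf("newdata missing variable(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  clip01(model$predict_fun(model$state, tibble::as_tibble(newdata)))
}

#' Project a fitted model over a climate stack
#'
#' Scores every valid cell and returns the result as a suitability map;
#' nodata cells stay NA.
#'
#' @param model An `sdm_fit`.
#' @param stack A [climate_stack()] holding the model's variables.
#' @param species,scenario Labels stored on the output map.
#' @return A [suitability_map()].
#' @export
predict_model <- function(model, stack, species = "species",
                          scenario = "current") {
  miss <- setdiff(model$variables, layer_names(stack))
  if (length(miss))
    stop(sprintf("stack missing variable(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  lin <- which(stack$mask)
  newdata <- tibble::as_tibble(
    purrr::map(stack$layers[model$variables], ~ .x[lin])
  )
  scores <- score_points(model, newdata)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[lin] <- scores
  suitability_map(stack$grid, vals, species = species, scenario = scenario)
}
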