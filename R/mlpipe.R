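#' Absolute Pearson correlation matrix
#'
#' Pairwise absolute Pearson correlations among candidate model variables;
#' the quantity collinearity screening operates on.
#'
#' @param table Data.frame of records.
#' @param variables Columns to correlate (default: all numeric columns).
#' @return Symmetric matrix of `|r|` values in `[0, 1]` with unit diagonal.
#' @export
abs_pearson_matrix <- function(table, variables = NULL) {
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  if (nrow(table) < 3L) .stop_domain("need at least 3 records")
  x <- as.matrix(table[variables])
  const <- variables[apply(x, 2L, function(v) stats::sd(v) == 0)]
  if (length(const)) {
    .stop_domain("correlation undefined for constant column(s): ",
                 paste(const, collapse = ", "))
  }
  m <- abs(stats::cor(x))
  diag(m) <- 1
  m
}

#' Collinearity-based variable selection
#'
#' Iteratively removes collinear variables: while any pair of kept variables
#' has `|r|` above the threshold, the currently worst-offending pair is
#' processed and its member with the lower absolute correlation with the
#' target (D12) is dropped. Ties are broken by a preference order encoding
#' how easy a variable is to obtain for a new system (earlier = preferred).
#' Processing pairs in descending `|r|` makes the result deterministic.
#'
#' @param corr Symmetric matrix of absolute pairwise correlations
#'   (see [abs_pearson_matrix()]).
#' @param target_corr Named vector: absolute Pearson correlation of each
#'   variable with the target.
#' @param threshold Collinearity threshold in (0, 1]; default 0.50.
#' @param preference_order Variable ranking used for ties; defaults to the
#'   order of `target_corr`.
#' @return Object of class `d12_selection`: list with `kept` (ordered names),
#'   `dropped` (data.frame of variable, reason), `threshold`.
#' @export
select_variables <- function(corr, target_corr, threshold = 0.50,
                             preference_order = names(target_corr)) {
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1) {
    .stop_domain("'threshold' must lie in (0, 1]")
  }
  vars <- names(target_corr)
  stopifnot(setequal(rownames(corr), vars))
  corr <- corr[vars, vars, drop = FALSE]
  rank_of <- stats::setNames(seq_along(preference_order), preference_order)
  kept <- vars
  dropped <- list()
  repeat {
    m <- corr[kept, kept, drop = FALSE]
    diag(m) <- 0
    if (length(kept) < 2L || max(m) <= threshold) break
    ij <- which(m == max(m), arr.ind = TRUE)[1L, ]
    pair <- kept[ij]
    tc <- target_corr[pair]
    loser <- if (tc[1L] != tc[2L]) {
      pair[which.min(tc)]
    } else {
      pair[which.max(rank_of[pair])]   # tie: drop the harder-to-obtain one
    }
    winner <- setdiff(pair, loser)
    dropped[[loser]] <- data.frame(
      variable = loser,
      reason = sprintf("collinear with %s (|r| = %.3f, target |r| %.3f vs %.3f)",
                       winner, max(m), target_corr[loser], target_corr[winner]),
      stringsAsFactors = FALSE)
    kept <- setdiff(kept, loser)
  }
  structure(list(kept = kept,
                 dropped = if (length(dropped)) {
                   do.call(rbind, c(dropped, list(make.row.names = FALSE)))
                 } else {
                   data.frame(variable = character(), reason = character())
                 },
                 threshold = threshold),
            class = "d12_selection")
}

#' @export
print.d12_selection <- function(x, ...) {
  cat(sprintf("variable selection at |r| <= %.2f: kept %s\n", x$threshold,
              paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped)) {
    cat("dropped:\n")
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  %s: %s\n", x$dropped$variable[i], x$dropped$reason[i]))
    }
  }
  invisible(x)
}

#' Min-max scaling learned on training data
#'
#' `fit_scaler()` records per-variable (min, max) bounds from training rows;
#' `apply_scaler()` maps values affinely so the training range becomes
#' `[0, 1]`. Test rows falling outside the training range are NOT clipped
#' (the affine map is extended), preserving the models' ability to
#' extrapolate.
#'
#' @param train Data.frame of training rows.
#' @param variables Columns to scale.
#' @return `fit_scaler()`: object of class `d12_scaler` (named list of
#'   `c(min, max)`); `apply_scaler()`: data.frame of scaled columns.
#' @export
fit_scaler <- function(train, variables) {
  bounds <- lapply(variables, function(v) {
    r <- range(train[[v]])
    if (r[1L] == r[2L]) {
      .stop_domain("degenerate (constant) column cannot be scaled: ", v)
    }
    r
  })
  structure(stats::setNames(bounds, variables), class = "d12_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `d12_scaler` from [fit_scaler()].
#' @param records Data.frame carrying the scaler's variables.
#' @export
apply_scaler <- function(scaler, records) {
  stopifnot(inherits(scaler, "d12_scaler"))
  out <- lapply(names(scaler), function(v) {
    if (is.null(records[[v]])) .stop_domain("records lack variable: ", v)
    b <- scaler[[v]]
    (records[[v]] - b[1L]) / (b[2L] - b[1L])
  })
  stats::setNames(as.data.frame(out), names(scaler))
}

#' Declared hyper-parameter grids
#'
#' Loads the hyper-parameter grids shipped as data
#' (`extdata/hyper_grids.json`), one per algorithm. A `max_depth`/`num_trees`
#' entry of 0 means "unlimited".
#'
#' @return Named list of grids (named lists of candidate value vectors).
#' @export
default_grids <- function() {
  path <- system.file("extdata", "hyper_grids.json", package = "tracerdiff",
                      mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

.algorithms <- c("mlr", "knn", "dtree", "rforest", "gboost")

# Validation-fold score: coefficient of determination, with a graceful
# degenerate case — a constant validation fold (zero variance) scores by
# negative squared error so perfect predictions still rank first.
.validation_score <- function(pred, obs) {
  if (length(obs) >= 2L && stats::var(obs) > 0) {
    r_squared(pred, obs)
  } else {
    -sum((obs - pred)^2)
  }
}

.expand_grid <- function(grid) {
  if (length(grid) == 0L) return(list(list()))
  cand <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cand)), function(i) as.list(cand[i, , drop = FALSE]))
}

.fit_algorithm <- function(algorithm, x, y, params, seed) {
  data <- cbind(x, .target = y)
  switch(algorithm,
    mlr = stats::lm(.target ~ ., data = data),
    knn = caret::knnreg(as.matrix(x), y, k = params$k),
    dtree = rpart::rpart(
      .target ~ ., data = data, method = "anova",
      control = rpart::rpart.control(
        maxdepth = if (params$max_depth == 0) 30L else params$max_depth,
        minbucket = params$min_leaf, minsplit = 2L, cp = 0, xval = 0L)),
    rforest = ranger::ranger(
      y = y, x = x,
      num.trees = params$num_trees,
      max.depth = params$max_depth,     # 0 = unlimited in ranger
      mtry = if (identical(params$feature_subset, "sqrt")) {
        max(1L, floor(sqrt(ncol(x))))
      } else ncol(x),
      seed = seed, num.threads = 1L),
    gboost = {
      # Boosting gain thresholds underflow at the 1e-5 cm2 s-1 magnitude of
      # liquid-phase diffusivities, so the booster is fit on the
      # standardized target and predictions are unscaled on the way out.
      y_center <- mean(y)
      y_scale <- stats::sd(y)
      if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
      booster <- xgboost::xgboost(
        x = as.matrix(x), y = (y - y_center) / y_scale,
        nrounds = params$n_stages, learning_rate = params$learning_rate,
        max_depth = params$max_depth, objective = "reg:squarederror",
        verbosity = 0L, nthreads = 1L, seed = seed)
      structure(list(booster = booster, y_center = y_center,
                     y_scale = y_scale), class = "tracerdiff_gboost")
    },
    .stop_domain("unknown algorithm: ", algorithm)
  )
}

.predict_algorithm <- function(algorithm, fit, x) {
  switch(algorithm,
    mlr = unname(stats::predict(fit, newdata = x)),
    knn = unname(stats::predict(fit, newdata = as.matrix(x))),
    dtree = unname(stats::predict(fit, newdata = x)),
    rforest = stats::predict(fit, data = x, num.threads = 1L)$predictions,
    gboost = fit$y_center + fit$y_scale *
      stats::predict(fit$booster, newdata = as.matrix(x))
  )
}

#' Grid-search training with k-fold cross validation
#'
#' Exhaustive search over a declared hyper-parameter grid. For each candidate
#' the mean validation coefficient of determination over `folds`
#' cross-validation folds is computed; the best candidate (ties broken by
#' first-in-grid order) is refit on the full training set. Folds are
#' contiguous blocks after one seeded shuffle, so every training row appears
#' in exactly one validation fold. Input variables are min-max scaled with
#' bounds learned on the fitting rows.
#'
#' @param train Data.frame of training records (must carry `variables` and
#'   the target column).
#' @param algorithm One of `"mlr"`, `"knn"`, `"dtree"`, `"rforest"`,
#'   `"gboost"`.
#' @param variables Predictor columns (typically the `kept` set of a
#'   [select_variables()] result).
#' @param grid Named list of candidate hyper-parameter vectors; defaults to
#'   the packaged grid for the algorithm ([default_grids()]).
#' @param folds Number of cross-validation folds (default 4).
#' @param seed Integer seed controlling fold assignment and any algorithmic
#'   randomness.
#' @param target Target column name (default `"D12"`).
#' @param selection Optional [select_variables()] result stored with the
#'   model for provenance.
#' @return Object of class `d12_model`: algorithm id, tuned `hyper_params`,
#'   `variables`, `scaler`, fitted regressor, `seed`, `cv_score` and the full
#'   `cv_table` of candidate scores.
#' @export
grid_search_train <- function(train, algorithm, variables,
                              grid = default_grids()[[algorithm]],
                              folds = 4L, seed, target = "D12",
                              selection = NULL) {
  algorithm <- match.arg(algorithm, .algorithms)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.null(grid)) .stop_domain("empty grid for algorithm ", algorithm)
  if (nrow(train) < folds) .stop_domain("need at least 'folds' training rows")
  miss <- setdiff(c(variables, target), names(train))
  if (length(miss)) {
    .stop_domain("training data lack column(s): ", paste(miss, collapse = ", "))
  }
  candidates <- .expand_grid(grid)
  if (!length(candidates)) .stop_domain("empty grid for algorithm ", algorithm)

  y <- train[[target]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  shuffled <- sample.int(nrow(train))
  fold_id <- integer(nrow(train))
  fold_id[shuffled] <- cut(seq_along(shuffled), folds, labels = FALSE)

  score_one <- function(params) {
    scores <- vapply(seq_len(folds), function(f) {
      fit_rows <- fold_id != f
      scaler <- fit_scaler(train[fit_rows, , drop = FALSE], variables)
      xs_fit <- apply_scaler(scaler, train[fit_rows, , drop = FALSE])
      xs_val <- apply_scaler(scaler, train[!fit_rows, , drop = FALSE])
      fit <- .fit_algorithm(algorithm, xs_fit, y[fit_rows], params,
                            seed = as.integer(seed) + f)
      pred <- .predict_algorithm(algorithm, fit, xs_val)
      .validation_score(pred, y[!fit_rows])
    }, 0)
    mean(scores)
  }
  cv_scores <- vapply(candidates, score_one, 0)
  best <- which.max(cv_scores)          # ties: first in grid order

  scaler <- fit_scaler(train, variables)
  xs <- apply_scaler(scaler, train)
  fit <- .fit_algorithm(algorithm, xs, y, candidates[[best]],
                        seed = as.integer(seed))
  structure(list(algorithm = algorithm,
                 hyper_params = candidates[[best]],
                 variables = variables,
                 selection = selection,
                 scaler = scaler,
                 fit = fit,
                 seed = as.integer(seed),
                 folds = folds,
                 target = target,
                 cv_score = cv_scores[best],
                 cv_table = data.frame(candidate = seq_along(cv_scores),
                                       cv_r2 = cv_scores)),
            class = "d12_model")
}

#' Train a diffusivity model end to end
#'
#' Convenience wrapper running collinearity-based variable selection on the
#' training set, then [grid_search_train()] on the kept variables.
#'
#' @inheritParams grid_search_train
#' @param candidate_variables Pool of candidate predictors (default: every
#'   property column present in `train` plus `T`, `rho1`, `mu1`).
#' @param threshold Collinearity threshold passed to [select_variables()].
#' @param preference_order Tie-break ranking for selection; defaults to
#'   measured state variables first, Lennard-Jones parameters last.
#' @return A `d12_model` (see [grid_search_train()]).
#' @export
train_d12_model <- function(train, algorithm,
                            candidate_variables = NULL,
                            threshold = 0.50,
                            grid = default_grids()[[algorithm]],
                            folds = 4L, seed, target = "D12",
                            preference_order = NULL) {
  if (is.null(candidate_variables)) {
    candidate_variables <- intersect(c("T", "rho1", "mu1", .prop_cols),
                                     names(train))
  }
  if (is.null(preference_order)) preference_order <- candidate_variables
  corr <- abs_pearson_matrix(train, candidate_variables)
  tcor <- vapply(candidate_variables,
                 function(v) abs(stats::cor(train[[v]], train[[target]])), 0)
  sel <- select_variables(corr, tcor, threshold = threshold,
                          preference_order = preference_order)
  grid_search_train(train, algorithm, variables = sel$kept, grid = grid,
                    folds = folds, seed = seed, target = target,
                    selection = sel)
}

#' Predict D12 with a trained model
#'
#' Applies the stored variable selection, scaler and regressor to new
#' records. Deterministic given the model object.
#'
#' @param object A `d12_model`.
#' @param newdata Data.frame carrying the model's selected variables.
#' @param ... Unused.
#' @return Numeric vector of predicted D12, cm2 s-1, one per row.
#' @export
predict.d12_model <- function(object, newdata, ...) {
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss)) {
    .stop_domain("records lack model variable(s): ", paste(miss, collapse = ", "))
  }
  xs <- apply_scaler(object$scaler, newdata)
  .predict_algorithm(object$algorithm, object$fit, xs)
}

#' @export
print.d12_model <- function(x, ...) {
  hp <- if (length(x$hyper_params)) {
    paste(names(x$hyper_params), unlist(x$hyper_params), sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("D12 model [%s]: variables %s; hyper-parameters: %s; CV R2 = %.4f (seed %d)\n",
              x$algorithm, paste(x$variables, collapse = ", "), hp,
              x$cv_score, x$seed))
  invisible(x)
}

#' Serialize a trained model
#'
#' `write_d12_model()` stores the regressor as an opaque blob (`.rds`) next
#' to a human-readable JSON sidecar carrying algorithm, tuned grid point,
#' selected variables, scaler bounds and seed. `read_d12_model()` restores
#' the model.
#'
#' @param model A `d12_model`.
#' @param path Path of the model blob; the sidecar gets extension `.json`.
#' @return `path`, invisibly (`read_d12_model()` returns the model).
#' @export
write_d12_model <- function(model, path) {
  stopifnot(inherits(model, "d12_model"))
  saveRDS(model, path)
  sidecar <- list(algorithm = model$algorithm,
                  hyper_params = model$hyper_params,
                  variables = model$variables,
                  scaler = lapply(unclass(model$scaler), as.numeric),
                  seed = model$seed,
                  cv_score = model$cv_score,
                  schema = .schema_version)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_d12_model
#' @export
read_d12_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "d12_model"))
  model
}

#' y-randomization (y-scrambling) validation
#'
#' Repeats the identical model-building procedure on training sets whose
#' target vector has been randomly permuted (the predictors are untouched),
#' scoring each rebuilt model on the untouched test set. If the original
#' model's external score is far above the permuted distribution, its
#' performance cannot be an artifact of chance correlation.
#'
#' @inheritParams grid_search_train
#' @param test Test records scored with each rebuilt model.
#' @param n_perm Number of permutations (the reference protocol uses 200).
#' @return Object of class `d12_yrand`: list with `original_q2` and the
#'   vector `permuted_q2` of length `n_perm`.
#' @export
y_randomization <- function(train, test, algorithm, variables,
                            grid = default_grids()[[algorithm]],
                            folds = 4L, n_perm = 200L, seed, target = "D12") {
  if (!is.numeric(n_perm) || n_perm < 1L) .stop_domain("'n_perm' must be >= 1")
  model <- grid_search_train(train, algorithm, variables, grid = grid,
                             folds = folds, seed = seed, target = target)
  q2_of <- function(m) r_squared(predict(m, test), test[[target]])
  original <- q2_of(model)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  permuted <- vapply(seq_len(n_perm), function(p) {
    set.seed(as.integer(seed) + p)
    shuffled <- train
    shuffled[[target]] <- sample(train[[target]])
    q2_of(grid_search_train(shuffled, algorithm, variables, grid = grid,
                            folds = folds, seed = seed, target = target))
  }, 0)
  structure(list(original_q2 = original, permuted_q2 = permuted,
                 algorithm = algorithm, n_perm = as.integer(n_perm)),
            class = "d12_yrand")
}

#' @export
print.d12_yrand <- function(x, ...) {
  cat(sprintf("y-randomization [%s]: original Q2 = %.4f; %d permutations, Q2 max = %.4f, median = %.4f\n",
              x$algorithm, x$original_q2, x$n_perm,
              max(x$permuted_q2), stats::median(x$permuted_q2)))
  invisible(x)
}
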