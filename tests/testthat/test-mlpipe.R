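test_that("absolute Pearson matrix is symmetric, unit-diagonal and sign-blind", {
  df <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4), z = -c(1, 2, 3))
  m <- abs_pearson_matrix(df)
  expect_equal(diag(m), c(x = 1, y = 1, z = 1))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m["x", "z"], 1)              # |corr(x, -x)| = 1
  expect_equal(m["x", "y"], 0.982, tolerance = 1e-3) # hand Pearson
  expect_error(abs_pearson_matrix(data.frame(x = c(1, 2, 3), k = c(5, 5, 5))),
               "constant column.*k")
  expect_error(abs_pearson_matrix(df[1:2, ]), "at least 3")
})

test_that("collinear pairs are resolved in favour of the target-correlated member", {
  # duplicated column: the one with lower target correlation is dropped
  corr <- matrix(c(1, 1, 0.2,
                   1, 1, 0.2,
                   0.2, 0.2, 1), 3, 3,
                 dimnames = list(c("a", "a2", "b"), c("a", "a2", "b")))
  sel <- select_variables(corr, c(a = 0.9, a2 = 0.6, b = 0.4))
  expect_setequal(sel$kept, c("a", "b"))
  expect_equal(sel$dropped$variable, "a2")
  expect_match(sel$dropped$reason, "collinear with a")
  # all below threshold: no-op
  corr2 <- matrix(c(1, 0.3, 0.3, 1), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  sel2 <- select_variables(corr2, c(a = 0.9, b = 0.1))
  expect_setequal(sel2$kept, c("a", "b"))
  expect_equal(nrow(sel2$dropped), 0L)
  # ties on target correlation fall back to the preference order
  sel3 <- select_variables(corr, c(a = 0.5, a2 = 0.5, b = 0.4),
                           preference_order = c("a2", "a", "b"))
  expect_true("a2" %in% sel3$kept)
  expect_false("a" %in% sel3$kept)
  expect_error(select_variables(corr, c(a = 1, a2 = 1, b = 1), threshold = 0),
               "threshold")
})

test_that("selection leaves no kept pair above the threshold (post hoc invariant)", {
  rec <- generate_dataset(generator_spec(n_systems = 40, seed = 21,
                                         mechanism = "nonlinear_gboost_target"))
  rec <- inject_collinearity(rec, list(
    T_dup = list(source = "T", slope = 2, intercept = -50, noise_sd = 0),
    M2_noisy = list(source = "M2", slope = 1, intercept = 0, noise_sd = 5)
  ), seed = 3)
  vars <- c(nonpolar_variables, "T_dup", "M2_noisy", "eps1")
  corr <- abs_pearson_matrix(rec, vars)
  tcor <- vapply(vars, function(v) abs(cor(rec[[v]], rec$D12)), 0)
  sel <- select_variables(corr, tcor, threshold = 0.50)
  kept_corr <- corr[sel$kept, sel$kept]
  diag(kept_corr) <- 0
  expect_lte(max(kept_corr), 0.50)
  # the planted exact duplicate conflicts with T: exactly one of them survives
  expect_equal(sum(c("T", "T_dup") %in% sel$kept), 1L)
})

test_that("min-max scaler maps the training range onto [0,1] without clipping", {
  train <- data.frame(a = c(2, 4, 6), b = c(0, 5, 10))
  sc <- fit_scaler(train, c("a", "b"))
  scaled <- apply_scaler(sc, train)
  expect_equal(scaled$a, c(0, 0.5, 1))
  expect_true(all(scaled$b >= 0 & scaled$b <= 1))
  expect_equal(apply_scaler(sc, data.frame(a = 8, b = 5))$a, 1.5) # no clipping
  expect_equal(apply_scaler(sc, data.frame(a = -2, b = 5))$a, -1)
  expect_error(fit_scaler(data.frame(a = c(3, 3, 3)), "a"), "degenerate")
  expect_error(apply_scaler(sc, data.frame(a = 1)), "lack variable")
})

test_that("grid search respects the declared grid and the fold partition", {
  rec <- generate_dataset(generator_spec(n_systems = 20, seed = 5,
                                         mechanism = "nonlinear_gboost_target",
                                         noise_cv = 0.05))
  grids <- default_grids()
  m <- grid_search_train(rec, "knn", nonpolar_variables,
                         grid = grids$knn, seed = 17)
  expect_true(m$hyper_params$k %in% grids$knn$k)
  expect_equal(nrow(m$cv_table), length(grids$knn$k))
  m2 <- grid_search_train(rec, "dtree", nonpolar_variables,
                          grid = list(max_depth = c(2L, 4L), min_leaf = c(1L, 3L)),
                          seed = 17)
  expect_true(m2$hyper_params$max_depth %in% c(2L, 4L))
  expect_true(m2$hyper_params$min_leaf %in% c(1L, 3L))
  expect_error(grid_search_train(rec, "gboost", nonpolar_variables,
                                 grid = NULL, seed = 1), "empty grid")
})

test_that("multilinear regression on exactly affine data validates perfectly", {
  set.seed(8)
  n <- 60
  rec <- data.frame(T = runif(n, 280, 500), mu1 = runif(n, 0.3, 3),
                    M2 = runif(n, 50, 500))
  rec$D12 <- 1e-7 * rec$T - 2e-6 * rec$mu1 + 1e-8 * rec$M2 + 3e-5
  m <- grid_search_train(rec, "mlr", c("T", "mu1", "M2"), grid = list(),
                         seed = 2)
  expect_equal(m$cv_score, 1, tolerance = 1e-9)
  expect_equal(predict(m, rec), rec$D12, tolerance = 1e-9)
})

test_that("1-nearest-neighbour memorizes the training set", {
  rec <- generate_dataset(generator_spec(n_systems = 10, seed = 6))
  m <- grid_search_train(rec, "knn", nonpolar_variables,
                         grid = list(k = 1L), seed = 3)
  expect_equal(predict(m, rec), rec$D12, tolerance = 1e-12)
})

test_that("the train-predict path is reproducible under a fixed seed", {
  rec <- generate_dataset(generator_spec(n_systems = 25, seed = 10,
                                         mechanism = "nonlinear_gboost_target"))
  sp <- split_train_test(rec, 0.7, seed = 10)
  for (alg in c("rforest", "gboost")) {
    m1 <- grid_search_train(sp$train, alg, nonpolar_variables,
                            grid = fast_grids[[alg]], seed = 42)
    m2 <- grid_search_train(sp$train, alg, nonpolar_variables,
                            grid = fast_grids[[alg]], seed = 42)
    expect_identical(predict(m1, sp$test), predict(m2, sp$test), label = alg)
    expect_identical(m1$cv_score, m2$cv_score, label = alg)
  }
})

test_that("prediction is a row-wise map and validates its inputs", {
  rec <- generate_dataset(generator_spec(n_systems = 15, seed = 12))
  m <- grid_search_train(rec, "gboost", nonpolar_variables,
                         grid = fast_grids$gboost, seed = 1)
  idx <- rev(seq_len(20))
  expect_equal(predict(m, rec[idx, ]), predict(m, rec[1:20, ])[idx])
  expect_error(predict(m, rec[, c("T", "mu1")]), "M2")
})

test_that("every algorithm predicts a constant when trained on a constant target", {
  rec <- generate_dataset(generator_spec(n_systems = 12, seed = 14))
  rec$D12 <- 5e-6
  for (alg in c("knn", "dtree", "rforest", "gboost")) {
    m <- grid_search_train(rec, alg, nonpolar_variables,
                           grid = fast_grids[[alg]], seed = 2)
    expect_equal(predict(m, rec[1:15, ]), rep(5e-6, 15), tolerance = 1e-6,
                 label = alg)
  }
})

test_that("y-randomization returns the requested number of scores and separates signal", {
  rec <- generate_dataset(generator_spec(n_systems = 30, seed = 31,
                                         mechanism = "nonlinear_gboost_target",
                                         noise_cv = 0.10))
  sp <- split_train_test(rec, 0.7, seed = 31)
  yr <- y_randomization(sp$train, sp$test, "mlr", nonpolar_variables,
                        grid = list(), n_perm = 25, seed = 7)
  expect_length(yr$permuted_q2, 25L)
  expect_true(all(yr$permuted_q2 < yr$original_q2))
  expect_error(y_randomization(sp$train, sp$test, "mlr", nonpolar_variables,
                               grid = list(), n_perm = 0, seed = 7), "n_perm")
})

test_that("y-randomization on a pure-noise target shows no signal to destroy", {
  set.seed(99)
  rec <- generate_dataset(generator_spec(n_systems = 30, seed = 32))
  rec$D12 <- exp(runif(nrow(rec), log(1e-6), log(1e-4))) # independent of X
  sp <- split_train_test(rec, 0.7, seed = 32)
  yr <- y_randomization(sp$train, sp$test, "mlr", nonpolar_variables,
                        grid = list(), n_perm = 40, seed = 8)
  # the original score sits inside the permuted distribution
  rank_frac <- mean(yr$permuted_q2 < yr$original_q2)
  expect_gt(rank_frac, 0.025)
  expect_lt(rank_frac, 0.975)
})

test_that("model serialization roundtrips and writes a readable sidecar", {
  rec <- generate_dataset(generator_spec(n_systems = 15, seed = 18))
  m <- train_d12_model(rec, "gboost", grid = fast_grids$gboost, seed = 4)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.rds")
  write_d12_model(m, path)
  back <- read_d12_model(path)
  expect_equal(predict(back, rec[1:10, ]), predict(m, rec[1:10, ]))
  side <- jsonlite::fromJSON(file.path(dir, "model.json"))
  expect_equal(side$algorithm, "gboost")
  expect_setequal(side$variables, m$variables)
  expect_equal(side$seed, 4)
})
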