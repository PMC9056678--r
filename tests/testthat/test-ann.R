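# small synthetic regression problem shared across the model tests
make_linear_problem <- function(n = 100, p = 12, noise = 0.2, seed = 41) {
  withr::with_seed(seed, {
    X <- matrix(rpois(n * p, 3), n, p)
    colnames(X) <- paste0("b", seq_len(p))
    beta <- rnorm(p) * (runif(p) < 0.5)
    y <- drop(X %*% beta) + rnorm(n, sd = noise)
    list(X = X, y = y, beta = beta)
  })
}

test_that("ann_spec validates and round-trips through its list form", {
  spec <- ann_spec(hidden = c(97, 24), batch_norm = TRUE, activation = "relu",
                   optimizer = "RMSprop", l2_lambda = 0.001, dropout = 0.03)
  expect_identical(spec$batch_norm, c(TRUE, TRUE))
  expect_identical(spec_from_list(spec_to_list(spec)), spec)

  expect_error(ann_spec(hidden = 0), "positive")
  expect_error(ann_spec(hidden = 8, epochs = 0), "positive integer")
  expect_error(ann_spec(hidden = 8, dropout = 1), "dropout")
  expect_error(ann_spec(hidden = 8, l2_lambda = -1), "l2_lambda")
  expect_error(ann_spec(hidden = 8, activation = "gelu"))
})

test_that("a full-width melting-point-style spec trains without error", {
  # 105 pruned descriptor columns, single batch-normalized tanh layer of the
  # same width, RMSprop with strong L2 and light dropout
  spec <- ann_spec(hidden = 105, batch_norm = TRUE, activation = "tanh",
                   optimizer = "RMSprop", l2_lambda = 0.1, dropout = 0.01,
                   epochs = 10)
  withr::with_seed(77, {
    X <- matrix(rpois(120 * 105, 2), 120, 105)
    colnames(X) <- paste0("bit", 1:105)
    y <- rnorm(120, mean = 400, sd = 300)
  })
  fit <- train_ann(spec, X, y, seed = 1)
  p <- predict(fit, X)
  expect_true(all(is.finite(p)))
  expect_length(p, 120L)
})

test_that("training is reproducible and inference deterministic", {
  prob <- make_linear_problem(n = 60)
  spec <- ann_spec(hidden = 16, activation = "relu", optimizer = "Adam",
                   dropout = 0.1, epochs = 40)
  f1 <- train_ann(spec, prob$X, prob$y, seed = 5)
  f2 <- train_ann(spec, prob$X, prob$y, seed = 5)
  expect_identical(predict(f1, prob$X), predict(f2, prob$X))
  # dropout is disabled at inference: repeated prediction identical
  expect_identical(predict(f1, prob$X), predict(f1, prob$X))
  # single-row input
  expect_length(predict(f1, prob$X[1, , drop = FALSE]), 1L)
  # different seed changes the fit
  f3 <- train_ann(spec, prob$X, prob$y, seed = 6)
  expect_false(identical(predict(f1, prob$X), predict(f3, prob$X)))
})

test_that("a wide unregularized layer fits a linear target well", {
  prob <- make_linear_problem(n = 100, noise = 0)
  spec <- ann_spec(hidden = 48, batch_norm = TRUE, activation = "relu",
                   optimizer = "Adam", l2_lambda = 0, dropout = 0,
                   epochs = 250)
  fit <- train_ann(spec, prob$X, prob$y, seed = 2)
  train_mae <- mae(prob$y, predict(fit, prob$X))
  expect_lt(train_mae, 0.05 * diff(range(prob$y)))
})

test_that("constant targets are learned as constants", {
  prob <- make_linear_problem(n = 40)
  y_const <- rep(3.5, 40)
  spec <- ann_spec(hidden = 8, activation = "tanh", epochs = 150)
  fit <- train_ann(spec, prob$X, y_const, seed = 1)
  expect_lt(max(abs(predict(fit, prob$X) - 3.5)), 0.2)
})

test_that("stronger L2 regularization does not improve training fit", {
  prob <- make_linear_problem(n = 80)
  fit_of <- function(lam) {
    spec <- ann_spec(hidden = 24, activation = "relu", l2_lambda = lam,
                     dropout = 0, epochs = 150)
    fit <- train_ann(spec, prob$X, prob$y, seed = 3)
    mean((prob$y - predict(fit, prob$X))^2)
  }
  expect_gte(fit_of(0.1), fit_of(0.001))
})

test_that("prediction enforces column alignment", {
  prob <- make_linear_problem(n = 30)
  spec <- ann_spec(hidden = 4, epochs = 5)
  fit <- train_ann(spec, prob$X, prob$y, seed = 1)
  shuffled <- prob$X[, rev(colnames(prob$X))]
  expect_error(predict(fit, shuffled), "do not match")
  expect_error(predict(fit, unname(prob$X)[, 1:3]), "expects")
})

test_that("grid search reuses folds, ranks dominating specs first", {
  prob <- make_linear_problem(n = 90)
  good <- ann_spec(hidden = 32, batch_norm = TRUE, activation = "relu",
                   optimizer = "Adam")
  bad <- ann_spec(hidden = 1, batch_norm = FALSE, activation = "sigmoid",
                  optimizer = "RMSprop", l2_lambda = 10, dropout = 0.8)

  single <- grid_search_cv(list(good), prob$X, prob$y, folds = 3, seed = 9,
                           epochs = 60)
  expect_length(single$results, 1L)
  expect_identical(format(best_spec(single)$hidden), format(good$hidden))

  cv <- grid_search_cv(list(bad, good), prob$X, prob$y, folds = 3, seed = 9,
                       epochs = 60)
  expect_identical(best_spec(cv)$hidden, good$hidden)

  # spec order must not affect per-spec CV means (shared fold partition)
  cv_flip <- grid_search_cv(list(good, bad), prob$X, prob$y, folds = 3,
                            seed = 9, epochs = 60)
  mean_of <- function(cvr, width) {
    for (r in cvr$results) if (r$spec$hidden[1] == width) return(r$mean)
  }
  expect_equal(mean_of(cv, 32), mean_of(cv_flip, 32), tolerance = 1e-12)
  expect_equal(mean_of(cv, 1), mean_of(cv_flip, 1), tolerance = 1e-12)

  expect_error(grid_search_cv(list(), prob$X, prob$y), "non-empty")
  expect_error(grid_search_cv(list(good), prob$X, prob$y, folds = 1000),
               "more folds")
})

test_that("baseline adapters honour their contracts", {
  prob <- make_linear_problem(n = 60)
  rf1 <- train_baseline("RFR", list(tree = 100), prob$X, prob$y, seed = 4)
  rf2 <- train_baseline("RFR", list(tree = 100), prob$X, prob$y, seed = 4)
  expect_identical(predict(rf1, prob$X), predict(rf2, prob$X))

  # epsilon wider than the centered y-range: nothing leaves the tube
  yc <- prob$y - mean(prob$y)
  sv <- train_baseline("SVM", list(gamma = "auto", C = 10,
                                   epsilon = diff(range(yc)) * 2),
                       prob$X, yc)
  expect_lt(stats::sd(predict(sv, prob$X)), 0.05 * stats::sd(yc))

  expect_error(train_baseline("GBM", list(), prob$X, prob$y),
               "unsupported baseline")
})

test_that("evaluate_external reports per-partition metrics and ranges", {
  ds <- generate_dataset(synthetic_spec(n_compounds = 120, seed = 8,
                                        noise_frac = 0.02))
  split <- split_dataset(ds, ratio = 0.2, seed = 2)
  X <- featurize_table(split$train$formula)
  pr <- prune_constant_bits(X)
  spec <- ann_spec(hidden = 24, batch_norm = TRUE, activation = "relu",
                   optimizer = "Adam", epochs = 150)
  fit <- train_ann(spec, pr$matrix, split$train$value, seed = 1)
  rep <- evaluate_external(fit, split)
  expect_s3_class(rep$train, "metric_report")
  expect_s3_class(rep$test, "metric_report")
  expect_equal(rep$test$endpoint_range, range(split$test$value))
  expect_gt(rep$train$r_squared, rep$test$r_squared - 0.5) # sanity, not tuned

  empty <- split
  empty$test <- empty$test[0, ]
  expect_error(evaluate_external(fit, empty), "empty test set")
})

test_that("epoch-size selection returns the budget with lowest test MAE", {
  prob <- make_linear_problem(n = 80)
  tr <- 1:64; te <- 65:80
  spec <- ann_spec(hidden = 16, activation = "relu")
  sel <- select_epochs(spec, prob$X[tr, ], prob$y[tr],
                       prob$X[te, ], prob$y[te],
                       epoch_grid = c(30L, 120L), seed = 1)
  expect_identical(nrow(sel$table), 2L)
  expect_identical(sel$best_epochs,
                   as.integer(sel$table$epochs[which.min(sel$table$mae)]))
  expect_s3_class(sel$best_fit, "econf_ann")
})
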