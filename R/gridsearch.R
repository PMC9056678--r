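# Cross-validated hyperparameter search, baseline regressors, and
# external-test evaluation.

.cv_folds <- function(n, folds, seed) {
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (folds > n) stop("more folds than observations", call. = FALSE)
  withr::with_seed(as.integer(seed), sample(rep_len(seq_len(folds), n)))
}

.fit_metrics <- function(y_obs, y_hat) {
  c(r_squared = r_squared(y_obs, y_hat),
    spearman = spearman_rank(y_obs, y_hat),
    mae = mae(y_obs, y_hat))
}

#' Cross-validation grid search over network specifications
#'
#' Evaluates every specification on one shared fold partition and ranks them.
#' During the search every spec is trained for a fixed number of epochs
#' (default 500); the epoch count stored in each spec is ignored. The ranking
#' key is mean CV MAE, with ties broken by mean Spearman correlation, then
#' mean R2.
#'
#' @param space List of [ann_spec()] objects.
#' @param X Descriptor matrix.
#' @param y Target vector.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed: fixes the fold partition and the per-fold
#'   training seeds, shared across all specs.
#' @param epochs Epochs used for every spec during the search.
#' @return Object of class `econf_cv`: list of per-spec results (spec,
#'   per-fold metrics, mean/sd of R2, SpeaR, MAE, and mean MAE as percent of
#'   the full y range), ordered best first.
#' @export
grid_search_cv <- function(space, X, y, folds = 5L, seed = 0L, epochs = 500L) {
  if (!is.list(space) || length(space) == 0L ||
      !all(vapply(space, inherits, logical(1), "ann_spec"))) {
    stop("space must be a non-empty list of ann_spec objects", call. = FALSE)
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  fold_id <- .cv_folds(nrow(X), folds, seed)
  y_range <- diff(range(y))

  results <- lapply(seq_along(space), function(si) {
    spec <- space[[si]]
    spec$epochs <- as.integer(epochs)
    fold_metrics <- t(vapply(seq_len(max(fold_id)), function(k) {
      tr <- fold_id != k
      fit <- train_ann(spec, X[tr, , drop = FALSE], y[tr],
                       seed = as.integer(seed) + k)
      .fit_metrics(y[!tr], predict(fit, X[!tr, , drop = FALSE]))
    }, numeric(3)))
    list(spec = spec,
         folds = fold_metrics,
         mean = colMeans(fold_metrics),
         sd = apply(fold_metrics, 2L, stats::sd),
         mae_over_range = 100 * mean(fold_metrics[, "mae"]) / y_range)
  })

  key <- sapply(results, function(r) r$mean[["mae"]])
  tie1 <- -sapply(results, function(r) r$mean[["spearman"]])
  tie2 <- -sapply(results, function(r) r$mean[["r_squared"]])
  results <- results[order(key, tie1, tie2)]
  structure(list(results = results, folds = folds, seed = as.integer(seed),
                 epochs = as.integer(epochs)),
            class = "econf_cv")
}

#' @export
print.econf_cv <- function(x, ...) {
  cat(sprintf("%d specs, %d-fold CV (seed %d, %d epochs)\n",
              length(x$results), x$folds, x$seed, x$epochs))
  for (r in x$results) {
    cat(sprintf("  [%s]\n    R2 %.2f+-%.2f  SpeaR %.2f+-%.2f  MAE %.4g+-%.3g (%.2f%% of range)\n",
                format(r$spec), r$mean["r_squared"], r$sd["r_squared"],
                r$mean["spearman"], r$sd["spearman"],
                r$mean["mae"], r$sd["mae"], r$mae_over_range))
  }
  invisible(x)
}

#' Best specification from a grid search
#' @param cv An `econf_cv`.
#' @return The top-ranked `ann_spec`.
#' @export
best_spec <- function(cv) {
  stopifnot(inherits(cv, "econf_cv"))
  cv$results[[1L]]$spec
}

#' Baseline regressors (support vector machine, random forest)
#'
#' Thin adapters over `e1071::svm` (eps-regression, radial kernel) and
#' `randomForest::randomForest`, exposing the same predict contract as the
#' network. The SVM `gamma` option mirrors the common conventions:
#' `"auto"` is `1/ncol(X)`, `"scale"` is `1/(ncol(X) * var(X))`.
#'
#' @param kind `"SVM"` or `"RFR"`.
#' @param params For SVM: list with `gamma` (`"auto"`, `"scale"` or numeric),
#'   `C`, `epsilon`. For RFR: list with `tree` (number of trees).
#' @param X Descriptor matrix.
#' @param y Target vector.
#' @param seed Integer seed (random forest only; SVM fitting is
#'   deterministic).
#' @return Object of class `econf_baseline`.
#' @export
train_baseline <- function(kind, params, X, y, seed = 0L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  fit <- switch(kind,
    SVM = {
      gamma <- params$gamma %||% "auto"
      if (identical(gamma, "auto")) {
        gamma <- 1 / ncol(X)
      } else if (identical(gamma, "scale")) {
        v <- stats::var(as.vector(X))
        gamma <- 1 / (ncol(X) * if (v > 0) v else 1)
      }
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 gamma = gamma, cost = params$C %||% 1,
                 epsilon = params$epsilon %||% 0.1, scale = FALSE,
                 fitted = FALSE)
    },
    RFR = withr::with_seed(as.integer(seed), {
      randomForest::randomForest(x = X, y = y, ntree = params$tree %||% 500)
    }),
    stop("unsupported baseline kind '", kind, "'; use \"SVM\" or \"RFR\"",
         call. = FALSE)
  )
  structure(list(kind = kind, fit = fit, columns = colnames(X),
                 params = params, seed = as.integer(seed)),
            class = "econf_baseline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
predict.econf_baseline <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  .check_columns(object$columns, X)
  if (object$kind == "SVM" && object$fit$tot.nSV == 0L) {
    # every residual fell inside the epsilon tube: the regression function is
    # the constant intercept
    return(rep(-object$fit$rho, nrow(X)))
  }
  unname(stats::predict(object$fit, X))
}

#' @export
print.econf_baseline <- function(x, ...) {
  cat("econf_baseline:", x$kind, "\n")
  invisible(x)
}

#' Evaluate a model on an external train/test split
#'
#' Featurizes both partitions of the split, aligns the descriptor columns to
#' the model's training columns, and reports R2, Spearman correlation and MAE
#' per partition together with each partition's own endpoint range and MAE as
#' a percentage of that range.
#'
#' @param model A trained `econf_ann` or `econf_baseline`.
#' @param split A [split_dataset()] whose records carry `formula` and `value`.
#' @return Object of class `external_report`: list with `train` and `test`
#'   [metric_report()]s.
#' @export
evaluate_external <- function(model, split) {
  stopifnot(inherits(split, "split_dataset"))
  if (nrow(split$test) == 0L) stop("empty test set", call. = FALSE)
  part_report <- function(records) {
    Xf <- featurize_table(records$formula)
    X <- align_columns(Xf, model$columns)
    metric_report(records$value, predict(model, X))
  }
  rep <- list(train = part_report(split$train), test = part_report(split$test))
  class(rep) <- "external_report"
  rep
}

#' @export
print.external_report <- function(x, ...) {
  cat("train: "); print(x$train)
  cat("test:  "); print(x$test)
  invisible(x)
}

#' Epoch-size selection against the external test set
#'
#' Retrains the selected specification at several epoch budgets and reports
#' external-test accuracy for each, returning the budget with the lowest test
#' MAE. Note this deliberately uses the test set to pick the epoch count —
#' a form of test-set-informed model selection; the resulting test metrics
#' are therefore mildly optimistic.
#'
#' @param spec An [ann_spec()].
#' @param X_train,y_train Training data.
#' @param X_test,y_test External test data.
#' @param epoch_grid Integer vector of epoch budgets to try.
#' @param seed Training seed (shared across budgets).
#' @return List with `table` (one row per budget: epochs, test R2, SpeaR,
#'   MAE), `best_epochs`, and `best_fit`.
#' @export
select_epochs <- function(spec, X_train, y_train, X_test, y_test,
                          epoch_grid = c(200L, 500L), seed = 0L) {
  rows <- lapply(epoch_grid, function(ep) {
    sp <- spec
    sp$epochs <- as.integer(ep)
    fit <- train_ann(sp, X_train, y_train, seed = seed)
    m <- .fit_metrics(y_test, predict(fit, X_test))
    list(fit = fit, row = c(epochs = ep, m))
  })
  tab <- as.data.frame(do.call(rbind, lapply(rows, `[[`, "row")))
  best <- which.min(tab$mae)
  list(table = tab, best_epochs = as.integer(tab$epochs[best]),
       best_fit = rows[[best]]$fit)
}
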