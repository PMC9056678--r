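# Model and dataset interpretation: layer-wise PCA of the first hidden
# block, mean absolute error binned over the endpoint range, and
# periodic-table element-coverage accounting.

# centered, unscaled 2-component PCA with a deterministic sign convention:
# in each component the largest-magnitude loading is positive
.pca_scores2 <- function(mat) {
  k <- min(2L, ncol(mat), nrow(mat) - 1L)
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE, rank. = k)
  for (j in seq_len(ncol(p$rotation))) {
    i_max <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i_max, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x, sdev = p$sdev[seq_len(k)])
}

#' Layer-wise feature-space traces of the first hidden block
#'
#' Runs the descriptor matrix through the first hidden block of a trained
#' network and returns the feature matrix at each stage together with its
#' 2-component PCA scores: the raw input, the fully connected (linear)
#' output, the batch-norm output (inference statistics; omitted with a notice
#' when the first layer carries no batch norm) and the activation output.
#' Stages follow the network's computation order (the batch-norm layer sits
#' between the linear map and the activation). Comparing the PCA score plots
#' stage by stage shows how the network rearranges compounds in feature space
#' as the property signal emerges.
#'
#' @param model A trained `econf_ann`.
#' @param X Descriptor matrix aligned to the model's columns.
#' @return Named list of `layer_trace` objects (`input`, `linear`,
#'   `batch_norm` if present, `activation`), each with `stage`, `features`,
#'   `pc_scores`, `pc_sdev`.
#' @export
layer_outputs <- function(model, X) {
  stopifnot(inherits(model, "econf_ann"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  .check_columns(model$columns, X)
  fw <- .ann_forward(model, X, trace_first_block = TRUE)

  stages <- c(list(input = X), fw$trace)
  if (!model$spec$batch_norm[1L]) {
    message("first hidden layer has no batch-norm; batch_norm stage omitted")
  }
  order_wanted <- c("input", "linear", "batch_norm", "activation")
  stages <- stages[intersect(order_wanted, names(stages))]
  lapply(names(stages), function(nm) {
    p <- .pca_scores2(stages[[nm]])
    structure(list(stage = nm, features = stages[[nm]],
                   pc_scores = p$scores, pc_sdev = p$sdev),
              class = "layer_trace")
  }) |> stats::setNames(names(stages))
}

#' Mean absolute error binned over the endpoint range
#'
#' Partitions `[min(y_exp), max(y_exp)]` into consecutive bins of the given
#' width (the last bin absorbs the maximum) and reports the mean absolute
#' prediction error and record count per bin. Typical widths: 100 for a
#' boiling-point scale in degrees C, 50 for melting/pyrolysis points, 0.5
#' for logS.
#'
#' @param y_exp Observed values.
#' @param y_pred Predicted values.
#' @param bin_width Positive bin width in endpoint units.
#' @return Data.frame with `bin_low`, `bin_high`, `count`, `mean_abs_error`
#'   (NA for empty bins).
#' @export
error_by_range <- function(y_exp, y_pred, bin_width) {
  .check_pair(y_exp, y_pred)
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  lo <- min(y_exp)
  hi <- max(y_exp)
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  idx <- findInterval(y_exp, breaks, rightmost.closed = TRUE)
  abs_err <- abs(y_exp - y_pred)
  nb <- max(idx)
  data.frame(
    bin_low = breaks[seq_len(nb)],
    bin_high = breaks[seq_len(nb) + 1L],
    count = vapply(seq_len(nb), function(b) sum(idx == b), integer(1)),
    mean_abs_error = vapply(seq_len(nb), function(b) {
      if (any(idx == b)) mean(abs_err[idx == b]) else NA_real_
    }, numeric(1))
  )
}

#' Periodic-table element coverage of a split
#'
#' Codes every element Z = 1..104 by where it occurs among the formulas of a
#' train/test split: 3 when present in both partitions, 2 in the training set
#' only, 1 in the test set only, 0 absent. Also reports the number of
#' distinct elements covered and that number as a percentage of the 104
#' supported elements — the compositional applicability domain of a model
#' fitted on the split.
#'
#' @param split A [split_dataset()] with `formula` columns.
#' @return Object of class `coverage_table`: data.frame (`symbol`, `z`,
#'   `code`) with attributes `n_elements` and `percent`.
#' @export
periodic_coverage <- function(split) {
  stopifnot(inherits(split, "split_dataset"))
  elements_of <- function(formulas) {
    if (length(formulas) == 0L) return(character(0))
    unique(unlist(lapply(formulas, function(f) names(parse_formula(f)))))
  }
  in_train <- .econf_symbols %in% elements_of(split$train$formula)
  in_test <- .econf_symbols %in% elements_of(split$test$formula)
  code <- ifelse(in_train & in_test, 3L,
                 ifelse(in_train, 2L, ifelse(in_test, 1L, 0L)))
  out <- data.frame(symbol = .econf_symbols, z = seq_along(.econf_symbols),
                    code = code, stringsAsFactors = FALSE)
  attr(out, "n_elements") <- sum(code > 0L)
  attr(out, "percent") <- 100 * sum(code > 0L) / .econf_z_max
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("element coverage: %d / %d elements (%.1f%%)\n",
              attr(x, "n_elements"), .econf_z_max, attr(x, "percent")))
  present <- x$symbol[x$code > 0L]
  cat("  both:", sum(x$code == 3L), " train-only:", sum(x$code == 2L),
      " test-only:", sum(x$code == 1L), "\n")
  invisible(x)
}
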