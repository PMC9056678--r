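# Evaluation metrics: coefficient of determination, mean absolute error,
# Spearman rank correlation, and the acceptable-prediction count used to
# judge model transferability.

.check_pair <- function(y_exp, y_pred, min_n = 1L) {
  if (length(y_exp) != length(y_pred)) {
    stop("y_exp and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_exp) < min_n) {
    stop("at least ", min_n, " observations required", call. = FALSE)
  }
  if (any(!is.finite(y_exp)) || any(!is.finite(y_pred))) {
    stop("non-finite values in inputs", call. = FALSE)
  }
  invisible(NULL)
}

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y_exp - y_pred)^2) / sum((y_exp - mean(y_exp))^2)`. Equals 1
#' for perfect predictions and 0 for a predictor that always returns the mean
#' of the observed values; it can be negative for predictors worse than that.
#'
#' @param y_exp Observed values (not all identical).
#' @param y_pred Predicted values.
#' @return R squared.
#' @export
r_squared <- function(y_exp, y_pred) {
  .check_pair(y_exp, y_pred, min_n = 2L)
  ss_tot <- sum((y_exp - mean(y_exp))^2)
  if (ss_tot == 0) {
    stop("R2 is undefined when observed values have zero variance",
         call. = FALSE)
  }
  1 - sum((y_exp - y_pred)^2) / ss_tot
}

#' Mean absolute error
#'
#' @param y_exp Observed values.
#' @param y_pred Predicted values.
#' @return Mean of `abs(y_exp - y_pred)`, in endpoint units.
#' @export
mae <- function(y_exp, y_pred) {
  .check_pair(y_exp, y_pred)
  mean(abs(y_exp - y_pred))
}

.rank_avg <- function(x) {
  # average ranks for ties, built from order statistics
  o <- order(x)
  r <- numeric(length(x))
  r[o] <- seq_along(x)
  s <- x[o]
  i <- 1L
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1L] == s[i]) j <- j + 1L
    if (j > i) r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

#' Spearman rank correlation
#'
#' Measures how well the predictions order the compounds. With tie-free data
#' the classical formula `1 - 6 * sum(d^2) / (n * (n^2 - 1))` is used, where
#' `d` is the per-compound rank difference. When either vector contains ties,
#' ranks are averaged within ties and the Pearson correlation of the two rank
#' vectors is returned (the classical formula assumes distinct ranks).
#'
#' @param y_exp Observed values (length >= 3, not all identical).
#' @param y_pred Predicted values (not all identical).
#' @return Correlation in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rank(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
spearman_rank <- function(y_exp, y_pred) {
  .check_pair(y_exp, y_pred, min_n = 3L)
  if (length(unique(y_exp)) == 1L || length(unique(y_pred)) == 1L) {
    stop("Spearman correlation is undefined for a constant vector",
         call. = FALSE)
  }
  r1 <- .rank_avg(y_exp)
  r2 <- .rank_avg(y_pred)
  n <- length(y_exp)
  ties <- anyDuplicated(y_exp) > 0L || anyDuplicated(y_pred) > 0L
  if (!ties) {
    1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
  } else {
    m1 <- r1 - mean(r1); m2 <- r2 - mean(r2)
    sum(m1 * m2) / sqrt(sum(m1^2) * sum(m2^2))
  }
}

#' Count acceptable predictions
#'
#' A prediction is acceptable when its absolute error is smaller than 10% of
#' the endpoint range (strict inequality).
#'
#' @param y_exp Observed values.
#' @param y_pred Predicted values.
#' @param endpoint_range Length-2 numeric `(min, max)` of the endpoint over
#'   the partition being judged.
#' @param fraction Cut-off as a fraction of the range (default 0.10).
#' @return Integer count of predictions within the cut-off.
#' @export
acceptable_predictions <- function(y_exp, y_pred, endpoint_range,
                                   fraction = 0.10) {
  .check_pair(y_exp, y_pred)
  width <- diff(range(endpoint_range))
  if (!is.finite(width) || width <= 0) {
    stop("endpoint range must have positive width", call. = FALSE)
  }
  sum(abs(y_exp - y_pred) < fraction * width)
}

#' Full metric report for one partition
#'
#' Bundles the three accuracy metrics with the endpoint range, MAE as a
#' percentage of that range, and the acceptable-prediction count, plus the
#' conventional pass/fail acceptance flags (R2 > 0.6, SpeaR > 0.6,
#' MAE < 10% of range).
#'
#' @param y_exp Observed values.
#' @param y_pred Predicted values.
#' @return Object of class `metric_report` (a list).
#' @export
metric_report <- function(y_exp, y_pred) {
  rng <- range(y_exp)
  m <- mae(y_exp, y_pred)
  rep <- list(
    n = length(y_exp),
    r_squared = r_squared(y_exp, y_pred),
    mae = m,
    spearman = spearman_rank(y_exp, y_pred),
    endpoint_range = rng,
    mae_over_range = 100 * m / diff(rng),
    acceptable_count = acceptable_predictions(y_exp, y_pred, rng)
  )
  rep$passes <- c(
    r_squared = rep$r_squared > 0.6,
    spearman = rep$spearman > 0.6,
    mae_over_range = rep$mae_over_range < 10
  )
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  R2 = %.3f  SpeaR = %.3f  MAE = %.4g (%.2f%% of range [%.4g, %.4g])\n",
    x$n, x$r_squared, x$spearman, x$mae, x$mae_over_range,
    x$endpoint_range[1], x$endpoint_range[2]))
  cat(sprintf("acceptable predictions: %d / %d;  pass flags: %s\n",
              x$acceptable_count, x$n,
              paste(names(x$passes)[x$passes], collapse = ", ")))
  invisible(x)
}
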