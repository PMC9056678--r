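# Fully-connected regression network with per-layer batch normalization,
# trained by mini-batch gradient descent (Adam or RMSprop) on a squared-error
# loss with an L2 penalty on the connection weights.

#' Neural-network hyperparameter specification
#'
#' Describes one network: hidden-layer widths with per-layer batch-norm
#' flags, activation, optimizer, L2 regularization strength, dropout ratio
#' and training epochs. The network is
#' `input -> [FC(width) -> (bN) -> activation -> dropout]* -> linear(1)`.
#'
#' @param hidden Integer vector of hidden-layer widths (>= 1 each).
#' @param batch_norm Logical, recycled over layers: insert a batch-norm layer
#'   right after each fully connected layer.
#' @param activation `"tanh"`, `"relu"` or `"sigmoid"`.
#' @param optimizer `"Adam"` or `"RMSprop"`.
#' @param l2_lambda L2 penalty coefficient on FC weights (not biases, not
#'   batch-norm parameters).
#' @param dropout Dropout ratio in `[0, 1)` applied after each activation
#'   during training only.
#' @param epochs Number of passes over the training data (> 0).
#' @param learning_rate Optimizer step size.
#' @param batch_size Mini-batch size.
#' @param scale_y Standardize the target internally during optimization
#'   (predictions are returned in original units).
#' @return Object of class `ann_spec`.
#' @export
#' @examples
#' ann_spec(hidden = 105, batch_norm = TRUE, activation = "tanh",
#'          optimizer = "RMSprop", l2_lambda = 0.1, dropout = 0.01)
ann_spec <- function(hidden, batch_norm = TRUE, activation = c("tanh", "relu", "sigmoid"),
                     optimizer = c("Adam", "RMSprop"), l2_lambda = 0,
                     dropout = 0, epochs = 500L, learning_rate = 1e-3,
                     batch_size = 32L, scale_y = TRUE) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || any(hidden < 1L)) {
    stop("hidden widths must be positive integers", call. = FALSE)
  }
  batch_norm <- rep_len(as.logical(batch_norm), length(hidden))
  activation <- match.arg(activation)
  optimizer <- match.arg(optimizer)
  if (l2_lambda < 0) stop("l2_lambda must be >= 0", call. = FALSE)
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)", call. = FALSE)
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be a positive integer", call. = FALSE)
  spec <- list(hidden = hidden, batch_norm = batch_norm,
               activation = activation, optimizer = optimizer,
               l2_lambda = l2_lambda, dropout = dropout, epochs = epochs,
               learning_rate = learning_rate,
               batch_size = as.integer(batch_size), scale_y = scale_y)
  class(spec) <- "ann_spec"
  spec
}

#' @export
format.ann_spec <- function(x, ...) {
  hid <- paste(ifelse(x$batch_norm, paste0(x$hidden, ", bN"), x$hidden),
               collapse = ", ")
  sprintf("hid: (%s), act: %s, opt: %s, lambda: %g, dr: %g, epochs: %d",
          hid, x$activation, x$optimizer, x$l2_lambda, x$dropout, x$epochs)
}

#' @export
print.ann_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Serialize / restore a spec
#' @param spec An `ann_spec`.
#' @return `spec_to_list`: a plain list; `spec_from_list`: the `ann_spec`.
#' @export
spec_to_list <- function(spec) unclass(spec)

#' @rdname spec_to_list
#' @param x Plain list as produced by [spec_to_list()].
#' @export
spec_from_list <- function(x) {
  do.call(ann_spec, x[c("hidden", "batch_norm", "activation", "optimizer",
                        "l2_lambda", "dropout", "epochs", "learning_rate",
                        "batch_size", "scale_y")])
}

.act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a))
  )
}

.bn_eps <- 1e-5
.bn_momentum <- 0.9

.new_opt_state <- function(params, kind) {
  lapply(params, function(p) {
    if (kind == "Adam") list(m = p * 0, v = p * 0) else list(v = p * 0)
  })
}

.opt_step <- function(p, g, st, kind, lr, t) {
  if (kind == "Adam") {
    st$m <- 0.9 * st$m + 0.1 * g
    st$v <- 0.999 * st$v + 0.001 * g^2
    mhat <- st$m / (1 - 0.9^t)
    vhat <- st$v / (1 - 0.999^t)
    p <- p - lr * mhat / (sqrt(vhat) + 1e-8)
  } else { # RMSprop
    st$v <- 0.9 * st$v + 0.1 * g^2
    p <- p - lr * g / (sqrt(st$v) + 1e-8)
  }
  list(p = p, st = st)
}

#' Train the regression network
#'
#' Optimizes mean squared error plus `l2_lambda * sum(W^2)` over the
#' connection weights, by mini-batch Adam or RMSprop. Batch-norm layers keep
#' exponential running estimates of the batch statistics for inference.
#' Training is reproducible for a given seed.
#'
#' @param spec An [ann_spec()].
#' @param X Numeric matrix of descriptors (rows = compounds); column names
#'   are recorded and enforced at prediction time.
#' @param y Numeric target vector.
#' @param seed Integer seed governing initialization, shuffling and dropout.
#' @param verbose Print the loss every few epochs.
#' @return Object of class `econf_ann` with the learned parameters, the
#'   spec, the training-column labels and the final training loss.
#' @export
train_ann <- function(spec, X, y, seed = 0L, verbose = FALSE) {
  stopifnot(inherits(spec, "ann_spec"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least 2 training rows", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(X))) {
    stop("non-finite values in training data", call. = FALSE)
  }

  y_center <- if (spec$scale_y) mean(y) else 0
  y_scale <- if (spec$scale_y) stats::sd(y) else 1
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  yt <- (y - y_center) / y_scale

  act <- .act_fun(spec$activation)
  dims <- c(ncol(X), spec$hidden, 1L)
  L <- length(spec$hidden)

  model <- withr::with_seed(as.integer(seed), {
    params <- list()
    for (l in seq_len(L + 1L)) {
      fan_in <- dims[l]; fan_out <- dims[l + 1L]
      sdw <- if (spec$activation == "relu" && l <= L) {
        sqrt(2 / fan_in)
      } else {
        sqrt(2 / (fan_in + fan_out))
      }
      params[[paste0("W", l)]] <- matrix(stats::rnorm(fan_in * fan_out, sd = sdw),
                                         fan_in, fan_out)
      params[[paste0("b", l)]] <- numeric(fan_out)
      if (l <= L && spec$batch_norm[l]) {
        params[[paste0("g", l)]] <- rep(1, fan_out)
        params[[paste0("be", l)]] <- numeric(fan_out)
      }
    }
    running <- list()
    for (l in seq_len(L)) {
      if (spec$batch_norm[l]) {
        running[[paste0("mean", l)]] <- numeric(dims[l + 1L])
        running[[paste0("var", l)]] <- rep(1, dims[l + 1L])
      }
    }

    opt <- .new_opt_state(params, spec$optimizer)
    n <- nrow(X)
    bs <- min(spec$batch_size, n)
    t_step <- 0L
    last_loss <- NA_real_

    for (epoch in seq_len(spec$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = bs)
      for (s in starts) {
        idx <- perm[s:min(s + bs - 1L, n)]
        m <- length(idx)
        if (m < 2L && any(spec$batch_norm)) next  # batch stats need >= 2 rows
        A <- X[idx, , drop = FALSE]
        yb <- yt[idx]

        cache <- vector("list", L)
        for (l in seq_len(L)) {
          Z <- A %*% params[[paste0("W", l)]] +
            matrix(params[[paste0("b", l)]], m, dims[l + 1L], byrow = TRUE)
          c_l <- list(A_in = A, Z = Z)
          if (spec$batch_norm[l]) {
            mu <- colMeans(Z)
            Zc <- sweep(Z, 2L, mu)
            v <- colMeans(Zc^2)
            inv_sd <- 1 / sqrt(v + .bn_eps)
            Zhat <- sweep(Zc, 2L, inv_sd, `*`)
            Zn <- sweep(sweep(Zhat, 2L, params[[paste0("g", l)]], `*`),
                        2L, params[[paste0("be", l)]], `+`)
            running[[paste0("mean", l)]] <-
              .bn_momentum * running[[paste0("mean", l)]] + (1 - .bn_momentum) * mu
            running[[paste0("var", l)]] <-
              .bn_momentum * running[[paste0("var", l)]] +
              (1 - .bn_momentum) * v * m / max(m - 1L, 1L)
            c_l$Zhat <- Zhat
            c_l$inv_sd <- inv_sd
            Zact_in <- Zn
          } else {
            Zact_in <- Z
          }
          Aout <- act$f(Zact_in)
          c_l$Zact_in <- Zact_in
          c_l$A_out <- Aout
          if (spec$dropout > 0) {
            mask <- matrix(stats::runif(m * dims[l + 1L]) >= spec$dropout,
                           m, dims[l + 1L]) / (1 - spec$dropout)
            Aout <- Aout * mask
            c_l$mask <- mask
          }
          c_l$A_drop <- Aout
          cache[[l]] <- c_l
          A <- Aout
        }
        yhat <- drop(A %*% params[[paste0("W", L + 1L)]] + params[[paste0("b", L + 1L)]])
        err <- yhat - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop("training diverged (non-finite loss) for spec [", format(spec),
               "]", call. = FALSE)
        }
        last_loss <- loss

        grads <- list()
        dyhat <- matrix(2 * err / m, m, 1L)
        Wl <- paste0("W", L + 1L)
        grads[[Wl]] <- crossprod(cache[[L]]$A_drop, dyhat) +
          2 * spec$l2_lambda * params[[Wl]]
        grads[[paste0("b", L + 1L)]] <- colSums(dyhat)
        dA <- dyhat %*% t(params[[Wl]])

        for (l in rev(seq_len(L))) {
          c_l <- cache[[l]]
          if (!is.null(c_l$mask)) dA <- dA * c_l$mask
          dZact <- dA * act$df(c_l$Zact_in, c_l$A_out)
          if (spec$batch_norm[l]) {
            gl <- params[[paste0("g", l)]]
            grads[[paste0("g", l)]] <- colSums(dZact * c_l$Zhat)
            grads[[paste0("be", l)]] <- colSums(dZact)
            dZhat <- sweep(dZact, 2L, gl, `*`)
            mloc <- nrow(dZhat)
            sum_d <- colSums(dZhat)
            sum_dz <- colSums(dZhat * c_l$Zhat)
            dZ <- sweep(
              dZhat * mloc - matrix(sum_d, mloc, length(sum_d), byrow = TRUE) -
                c_l$Zhat * matrix(sum_dz, mloc, length(sum_dz), byrow = TRUE),
              2L, c_l$inv_sd / mloc, `*`)
          } else {
            dZ <- dZact
          }
          Wl <- paste0("W", l)
          grads[[Wl]] <- crossprod(c_l$A_in, dZ) + 2 * spec$l2_lambda * params[[Wl]]
          grads[[paste0("b", l)]] <- colSums(dZ)
          if (l > 1L) dA <- dZ %*% t(params[[Wl]])
        }

        t_step <- t_step + 1L
        for (nm in names(grads)) {
          upd <- .opt_step(params[[nm]], grads[[nm]], opt[[nm]],
                           spec$optimizer, spec$learning_rate, t_step)
          params[[nm]] <- upd$p
          opt[[nm]] <- upd$st
        }
      }
      if (verbose && (epoch %% 50L == 0L || epoch == 1L)) {
        message(sprintf("epoch %4d  batch loss %.6f", epoch, last_loss))
      }
    }
    list(params = params, running = running, last_loss = last_loss)
  })

  fit <- list(spec = spec, params = model$params, running = model$running,
              columns = colnames(X), dims = dims,
              y_center = y_center, y_scale = y_scale,
              seed = as.integer(seed), final_loss = model$last_loss)
  class(fit) <- "econf_ann"
  fit
}

# forward pass in inference mode; optionally returns the first-block stages
.ann_forward <- function(fit, X, trace_first_block = FALSE) {
  spec <- fit$spec
  act <- .act_fun(spec$activation)
  L <- length(spec$hidden)
  A <- X
  trace <- list()
  for (l in seq_len(L)) {
    Z <- A %*% fit$params[[paste0("W", l)]] +
      matrix(fit$params[[paste0("b", l)]], nrow(A), fit$dims[l + 1L],
             byrow = TRUE)
    if (trace_first_block && l == 1L) trace$linear <- Z
    if (spec$batch_norm[l]) {
      mu <- fit$running[[paste0("mean", l)]]
      v <- fit$running[[paste0("var", l)]]
      Zhat <- sweep(sweep(Z, 2L, mu), 2L, 1 / sqrt(v + .bn_eps), `*`)
      Z <- sweep(sweep(Zhat, 2L, fit$params[[paste0("g", l)]], `*`),
                 2L, fit$params[[paste0("be", l)]], `+`)
      if (trace_first_block && l == 1L) trace$batch_norm <- Z
    }
    A <- act$f(Z)
    if (trace_first_block && l == 1L) trace$activation <- A
  }
  yhat <- drop(A %*% fit$params[[paste0("W", L + 1L)]] +
                 fit$params[[paste0("b", L + 1L)]])
  yhat <- yhat * fit$y_scale + fit$y_center
  if (trace_first_block) list(yhat = yhat, trace = trace) else yhat
}

.check_columns <- function(fit_columns, X) {
  if (!is.null(fit_columns)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != length(fit_columns)) {
        stop("newdata has ", ncol(X), " columns; model expects ",
             length(fit_columns), call. = FALSE)
      }
    } else if (!identical(colnames(X), fit_columns)) {
      stop("newdata columns do not match training columns; ",
           "align with align_columns()", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Predict from a trained network
#'
#' Inference is deterministic: dropout is disabled and batch-norm layers use
#' their running statistics.
#'
#' @param object An `econf_ann` from [train_ann()].
#' @param newdata Descriptor matrix aligned to the training columns.
#' @param ... Unused.
#' @return Numeric vector of predictions in endpoint units.
#' @export
predict.econf_ann <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  .check_columns(object$columns, X)
  .ann_forward(object, X)
}

#' @export
print.econf_ann <- function(x, ...) {
  cat("econf_ann:", format(x$spec), "\n")
  cat(sprintf("input dim %d, trained with seed %d, final batch loss %.5g\n",
              x$dims[1L], x$seed, x$final_loss))
  invisible(x)
}
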