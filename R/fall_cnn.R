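#' Log-cosh loss
#'
#' Mean over components of `log(cosh(predicted - target))`, the smooth,
#' outlier-robust loss used to train the fall-detection networks. Evaluated
#' in the numerically stable form `|r| + log1p(exp(-2|r|)) - log(2)`, exact
#' for large residuals where `cosh` would overflow.
#'
#' @param predicted,target numeric vectors (or matrices) of equal length.
#' @return non-negative scalar.
#' @export
logcosh_loss <- function(predicted, target) {
  if (length(predicted) != length(target))
    fallcnn_error("bad_argument", "predicted and target lengths differ")
  r <- abs(as.numeric(predicted) - as.numeric(target))
  mean(r + log1p(exp(-2 * r)) - log(2))
}

#' Training configuration for [fall_cnn()]
#'
#' Defaults follow the published recipe: stochastic gradient descent with
#' Nesterov momentum 0.999, initial learning rate 0.0107 decayed per update
#' as `lr_t = lr0 / (1 + decay * t)` with `decay = 1e-6`, log-cosh loss,
#' 20 epochs. Batch size (32) and Glorot-uniform initialization are this
#' package's choices where the recipe is silent.
#'
#' @param learning_rate initial learning rate.
#' @param momentum momentum coefficient.
#' @param decay per-update learning-rate decay.
#' @param nesterov use Nesterov momentum.
#' @param epochs training epochs (`0` returns the seeded initialization).
#' @param batch_size minibatch size.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.0107, momentum = 0.999,
                         decay = 1e-6, nesterov = TRUE, epochs = 20L,
                         batch_size = 32L, seed = 1L) {
  if (learning_rate <= 0 || momentum < 0 || decay < 0)
    fallcnn_error("bad_argument", "rates must be positive")
  if (epochs < 0 || batch_size < 1)
    fallcnn_error("bad_argument", "epochs must be >= 0 and batch_size >= 1")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 decay = decay, nesterov = isTRUE(nesterov),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss = "logcosh"),
            class = "train_config")
}

onehot <- function(labels) {
  # columns (adl, fall); fall is the positive class (index 2)
  Y <- matrix(0, length(labels), 2L)
  Y[cbind(seq_along(labels), ifelse(labels == "fall", 2L, 1L))] <- 1
  Y
}

scores_to_labels <- function(P) {
  # ties broken toward the negative (adl) class
  ifelse(P[, 2L] > P[, 1L], "fall", "adl")
}

#' Fit a fall-detection CNN
#'
#' Trains one of the three 1D-CNN variants on a labeled window dataset with
#' minibatch stochastic gradient descent (Nesterov momentum, per-update
#' learning-rate decay), minimizing the log-cosh loss between the softmax
#' output scores and one-hot labels, with an L2 penalty (0.01) on
#' convolution kernels. Training is fully deterministic given
#' `config$seed`: the seed drives weight initialization, epoch shuffling
#' and dropout masks.
#'
#' The dataset should be normalized (see [fit_min_max()] /
#' [apply_min_max()]) before fitting; pass the normalizer so that
#' [predict.fall_cnn()] can apply it to new raw windows.
#'
#' @param data an `accel_dataset` whose windows are all labeled `"fall"` or
#'   `"adl"`.
#' @param variant network variant, see [build_stack()].
#' @param config a [train_config()].
#' @param normalizer optional `"minmax_normalizer"` stored with the model
#'   and applied by `predict()` when `normalize = TRUE`.
#' @param validation optional `accel_dataset` evaluated (without dropout)
#'   at the end of each epoch.
#' @return an object of class `"fall_cnn"` with components `stack`,
#'   `weights`, `config`, `history` (data.frame with one row per epoch:
#'   `epoch`, `loss`, `accuracy`, and `val_loss`/`val_accuracy` when a
#'   validation set is given), `normalizer` and `call`.
#' @seealso [predict.fall_cnn()], [build_stack()], [run_experiment()]
#' @examples
#' cfg <- sim_config(window_length = 25, seed = 7)
#' d <- gen_dataset(cfg, n_fall = 20, n_adl = 20)
#' norm <- fit_min_max(d)
#' fit <- fall_cnn(apply_min_max(d, norm), "CNN-1Conv",
#'                 config = train_config(epochs = 2, seed = 1),
#'                 normalizer = norm)
#' print(fit)
#' @export
fall_cnn <- function(data, variant = c("CNN-3B3Conv", "CNN-3Conv", "CNN-1Conv"),
                     config = train_config(), normalizer = NULL,
                     validation = NULL) {
  variant <- match.arg(variant)
  if (!inherits(data, "accel_dataset"))
    fallcnn_error("bad_argument", "data must be an accel_dataset")
  labels <- dataset_labels(data)
  if (any(labels == "unlabeled"))
    fallcnn_error("bad_argument", "all training windows must be labeled fall/adl")
  stack <- build_stack(variant, data$window_length)
  X <- dataset_array(data)
  Y <- onehot(labels)
  B <- dim(X)[[1L]]

  val <- NULL
  if (!is.null(validation)) {
    val <- list(X = dataset_array(validation),
                Y = onehot(dataset_labels(validation)))
  }

  history <- NULL
  weights <- NULL
  with_seed(config$seed, {
    weights <- init_weights(stack)
    vel <- lapply(weights, function(w)
      if (is.null(w)) NULL else list(W = w$W * 0, b = w$b * 0))
    t_upd <- 0L
    hist_rows <- vector("list", config$epochs)
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(B)
      batch_starts <- seq.int(1L, B, by = config$batch_size)
      ep_loss <- ep_acc <- numeric(length(batch_starts))
      for (bi in seq_along(batch_starts)) {
        idx <- perm[batch_starts[[bi]]:min(batch_starts[[bi]] +
                                             config$batch_size - 1L, B)]
        Xb <- X[idx, , , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        fwd <- forward_pass(stack, weights, Xb, training = TRUE, cache = TRUE)
        P <- fwd$scores
        ep_loss[[bi]] <- logcosh_loss(P, Yb) + l2_penalty(stack, weights)
        ep_acc[[bi]] <- mean(scores_to_labels(P) ==
                               ifelse(Yb[, 2L] == 1, "fall", "adl"))
        dOut <- tanh(P - Yb) / length(P)
        grads <- backward_pass(stack, weights, fwd, dOut)
        t_upd <- t_upd + 1L
        lr <- config$learning_rate / (1 + config$decay * t_upd)
        m <- config$momentum
        for (li in seq_along(weights)) {
          if (is.null(weights[[li]])) next
          for (par in c("W", "b")) {
            g <- grads[[li]][[par]]
            v <- m * vel[[li]][[par]] - lr * g
            vel[[li]][[par]] <- v
            weights[[li]][[par]] <- weights[[li]][[par]] +
              if (config$nesterov) m * v - lr * g else v
          }
        }
      }
      row <- data.frame(epoch = epoch, loss = mean(ep_loss),
                        accuracy = mean(ep_acc))
      if (!is.null(val)) {
        Pv <- forward_pass(stack, weights, val$X)$scores
        row$val_loss <- logcosh_loss(Pv, val$Y) + l2_penalty(stack, weights)
        row$val_accuracy <- mean(scores_to_labels(Pv) ==
                                   ifelse(val$Y[, 2L] == 1, "fall", "adl"))
      }
      hist_rows[[epoch]] <- row
    }
    history <- if (config$epochs > 0) do.call(rbind, hist_rows) else
      data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  })

  structure(list(stack = stack, weights = weights, config = config,
                 history = history, normalizer = normalizer,
                 call = match.call()),
            class = "fall_cnn")
}

as_window_array <- function(newdata, L) {
  if (inherits(newdata, "accel_dataset")) return(dataset_array(newdata))
  if (is.matrix(newdata)) newdata <- list(newdata)
  if (is.list(newdata)) {
    d <- array(0, c(length(newdata), L, 3L))
    for (i in seq_along(newdata)) {
      w <- newdata[[i]]
      if (nrow(w) != L || ncol(w) != 3L)
        fallcnn_error("bad_window",
                      sprintf("window %d is %d x %d, expected %d x 3",
                              i, nrow(w), ncol(w), L))
      d[i, , ] <- unclass(w)
    }
    return(d)
  }
  if (is.array(newdata) && length(dim(newdata)) == 3L) return(newdata)
  fallcnn_error("bad_argument", "newdata must be a dataset, window list or array")
}

#' Predict fall/ADL labels for new windows
#'
#' Runs the trained network (dropout disabled) and returns the two softmax
#' scores and the predicted label per window. Scores sum to one; ties are
#' broken toward the negative (`adl`) class.
#'
#' @param object a fitted [fall_cnn()] model.
#' @param newdata an `accel_dataset`, a list of windows, a single `L x 3`
#'   matrix, or a `B x L x 3` array.
#' @param normalize apply the model's stored min-max normalizer to
#'   `newdata` first (default `TRUE` when one was stored; `newdata` must
#'   then be on the raw scale).
#' @param batch_size windows evaluated per forward pass (memory bound).
#' @param ... unused.
#' @return data.frame with columns `score_adl`, `score_fall`, `label`.
#' @export
predict.fall_cnn <- function(object, newdata,
                             normalize = !is.null(object$normalizer),
                             batch_size = 256L, ...) {
  if (isTRUE(normalize)) {
    if (is.null(object$normalizer))
      fallcnn_error("bad_argument", "model has no stored normalizer")
    if (!inherits(newdata, "accel_dataset")) {
      X <- as_window_array(newdata, object$stack$input_length)
      newdata <- accel_dataset(lapply(seq_len(dim(X)[[1L]]),
                                      function(i) accel_window(X[i, , ])))
    }
    newdata <- apply_min_max(newdata, object$normalizer)
  }
  X <- as_window_array(newdata, object$stack$input_length)
  B <- dim(X)[[1L]]
  P <- matrix(0, B, 2L)
  for (s in seq.int(1L, B, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, B)
    P[idx, ] <- forward_pass(object$stack, object$weights,
                             X[idx, , , drop = FALSE])$scores
  }
  data.frame(score_adl = P[, 1L], score_fall = P[, 2L],
             label = scores_to_labels(P))
}

#' @export
print.fall_cnn <- function(x, ...) {
  cat(sprintf("Fall-detection CNN (%s), input %d x 3\n",
              x$stack$variant, x$stack$input_length))
  cat(sprintf("  %s trainable parameters; trained %d epoch(s), seed %d\n",
              format(count_parameters(x$stack), big.mark = ","),
              nrow(x$history), x$config$seed))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.5f, accuracy %.4f\n",
                last$loss, last$accuracy))
    if (!is.null(last$val_accuracy))
      cat(sprintf("  final validation loss %.5f, accuracy %.4f\n",
                  last$val_loss, last$val_accuracy))
  }
  invisible(x)
}

#' @export
summary.fall_cnn <- function(object, ...) {
  structure(list(model = object,
                 shapes = propagate_shapes(object$stack),
                 n_parameters = count_parameters(object$stack)),
            class = "summary.fall_cnn")
}

#' @export
print.summary.fall_cnn <- function(x, ...) {
  print(x$model)
  cat("\nArchitecture:\n")
  print(x$model$stack)
  if (nrow(x$model$history) > 0) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(x$model$history, 5L), row.names = FALSE)
  }
  invisible(x)
}

#' Extract trained weights
#'
#' @param object a fitted [fall_cnn()] model.
#' @param ... unused.
#' @return list with one `list(W, b)` entry per trainable layer (conv and
#'   dense), `NULL` for parameter-free layers, in stack order.
#' @export
coef.fall_cnn <- function(object, ...) object$weights

#' Plot the training history
#'
#' Loss and training accuracy per epoch (plus validation curves when
#' recorded).
#'
#' @param x a fitted [fall_cnn()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fall_cnn <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) {
    warning("no training history to plot (epochs = 0)")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = paste(x$stack$variant, "loss"), ...)
  if (!is.null(h$val_loss)) {
    graphics::lines(h$epoch, h$val_loss, type = "b", lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  graphics::plot(h$epoch, h$accuracy, type = "b", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy",
                 main = paste(x$stack$variant, "accuracy"), ...)
  if (!is.null(h$val_accuracy))
    graphics::lines(h$epoch, h$val_accuracy, type = "b", lty = 2)
  invisible(x)
}
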