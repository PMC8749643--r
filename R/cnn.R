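#' Hyperparameter configuration of the 1D-CNN
#'
#' The network is two conv-conv-pool blocks followed by fully connected
#' hidden layers and a 10-way softmax output. Defaults follow the best
#' configuration found by Bayesian optimization on the second-region
#' dataset (filters 10/16, 3 hidden layers of 40 nodes, kernel 6,
#' dropout 0.37, batch 85, 100 epochs), except the learning rate, where
#' the sensitivity analysis's optimum of 9e-4 is used: large rates make
#' the cross-entropy loss oscillate instead of converging.
#'
#' Values outside the Bayesian search bounds (filters 2-64, hidden
#' layers 1-10, kernel 2-32, dropout 0.01-1, nodes 1-100, learning rate
#' 1e-4-0.1, batch 10-300, epochs 10-500) are allowed but trigger a
#' warning of class `oxispec_config_bounds`.
#'
#' @param filters_block1 Filters in convolutional layers 1-2.
#' @param filters_block2 Filters in convolutional layers 3-4.
#' @param n_dense_layers Number of fully connected hidden layers.
#' @param kernel_size Convolution kernel length (clamped per layer to the
#'   layer's input length, with a warning).
#' @param dropout_ratio Dropout probability after each hidden layer.
#' @param dense_nodes Nodes per fully connected hidden layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return Object of class `cnn_config` (a named list).
#' @export
#' @examples
#' cfg <- cnn_config(epochs = 30)
cnn_config <- function(filters_block1 = 10, filters_block2 = 16,
                       n_dense_layers = 3, kernel_size = 6,
                       dropout_ratio = 0.37, dense_nodes = 40,
                       learning_rate = 9e-4, batch_size = 85,
                       epochs = 100, seed = 1L) {
  cfg <- list(filters_block1 = filters_block1, filters_block2 = filters_block2,
              n_dense_layers = n_dense_layers, kernel_size = kernel_size,
              dropout_ratio = dropout_ratio, dense_nodes = dense_nodes,
              learning_rate = learning_rate, batch_size = batch_size,
              epochs = epochs, seed = as.integer(seed))
  bad <- character(0)
  chk <- function(name, lo, hi) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop(name, " must be a single number", call. = FALSE)
    }
    if (v < lo || v > hi) bad <<- c(bad, sprintf("%s=%g (bounds %g..%g)", name, v, lo, hi))
  }
  chk("filters_block1", 2, 64); chk("filters_block2", 2, 64)
  chk("n_dense_layers", 1, 10); chk("kernel_size", 2, 32)
  chk("dropout_ratio", 0.01, 1); chk("dense_nodes", 1, 100)
  chk("learning_rate", 1e-4, 0.1); chk("batch_size", 10, 300)
  chk("epochs", 10, 500)
  if (length(bad)) {
    warning(warningCondition(
      paste("config outside the search bounds:", paste(bad, collapse = ", ")),
      class = "oxispec_config_bounds"))
  }
  structure(cfg, class = "cnn_config")
}

# Layer stack + initialized parameters for a given input length.
cnn_architecture <- function(cfg, input_length, n_classes, n_blocks = 2) {
  if (n_blocks == 2 && input_length < 4) {
    stop("input_length ", input_length, " is too short for two pooling ",
         "layers; rebuild with n_blocks = 1", call. = FALSE)
  }
  if (n_blocks == 1 && input_length < 2) {
    stop("input_length must be at least 2", call. = FALSE)
  }
  layers <- list()
  params <- list()
  # effective kernel: convolutions use "same" padding, so any kernel up to
  # the model input length is admissible; larger requests are clamped once
  k_eff <- min(cfg$kernel_size, input_length)
  he <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))
  add_conv <- function(id, c_in, c_out, len) {
    k <- k_eff
    wn <- paste0("conv", id, "_W"); bn <- paste0("conv", id, "_b")
    params[[wn]] <<- matrix(he(k * c_in * c_out, k * c_in), k * c_in, c_out)
    params[[bn]] <<- numeric(c_out)
    layers[[length(layers) + 1]] <<- list(type = "conv", W = wn, b = bn, k = k)
    layers[[length(layers) + 1]] <<- list(type = "relu")
  }
  len <- input_length
  add_conv(1, 1, cfg$filters_block1, len)
  add_conv(2, cfg$filters_block1, cfg$filters_block1, len)
  layers[[length(layers) + 1]] <- list(type = "pool")
  len <- len %/% 2L
  c_prev <- cfg$filters_block1
  if (n_blocks == 2) {
    add_conv(3, cfg$filters_block1, cfg$filters_block2, len)
    add_conv(4, cfg$filters_block2, cfg$filters_block2, len)
    layers[[length(layers) + 1]] <- list(type = "pool")
    len <- len %/% 2L
    c_prev <- cfg$filters_block2
  }
  layers[[length(layers) + 1]] <- list(type = "flatten")
  fan <- len * c_prev
  for (j in seq_len(cfg$n_dense_layers)) {
    wn <- paste0("dense", j, "_W"); bn <- paste0("dense", j, "_b")
    params[[wn]] <- matrix(he(fan * cfg$dense_nodes, fan), fan, cfg$dense_nodes)
    params[[bn]] <- numeric(cfg$dense_nodes)
    layers[[length(layers) + 1]] <- list(type = "dense", W = wn, b = bn)
    layers[[length(layers) + 1]] <- list(type = "relu")
    layers[[length(layers) + 1]] <- list(type = "dropout", rate = cfg$dropout_ratio)
    fan <- cfg$dense_nodes
  }
  params[["out_W"]] <- matrix(he(fan * n_classes, fan), fan, n_classes)
  params[["out_b"]] <- numeric(n_classes)
  layers[[length(layers) + 1]] <- list(type = "dense", W = "out_W", b = "out_b")
  if (k_eff < cfg$kernel_size) {
    warning(warningCondition(
      sprintf("kernel size %d clamped to the input length %d",
              cfg$kernel_size, input_length),
      class = "oxispec_kernel_clamp"))
  }
  list(layers = layers, params = params, spatial_out = len)
}

#' Build an untrained 1D-CNN
#'
#' Constructs the layer stack (conv-conv-pool twice, then fully
#' connected hidden layers with dropout, then softmax over the labels)
#' with seeded He-normal initialization. The result is an `oxi_cnn`
#' object with `fitted = FALSE`; [predict.oxi_cnn()] already works on it
#' and [oxi_cnn()] trains it.
#'
#' @param config A [cnn_config()].
#' @param input_length Number of spectral channels (3, 6 or 12 for the
#'   preset regions). Inputs shorter than 4 need `n_blocks = 1`.
#' @param label_vector Ascending SpO2 labels, one per output class.
#' @param n_blocks Number of conv-conv-pool blocks (1 or 2).
#' @return Object of class `oxi_cnn`.
#' @export
build_cnn <- function(config = cnn_config(), input_length,
                      label_vector = seq(81, 99, by = 2), n_blocks = 2) {
  if (is.unsorted(label_vector, strictly = TRUE)) {
    stop("label_vector must be strictly ascending", call. = FALSE)
  }
  set.seed(config$seed)
  arch <- cnn_architecture(config, input_length, length(label_vector), n_blocks)
  structure(list(
    layers = arch$layers,
    params = arch$params,
    config = config,
    input_length = as.integer(input_length),
    label_vector = label_vector,
    n_blocks = n_blocks,
    center = rep(0, input_length),
    scale = rep(1, input_length),
    fitted = FALSE,
    history = NULL
  ), class = "oxi_cnn")
}

#' Fit the 1D-CNN SpO2 classifier
#'
#' Trains the two-block 1D convolutional network on normalized spectra
#' with softmax outputs and categorical cross-entropy, optimized by Adam
#' in shuffled minibatches. The ten output weights are turned into a
#' scalar SpO2 by weighted-label expectation decoding, see
#' [decode_spo2()]. Training is deterministic for a given
#' `config$seed`.
#'
#' @param x A `labeled_dataset` (see [build_dataset()]) or a numeric
#'   matrix of normalized spectra rows.
#' @param y Integer labels (ignored when `x` is a `labeled_dataset`).
#' @param config A [cnn_config()].
#' @param label_vector Ascending class labels; defaults to the dataset's
#'   label vector or the sorted unique values of `y`.
#' @param n_blocks Conv-pool blocks; default 2, or 1 when the input is
#'   shorter than 4 channels.
#' @param verbose Print the loss every 10 epochs.
#' @return Object of class `oxi_cnn` with `fitted = TRUE` and a training
#'   `history` (per-epoch loss and argmax accuracy).
#' @export
#' @examples
#' frames <- generate_sweep(cfg = simulator_config(), seed = 1)
#' ds <- build_dataset(frames, "SECOND", 0.02, n_rows_per_label = 20, seed = 1)
#' fit <- oxi_cnn(ds, config = cnn_config(epochs = 10, seed = 1))
#' predict(fit, ds$X[1:2, ])
oxi_cnn <- function(x, y = NULL, config = cnn_config(),
                    label_vector = NULL, n_blocks = NULL, verbose = FALSE) {
  if (inherits(x, "labeled_dataset")) {
    if (is.null(label_vector)) label_vector <- x$label_vector
    y <- x$y
    x <- x$X
  }
  x <- as.matrix(x)
  x_raw <- x
  if (is.null(label_vector)) label_vector <- sort(unique(y))
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)", call. = FALSE)
  yidx <- match(y, label_vector)
  if (anyNA(yidx)) {
    stop("labels not in label_vector: ",
         paste(unique(y[is.na(yidx)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(n_blocks)) n_blocks <- if (ncol(x) < 4) 1 else 2

  model <- build_cnn(config, ncol(x), label_vector, n_blocks)
  n <- nrow(x)
  k <- length(label_vector)
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), yidx)] <- 1

  # Per-channel standardization, estimated on the training rows and kept
  # with the model: centered inputs condition the gradient descent much
  # better than raw [0, 1] intensities.
  model$center <- colMeans(x)
  model$scale <- apply(x, 2, stats::sd)
  model$scale[model$scale < 1e-8] <- 1
  x <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)

  bs <- max(1L, min(as.integer(config$batch_size), n))
  state <- adam_init(model$params)
  params <- model$params
  hist_loss <- numeric(config$epochs)
  hist_acc <- numeric(config$epochs)
  X3 <- x
  dim(X3) <- c(n, ncol(x), 1L)

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      Xb <- X3[idx, , , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fwd <- net_forward(model$layers, params, Xb, training = TRUE)
      sc <- softmax_ce(fwd$logits, Yb)
      grads <- net_backward(model$layers, params, fwd$caches, sc$dZ)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + sc$loss * length(idx)
      ep_correct <- ep_correct +
        sum(max.col(sc$probs, ties.method = "first") == max.col(Yb))
      if (!is.finite(sc$loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; the learning rate is likely too high and the loss is ",
             "oscillating - reduce config$learning_rate", call. = FALSE)
      }
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
    if (verbose && (ep %% 10 == 0 || ep == 1)) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                      hist_loss[ep], hist_acc[ep]))
    }
  }
  model$params <- params
  model$fitted <- TRUE
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = hist_loss, accuracy = hist_acc)
  model$train_x <- x_raw
  model$train_y <- y
  model
}

#' Class-weight predictions and decoded SpO2 from a fitted 1D-CNN
#'
#' Inference runs without dropout and is deterministic. `type =
#' "weights"` returns the softmax class weights (rows sum to 1),
#' `"class"` the argmax label, `"spo2"` (default) the weighted-label
#' expectation `sum(L_i * W_i)`.
#'
#' @param object An `oxi_cnn`.
#' @param newdata Matrix of normalized spectra rows, a single row
#'   vector, or a `labeled_dataset`.
#' @param type `"spo2"`, `"weights"` or `"class"`.
#' @param ... Unused.
#' @return Numeric vector (spo2/class) or weight matrix with one column
#'   per label.
#' @export
predict.oxi_cnn <- function(object, newdata,
                            type = c("spo2", "weights", "class"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "labeled_dataset")) newdata <- newdata$X
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_length) {
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         object$input_length, call. = FALSE)
  }
  X3 <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  dim(X3) <- c(nrow(newdata), ncol(newdata), 1L)
  logits <- net_forward(object$layers, object$params, X3,
                        training = FALSE)$logits
  W <- softmax_rows(logits)
  colnames(W) <- object$label_vector
  switch(type,
    weights = W,
    class = object$label_vector[max.col(W, ties.method = "first")],
    spo2 = decode_spo2(W, object$label_vector)
  )
}

#' Weighted-label expectation decoding
#'
#' Converts softmax class weights into a scalar SpO2 estimate,
#' `SpO2 = sum_i L_i * W_i`, where `L_i` is the i-th SpO2 label and
#' `W_i` its weight. The result always lies between the smallest and
#' largest label.
#'
#' @param w Weight vector summing to 1, or a matrix with one row per
#'   prediction.
#' @param label_vector Ascending labels matching the weights (default
#'   81, 83, ..., 99).
#' @return Numeric SpO2 estimate(s) in percent.
#' @export
#' @examples
#' decode_spo2(c(rep(0, 8), 0.5, 0.5))     # 98
#' decode_spo2(rep(0.1, 10))               # 90
decode_spo2 <- function(w, label_vector = seq(81, 99, by = 2)) {
  if (is.null(dim(w))) w <- matrix(w, nrow = 1)
  if (ncol(w) != length(label_vector)) {
    stop("weights and label_vector lengths differ", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- rowSums(w)
  if (any(abs(s - 1) > 1e-6)) {
    stop("weights must sum to 1 (within 1e-6)", call. = FALSE)
  }
  drop(w %*% label_vector)
}

#' @export
print.oxi_cnn <- function(x, ...) {
  cat("<oxi_cnn> 1D-CNN SpO2 classifier",
      if (x$fitted) "(fitted)" else "(untrained)", "\n")
  cat("  input:", x$input_length, "channels;", x$n_blocks,
      "conv-conv-pool block(s);", x$config$n_dense_layers,
      "hidden layer(s) of", x$config$dense_nodes, "nodes\n")
  cat("  labels:", paste(x$label_vector, collapse = " "), "\n")
  if (x$fitted) {
    h <- x$history[nrow(x$history), ]
    cat(sprintf("  final training loss %.4f, accuracy %.3f after %d epochs\n",
                h$loss, h$accuracy, h$epoch))
  }
  invisible(x)
}

#' @export
summary.oxi_cnn <- function(object, ...) {
  n_par <- sum(vapply(object$params, length, numeric(1)))
  print(object)
  cat("  parameters:", n_par, "\n")
  cat("  config: filters", object$config$filters_block1, "/",
      object$config$filters_block2, ", kernel", object$config$kernel_size,
      ", dropout", object$config$dropout_ratio,
      ", lr", object$config$learning_rate,
      ", batch", object$config$batch_size, "\n")
  invisible(object)
}

#' @export
coef.oxi_cnn <- function(object, ...) object$params

#' @export
fitted.oxi_cnn <- function(object, ...) {
  if (!object$fitted) stop("model is not fitted", call. = FALSE)
  predict(object, object$train_x, type = "spo2")
}

#' Decoding residuals of a fitted 1D-CNN
#'
#' Difference between the expectation-decoded SpO2 and the true label on
#' the training rows.
#' @param object A fitted `oxi_cnn`.
#' @param ... Unused.
#' @export
residuals.oxi_cnn <- function(object, ...) {
  fitted(object) - object$train_y
}

#' Plot the training history of a fitted 1D-CNN
#'
#' @param x A fitted `oxi_cnn`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.oxi_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history", call. = FALSE)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$loss, type = "l",
                 xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::plot(x$history$epoch, x$history$accuracy, type = "l",
                 xlab = "epoch", ylab = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}
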