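#' CNN configuration
#'
#' Architecture and training hyperparameters of the spectral classifier.
#' Defaults are the reference settings for the seed application: two
#' 1-D convolution layers with 64 and 128 kernels (size 3, stride 1, no
#' padding), each followed by ReLU, max pooling (size 2, stride 2) and
#' batch normalization; dense layers of 512, 128 and `n_classes` units; the
#' first two dense layers are ReLU-activated and the last feeds a softmax.
#' Training minimizes softmax cross-entropy with plain SGD at learning rate
#' 0.005 for 300 epochs, batch size 1024 for pixel-level spectra and 200
#' for per-seed average spectra. Momentum is off by default.
#'
#' @param conv_channels kernels in the two convolution layers.
#' @param kernel_size convolution kernel length (stride 1, padding 0).
#' @param pool_size max-pooling window and stride.
#' @param dense_units widths of the first two dense layers.
#' @param n_classes number of varieties (width of the final dense layer).
#' @param lr SGD learning rate.
#' @param epochs training epochs.
#' @param batch_size_pixel,batch_size_object batch sizes by table level.
#' @param momentum SGD momentum (0 = plain SGD).
#' @param bn_eps,bn_momentum batch-normalization epsilon and running-average
#'   momentum.
#' @param seed RNG seed for weight initialization and shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_channels = c(64L, 128L), kernel_size = 3L,
                       pool_size = 2L, dense_units = c(512L, 128L),
                       n_classes = 3L, lr = 0.005, epochs = 300L,
                       batch_size_pixel = 1024L, batch_size_object = 200L,
                       momentum = 0, bn_eps = 1e-5, bn_momentum = 0.1,
                       seed = 1L) {
  stopifnot(length(conv_channels) == 2L, length(dense_units) == 2L,
            kernel_size >= 1L, pool_size >= 1L, n_classes >= 2L,
            lr > 0, epochs >= 1L)
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 lr = lr, epochs = as.integer(epochs),
                 batch_size_pixel = as.integer(batch_size_pixel),
                 batch_size_object = as.integer(batch_size_object),
                 momentum = momentum, bn_eps = bn_eps,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "cnn_config")
}

# config in the flat form the C++ engine expects
.cfg_cpp <- function(config, batch_size, epochs = NULL) {
  list(conv1 = config$conv_channels[1], conv2 = config$conv_channels[2],
       kernel_size = config$kernel_size, pool_size = config$pool_size,
       dense1 = config$dense_units[1], dense2 = config$dense_units[2],
       n_classes = config$n_classes, lr = config$lr,
       epochs = as.integer(if (is.null(epochs)) config$epochs else epochs),
       batch_size = as.integer(batch_size), momentum = config$momentum,
       bn_eps = config$bn_eps, bn_momentum = config$bn_momentum,
       seed = config$seed)
}

#' Feature lengths through the conv/pool stack
#'
#' Closed-form sizes of the feature maps for `n_bands` input points:
#' each valid convolution of kernel `k` shortens a length-n signal to
#' `n - k + 1`, and each pooling to `floor(n / pool)`. The flattened width
#' feeding the dense head is the final length times the second layer's
#' channel count.
#'
#' @param n_bands input spectrum length.
#' @param config a [cnn_config()].
#' @return Named integer vector: `conv1`, `pool1`, `conv2`, `pool2`,
#'   `flat`.
#' @export
conv_feature_lengths <- function(n_bands, config = cnn_config()) {
  n_bands <- as.integer(n_bands)
  k <- config$kernel_size
  p <- config$pool_size
  p1 <- n_bands - k + 1L
  q1 <- p1 %/% p
  p2 <- q1 - k + 1L
  q2 <- p2 %/% p
  if (p1 < 1L || q1 < 1L || p2 < 1L || q2 < 1L)
    stop("n_bands = ", n_bands, " is too short for the conv/pool stack")
  c(conv1 = p1, pool1 = q1, conv2 = p2, pool2 = q2,
    flat = q2 * config$conv_channels[2])
}

#' Fit the 1-D CNN spectral classifier
#'
#' Trains the convolutional network of [cnn_config()] on a labeled
#' [spectra_table]. The batch size is chosen by the table level (pixel or
#' object). Training is reproducible: the same `config$seed` gives
#' identical weights.
#'
#' @param train labeled [spectra_table] used for training.
#' @param val optional labeled [spectra_table]; its accuracy is recorded
#'   per epoch in the history (it does not influence training).
#' @param config a [cnn_config()].
#' @param epochs optional override of `config$epochs`.
#' @return An object of class `spectral_cnn` with elements `config`,
#'   `classes`, `wavelengths`, `weights`, `history` (per-epoch train loss,
#'   train accuracy, validation accuracy) and `feature_lengths`.
#' @seealso [predict.spectral_cnn()], [classify_seeds()]
#' @export
spectral_cnn <- function(train, val = NULL, config = cnn_config(),
                         epochs = NULL) {
  stopifnot(inherits(train, "spectra_table"), inherits(config, "cnn_config"))
  if (is.null(train$labels)) stop("training table has no labels")
  if (nrow(train$spectra) == 0L) stop("training table is empty")
  classes <- levels(train$labels)
  if (length(classes) != config$n_classes)
    stop("training labels have ", length(classes), " levels but config says ",
         config$n_classes, " classes")
  y <- as.integer(train$labels) - 1L
  batch <- if (train$level == "pixel") config$batch_size_pixel
           else config$batch_size_object
  xv <- NULL; yv <- NULL
  if (!is.null(val)) {
    stopifnot(inherits(val, "spectra_table"))
    if (ncol(val$spectra) != ncol(train$spectra))
      stop("validation band count differs from training")
    if (is.null(val$labels)) stop("validation table has no labels")
    if (!identical(levels(val$labels), classes))
      stop("validation label levels differ from training")
    xv <- val$spectra
    yv <- as.integer(val$labels) - 1L
  }
  fit <- cnn_train_cpp(train$spectra, y, xv, yv,
                       .cfg_cpp(config, batch, epochs))
  structure(list(config = config, classes = classes,
                 wavelengths = train$wavelengths,
                 level = train$level,
                 weights = fit$weights, history = fit$history,
                 feature_lengths = fit$feature_lengths,
                 flat_width = fit$flat_width),
            class = "spectral_cnn")
}

#' @export
print.spectral_cnn <- function(x, ...) {
  h <- x$history
  cat(sprintf("<spectral_cnn> %d classes (%s), %d input bands\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$wavelengths)))
  cat(sprintf("  conv %d/%d (k=%d), dense %d/%d/%d; trained %d epochs on %s spectra\n",
              x$config$conv_channels[1], x$config$conv_channels[2],
              x$config$kernel_size, x$config$dense_units[1],
              x$config$dense_units[2], x$config$n_classes, nrow(h), x$level))
  cat(sprintf("  final train loss %.4f, train acc %.3f", tail(h$train_loss, 1),
              tail(h$train_acc, 1)))
  if (!is.na(tail(h$val_acc, 1)))
    cat(sprintf(", val acc %.3f", tail(h$val_acc, 1)))
  cat("\n")
  invisible(x)
}

#' @export
summary.spectral_cnn <- function(object, ...) {
  fl <- object$feature_lengths
  cat("1-D CNN spectral classifier\n")
  cat(sprintf("  input: %d bands (%.1f-%.1f nm)\n", length(object$wavelengths),
              min(object$wavelengths), max(object$wavelengths)))
  cat(sprintf("  feature lengths: conv1 %d -> pool1 %d -> conv2 %d -> pool2 %d; flatten %d\n",
              fl[1], fl[2], fl[3], fl[4], object$flat_width))
  np <- sum(vapply(object$weights, length, 1L))
  cat(sprintf("  parameters: %d\n", np))
  print(object)
  invisible(object)
}

#' Predict class probabilities or labels
#'
#' Runs spectra through the trained network in evaluation mode (batch
#' normalization uses its running statistics).
#'
#' @param object a fitted [spectral_cnn()].
#' @param newdata a [spectra_table] or a plain matrix with matching band
#'   count.
#' @param type `"class"` for hard labels (factor), `"prob"` for the
#'   row-stochastic probability matrix.
#' @param ... unused.
#' @return Factor of length n, or an n x n_classes matrix.
#' @export
predict.spectral_cnn <- function(object, newdata,
                                 type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "spectra_table")) newdata$spectra
       else as.matrix(newdata)
  if (ncol(X) != length(object$wavelengths))
    stop("newdata has ", ncol(X), " bands; model expects ",
         length(object$wavelengths))
  cfg <- .cfg_cpp(object$config, 1L)
  P <- cnn_predict_cpp(object$weights, X, cfg)
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  factor(object$classes[max.col(P, ties.method = "first")],
         levels = object$classes)
}

#' Plot training history
#'
#' Draws the per-epoch training loss and the training/validation accuracy.
#'
#' @param x a fitted [spectral_cnn()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.spectral_cnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "train loss", ...)
  graphics::plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", ...)
  if (!all(is.na(h$val_acc)))
    graphics::lines(h$epoch, h$val_acc, lty = 2)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding weights, running
#' batch-normalization statistics, configuration and the class list.
#'
#' @param model a fitted [spectral_cnn()].
#' @param path checkpoint path.
#' @return `write_cnn` returns `path` invisibly; `read_cnn` the model.
#' @export
write_cnn <- function(model, path) {
  stopifnot(inherits(model, "spectral_cnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_cnn
#' @export
read_cnn <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "spectral_cnn"))
  model
}

#' Training log as CSV
#'
#' @param model a fitted [spectral_cnn()].
#' @param path output CSV path (epoch, train_loss, train_acc, val_acc).
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
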