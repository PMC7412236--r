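#' Network architecture specification
#'
#' Three compact 2D architectures for recurrence-image classification:
#'
#' * `"fcn"` — fully convolutional network: three 5x5 convolution blocks
#'   with 128, 256 and 128 channels, each followed by batch
#'   normalization and ReLU, then global average pooling and a softmax
#'   head. No fully-connected hidden layers, so the same weights accept
#'   any input side length >= 5.
#' * `"resnet"` — three residual blocks, each internally the FCN's three
#'   conv-BN-ReLU stages, with an additive shortcut (identity where
#'   channel counts match, 1x1 convolution + batch norm otherwise),
#'   global average pooling and softmax head.
#' * `"cnn"` — the plain baseline: two 3x3 convolutions of 32 channels,
#'   each followed by 2x2 max pooling, two fully-connected layers of 125
#'   units, softmax output. Needs input side >= 4 for its two pooling
#'   stages.
#'
#' @param kind One of `"fcn"`, `"resnet"`, `"cnn"`.
#' @param input_size Image side length the network will be trained on.
#'   Structural for `"cnn"` (its flatten layer); informational for the
#'   fully convolutional architectures.
#' @param n_classes Number of classes, >= 2.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(kind = c("fcn", "resnet", "cnn"),
                         input_size = 64L, n_classes = 2L) {
  kind <- match.arg(kind)
  input_size <- as.integer(input_size)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (kind == "cnn" && input_size < 4L)
    stop("cnn baseline needs input size >= 4 for its two 2x2 pooling stages")
  if (input_size < 5L && kind != "cnn")
    stop("input size must be >= 5 for the 5x5 convolutions")
  structure(list(kind = kind, input_size = input_size,
                 n_classes = n_classes),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", x$kind, " input", paste0(x$input_size, "x", x$input_size),
      " classes", x$n_classes, "\n")
  invisible(x)
}

#' Training configuration
#'
#' The training recipe: categorical cross-entropy loss under the Adam
#' optimizer. Defaults follow the benchmark recipe — learning rate 5e-5,
#' five repeated runs whose test errors are averaged. The epoch default
#' of 2000 matches the published visualization experiments; desk-scale
#' runs use far fewer epochs with a larger learning rate (see the
#' methods vignette).
#'
#' @param learning_rate Adam learning rate, > 0.
#' @param epochs Training epochs, >= 1.
#' @param batch_size Mini-batch size, >= 1.
#' @param n_repeats Number of repeated runs for [evaluate_repeated()].
#' @param seed Base RNG seed; run r of a repeated evaluation uses
#'   `seed + r - 1`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-5, epochs = 2000L,
                         batch_size = 32L, n_repeats = 5L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = as.integer(batch_size),
                 n_repeats = n_repeats, seed = as.integer(seed),
                 loss = "categorical_crossentropy", optimizer = "adam"),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat("<train_config> Adam lr", x$learning_rate, "| epochs", x$epochs,
      "| batch", x$batch_size, "| repeats", x$n_repeats,
      "| seed", x$seed, "\n")
  invisible(x)
}

# Coerce labels to integer class ids 1..K. Numeric labels are taken as
# ids directly; anything else goes through factor coding.
normalize_class_ids <- function(labels, n_classes) {
  if (is.numeric(labels)) {
    lab <- as.integer(labels)
    if (anyNA(lab) || any(lab < 1L) || any(lab > n_classes))
      stop("numeric labels must be class ids in 1..", n_classes)
  } else {
    f <- factor(as.character(labels))
    if (nlevels(f) > n_classes)
      stop("more label levels (", nlevels(f), ") than n_classes (",
           n_classes, ")")
    lab <- as.integer(f)
  }
  lab
}

as_image_cube <- function(images) {
  if (is.list(images))
    images <- simplify2array(lapply(images, unclass))
  images <- unclass(images)
  if (length(dim(images)) == 2L) dim(images) <- c(dim(images), 1L)
  if (length(dim(images)) != 3L)
    stop("images must be an H x W x N array or a list of matrices")
  if (dim(images)[1] != dim(images)[2])
    stop("images must be square")
  storage.mode(images) <- "double"
  images
}

# Global max-abs scaling: signed images to [-1, 1], unsigned to [0, 1].
# The scale is computed on the stack it is applied to.
scale_images <- function(images) {
  mx <- max(abs(images))
  if (mx > 0) images / mx else images
}

#' Build (initialize) a network
#'
#' Allocates and He-initializes all weights of the architecture under a
#' fixed seed, without training.
#'
#' @param spec A [network_spec()].
#' @param seed Initialization seed.
#' @return An `msrp_model`: list with `spec`, named `params`, `trained`
#'   flag and (after training) `history`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  params <- nn_init_cpp(spec$kind, spec$input_size, spec$n_classes,
                        as.integer(seed))
  structure(list(spec = spec, params = params, trained = FALSE,
                 history = NULL),
            class = "msrp_model")
}

#' @export
print.msrp_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<msrp_model>", x$spec$kind, "|", format(np, big.mark = ","),
      "parameters |", if (x$trained) "trained" else "untrained", "\n")
  if (!is.null(x$history))
    cat("  final loss", signif(utils::tail(x$history$loss, 1), 4),
        " train acc", signif(utils::tail(x$history$accuracy, 1), 4), "\n")
  invisible(x)
}

#' Count of convolutional weights in a model
#'
#' Sums the lengths of all convolution kernel tensors (biases, batch-norm
#' parameters and the softmax head excluded).
#'
#' @param model An `msrp_model`.
#' @return Integer weight count.
#' @export
conv_weight_count <- function(model) {
  nm <- names(model$params)
  keep <- grepl("conv[0-9s]*\\.W$", nm)
  sum(vapply(model$params[keep], length, 0L))
}

#' Train a network on an image stack
#'
#' Minimizes categorical cross-entropy with Adam at the configured
#' learning rate. Images are globally scaled by their maximum absolute
#' value before training (signed stacks to \[-1, 1\], unsigned to
#' \[0, 1\]); the scale is stored on the model and re-applied at
#' prediction. Training is fully reproducible given the seed.
#'
#' @param x A [network_spec()] (a fresh model is initialized from
#'   `cfg$seed`) or an existing `msrp_model`.
#' @param images H x W x N array (or list of `rp_image`s).
#' @param labels Integer class ids 1..K, factor, or character; every
#'   class must have at least one sample.
#' @param cfg A [train_config()].
#' @return A trained `msrp_model` with per-epoch `history` (`loss`,
#'   `accuracy`).
#' @export
train_network <- function(x, images, labels, cfg = train_config()) {
  images <- as_image_cube(images)
  if (inherits(x, "network_spec")) {
    if (dim(images)[1] != x$input_size)
      x <- network_spec(x$kind, input_size = dim(images)[1],
                        n_classes = x$n_classes)
    model <- build_network(x, seed = cfg$seed)
  } else if (inherits(x, "msrp_model")) {
    model <- x
  } else stop("x must be a network_spec or msrp_model")
  spec <- model$spec
  lab <- normalize_class_ids(labels, spec$n_classes)
  if (length(lab) != dim(images)[3])
    stop("got ", dim(images)[3], " images but ", length(lab), " labels")
  present <- tabulate(lab, nbins = spec$n_classes)
  if (any(present == 0L))
    stop("class ", which(present == 0L)[1], " has zero samples")
  mx <- max(abs(images))
  scaled <- if (mx > 0) images / mx else images
  fit <- nn_train_cpp(spec$kind, spec$input_size, spec$n_classes,
                      model$params, scaled, lab - 1L,
                      cfg$epochs, cfg$learning_rate, cfg$batch_size,
                      cfg$seed)
  structure(list(spec = spec, params = fit$params, trained = TRUE,
                 scale = mx,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      loss = fit$loss,
                                      accuracy = fit$accuracy)),
            class = "msrp_model")
}

#' Predict class probabilities / labels for an image stack
#'
#' @param model A trained `msrp_model`.
#' @param images H x W x N array (or list of `rp_image`s) matching the
#'   model's input size.
#' @return `predict_network`: N x K matrix of softmax probabilities (rows
#'   sum to 1). `classify_images`: integer vector of predicted class ids.
#' @export
predict_network <- function(model, images) {
  stopifnot(inherits(model, "msrp_model"))
  images <- as_image_cube(images)
  sc <- if (!is.null(model$scale) && model$scale > 0) model$scale else 1
  nn_predict_cpp(model$spec$kind, model$spec$input_size,
                 model$spec$n_classes, model$params, images / sc)
}

#' @rdname predict_network
#' @export
classify_images <- function(model, images) {
  max.col(predict_network(model, images), ties.method = "first")
}

#' Export the training history as CSV
#'
#' @param model A trained `msrp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  if (is.null(model$history)) stop("model has no training history")
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}

#' Mean test error over repeated training runs
#'
#' Trains `cfg$n_repeats` models from seeds `cfg$seed + 0 ... + n - 1`
#' and reports each run's test error and their mean — the repeated-run
#' averaging used for benchmark error rates.
#'
#' @param spec A [network_spec()].
#' @param train_images,train_labels Training stack.
#' @param test_images,test_labels Held-out stack.
#' @param cfg A [train_config()].
#' @return List with `mean_error`, `errors` (per run), and `models`
#'   (invisible payload: the fitted models).
#' @export
evaluate_repeated <- function(spec, train_images, train_labels,
                              test_images, test_labels,
                              cfg = train_config()) {
  errors <- numeric(cfg$n_repeats)
  models <- vector("list", cfg$n_repeats)
  for (r in seq_len(cfg$n_repeats)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    model <- train_network(spec, train_images, train_labels, cfg_r)
    pred <- classify_images(model, test_images)
    truth <- normalize_class_ids(test_labels, spec$n_classes)
    errors[r] <- error_rate(pred, truth)
    models[[r]] <- model
  }
  list(mean_error = mean(errors), errors = errors, models = models)
}
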