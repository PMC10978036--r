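#' CNN architecture configuration
#'
#' The image-quality network is deliberately small: two 3x3 convolutional
#' layers with ReLU activations (40 then 20 channels), global average pooling
#' of each channel to a scalar, and a dense weighted sum of the resulting
#' 20-element vector.  A sigmoid on top yields the good/bad classifier;
#' dropping the sigmoid exposes the raw logit, the real-valued image-quality
#' score used as a reconstruction penalty.  No bias terms anywhere, which
#' makes the score positively homogeneous: `score(c x) = c score(x)` for
#' `c > 0`.
#'
#' @param conv1_channels,conv2_channels Channel counts of the two
#'   convolutional layers.
#' @param kernel_size Odd kernel side length.
#' @param use_bias Include bias terms in the convolutions and the dense layer.
#' @param input_size Nominal input side length; the network is fully
#'   convolutional up to the pooling layer, so any input of at least
#'   `kernel_size` pixels is accepted at run time.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv1_channels = 40L, conv2_channels = 20L,
                       kernel_size = 3L, use_bias = FALSE,
                       input_size = 128L) {
  conv1_channels <- as.integer(conv1_channels)
  conv2_channels <- as.integer(conv2_channels)
  kernel_size <- as.integer(kernel_size)
  stopifnot(conv1_channels >= 1L, conv2_channels >= 1L,
            kernel_size >= 1L, kernel_size %% 2L == 1L,
            is.logical(use_bias), input_size >= kernel_size)
  structure(
    list(conv1_channels = conv1_channels, conv2_channels = conv2_channels,
         kernel_size = kernel_size, use_bias = use_bias,
         input_size = as.integer(input_size)),
    class = "cnn_config"
  )
}

#' Build the image-quality network
#'
#' Initializes a [cnn_config()] architecture with fan-in-scaled uniform
#' weights (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`), deterministically for a
#' given seed.  The returned model starts in `"classifier"` mode; flip it to
#' `"score"` mode with [set_mode()] to expose the pre-sigmoid logit used
#' during reconstruction.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `cnn_prior`.
#' @examples
#' m <- build_cnn(cnn_config(input_size = 64), seed = 1)
#' n_parameters(m)   # 7580 for the default architecture
#' @export
build_cnn <- function(config = cnn_config(), seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  .with_seed(as.integer(seed), {
    structure(
      list(config = config, weights = .init_weights(config),
           mode = "classifier", input_scale = 1.0, trained = FALSE),
      class = "cnn_prior"
    )
  })
}

# Fan-in-scaled uniform initialization, drawn from the current RNG stream.
.init_weights <- function(config) {
  k <- config$kernel_size
  c1 <- config$conv1_channels
  c2 <- config$conv2_channels
  init <- function(fan_in, n_out) {
    lim <- sqrt(6 / fan_in)
    matrix(stats::runif(fan_in * n_out, -lim, lim), fan_in, n_out)
  }
  w <- list(
    W1 = init(k * k, c1),            # (k*k*1) x c1
    W2 = init(k * k * c1, c2),       # (k*k*c1) x c2
    wd = as.numeric(init(c2, 1))     # dense weights, length c2
  )
  if (config$use_bias) {
    w$b1 <- numeric(c1); w$b2 <- numeric(c2); w$bd <- 0
  }
  w
}

#' @export
#' @method print cnn_prior
print.cnn_prior <- function(x, ...) {
  cat(sprintf(
    "Image-quality CNN: %dx%d kernels, %d->%d channels, GAP, dense (%s bias)\n",
    x$config$kernel_size, x$config$kernel_size, x$config$conv1_channels,
    x$config$conv2_channels, if (x$config$use_bias) "with" else "no"))
  cat(sprintf("  mode: %s | trained: %s | input scale: %.6g | %d parameters\n",
              x$mode, x$trained, x$input_scale, n_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param model A [build_cnn()] model.
#' @return Integer parameter count (7,580 for the default bias-free
#'   40/20-channel architecture: `3*3*1*40 + 3*3*40*20 + 20`).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "cnn_prior"))
  sum(vapply(model$weights, length, integer(1)))
}

#' Switch between classifier and score mode
#'
#' Classifier mode applies the output sigmoid and yields a probability in
#' (0, 1); score mode omits it and yields the raw logit in (-Inf, Inf).  The
#' two are linked by `classifier = sigmoid(score)` for identical weights.
#'
#' @param model A `cnn_prior`.
#' @param mode `"classifier"` or `"score"`.
#' @return The model with its mode set.
#' @export
set_mode <- function(model, mode = c("classifier", "score")) {
  stopifnot(inherits(model, "cnn_prior"))
  model$mode <- match.arg(mode)
  model
}

# Forward pass.  Images enter scaled by model$input_scale (a corpus-level
# constant fixed at training time so the score is a fixed function of the
# image during reconstruction).  Returns the score and, if keep = TRUE, the
# intermediates needed for backpropagation.
.cnn_forward <- function(model, image, keep = FALSE) {
  cfg <- model$config
  k <- cfg$kernel_size
  image <- as.matrix(image)
  N <- nrow(image)
  if (ncol(image) != N) stop("input image must be square")
  if (N < k) stop("input image smaller than the convolution kernel")
  if (!all(is.finite(image))) stop("input image contains non-finite values")
  w <- model$weights
  x <- image * model$input_scale
  cols1 <- im2col_cpp(array(x, c(N, N, 1L)), k)
  z1 <- cols1 %*% w$W1
  if (cfg$use_bias) z1 <- sweep(z1, 2, w$b1, "+")
  a1 <- pmax(z1, 0)
  cols2 <- im2col_cpp(array(a1, c(N, N, cfg$conv1_channels)), k)
  z2 <- cols2 %*% w$W2
  if (cfg$use_bias) z2 <- sweep(z2, 2, w$b2, "+")
  a2 <- pmax(z2, 0)
  v <- colMeans(a2)
  score <- sum(v * w$wd) + if (cfg$use_bias) w$bd else 0
  if (!keep) return(score)
  list(score = score, v = v, z1 = z1, z2 = z2, cols1 = cols1, cols2 = cols2,
       N = N)
}

.sigmoid <- function(s) 1 / (1 + exp(-s))

#' Raw CNN image-quality score (the logit)
#'
#' The pre-sigmoid output of the network: a real number in (-Inf, Inf) whose
#' larger values indicate more severe few-view streak artifacts.  This is the
#' quantity penalized by [reconstruct()].
#'
#' @param model A `cnn_prior`.
#' @param image Square numeric matrix, side at least `kernel_size`.
#' @return A single number.
#' @export
cnn_score <- function(model, image) {
  stopifnot(inherits(model, "cnn_prior"))
  .cnn_forward(model, image)
}

#' Classifier probability that an image is a "bad" few-view reconstruction
#'
#' Equal to `sigmoid(cnn_score(model, image))`.
#'
#' @inheritParams cnn_score
#' @return A probability in (0, 1).
#' @export
cnn_predict <- function(model, image) {
  .sigmoid(cnn_score(model, image))
}

# Shared backward pass; returns dscore/dx and, when with_weights = TRUE, the
# weight gradients (for a unit upstream derivative on the score).
.cnn_backward <- function(model, fw, with_weights = FALSE, with_input = TRUE) {
  cfg <- model$config
  k <- cfg$kernel_size
  w <- model$weights
  N <- fw$N
  npix <- N * N
  da2 <- matrix(rep(w$wd / npix, each = npix), nrow = npix)  # GAP backward
  dz2 <- da2 * (fw$z2 > 0)
  out <- list()
  if (with_weights) {
    out$dW2 <- crossprod(fw$cols2, dz2)
    out$dwd <- fw$v
    if (cfg$use_bias) { out$db2 <- colSums(dz2); out$dbd <- 1 }
  }
  dcols2 <- dz2 %*% t(w$W2)
  da1 <- matrix(col2im_cpp(dcols2, N, N, cfg$conv1_channels, k), nrow = npix)
  dz1 <- da1 * (fw$z1 > 0)
  if (with_weights) {
    out$dW1 <- crossprod(fw$cols1, dz1)
    if (cfg$use_bias) out$db1 <- colSums(dz1)
  }
  if (with_input) {
    dcols1 <- dz1 %*% t(w$W1)
    dx <- col2im_cpp(dcols1, N, N, 1L, k)
    out$dx <- matrix(dx, N, N) * model$input_scale
  }
  out
}

#' Gradient of the CNN score with respect to the input image
#'
#' Backpropagates a unit derivative on the score through the pooling, ReLUs
#' and convolutions.  At exactly-zero ReLU pre-activations the subgradient 0
#' is used.
#'
#' @inheritParams cnn_score
#' @return Numeric matrix of the same size as `image`.
#' @export
cnn_score_gradient <- function(model, image) {
  stopifnot(inherits(model, "cnn_prior"))
  fw <- .cnn_forward(model, image, keep = TRUE)
  .cnn_backward(model, fw, with_weights = FALSE, with_input = TRUE)$dx
}

#' Post-ReLU feature maps of a convolutional layer
#'
#' The channel activations the network computes on an image; on a trained
#' model these behave like edge/streak detectors and are useful for
#' qualitative inspection of what the score responds to.
#'
#' @inheritParams cnn_score
#' @param layer 1 or 2.
#' @return List of nonnegative matrices (one per channel: 40 for layer 1,
#'   20 for layer 2 at the default configuration).
#' @export
feature_maps <- function(model, image, layer) {
  stopifnot(inherits(model, "cnn_prior"))
  if (!layer %in% c(1L, 2L)) stop("layer must be 1 or 2")
  fw <- .cnn_forward(model, image, keep = TRUE)
  act <- if (layer == 1L) pmax(fw$z1, 0) else pmax(fw$z2, 0)
  lapply(seq_len(ncol(act)), function(c) matrix(act[, c], fw$N, fw$N))
}
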