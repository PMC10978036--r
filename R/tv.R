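#' Total-variation configuration
#'
#' Discrete TV with forward differences and replicate boundary (zero
#' difference at the last row/column).  The isotropic variant sums
#' `sqrt(Dx^2 + Dy^2 + eps^2)` over pixels; the anisotropic variant sums the
#' eps-smoothed absolute differences `sqrt(Dx^2 + eps^2) + sqrt(Dy^2 + eps^2)`.
#' `eps > 0` makes the norm differentiable everywhere and is required when a
#' gradient is requested.
#'
#' @param variant `"isotropic"` or `"anisotropic"`.
#' @param epsilon Smoothing constant, >= 0 (relative to unit-scaled images;
#'   default 1e-6).
#' @return An object of class `tv_config`.
#' @export
tv_config <- function(variant = c("isotropic", "anisotropic"),
                      epsilon = 1e-6) {
  variant <- match.arg(variant)
  stopifnot(length(epsilon) == 1L, epsilon >= 0)
  structure(list(variant = variant, epsilon = as.numeric(epsilon)),
            class = "tv_config")
}

.tv_diffs <- function(image) {
  N <- nrow(image); M <- ncol(image)
  dx <- cbind(image[, -1, drop = FALSE] - image[, -M, drop = FALSE],
              numeric(N))
  dy <- rbind(image[-1, , drop = FALSE] - image[-N, , drop = FALSE],
              numeric(M))
  list(dx = dx, dy = dy)
}

#' Total-variation norm of an image
#'
#' @param image Numeric matrix, at least 2x2.
#' @param cfg A [tv_config()].
#' @return A single nonnegative number.  On a constant image the isotropic
#'   variant returns the smoothing floor `N*M*eps` (0 when `eps = 0`).
#' @export
tv_norm <- function(image, cfg = tv_config()) {
  stopifnot(inherits(cfg, "tv_config"))
  image <- as.matrix(image)
  if (nrow(image) < 2L || ncol(image) < 2L) stop("image must be at least 2x2")
  d <- .tv_diffs(image)
  e2 <- cfg$epsilon^2
  if (cfg$variant == "isotropic") {
    sum(sqrt(d$dx^2 + d$dy^2 + e2))
  } else {
    sum(sqrt(d$dx^2 + e2) + sqrt(d$dy^2 + e2))
  }
}

#' Gradient of the smoothed total-variation norm
#'
#' Exact gradient of [tv_norm()] for `epsilon > 0`.  With `epsilon = 0` the
#' norm is not differentiable at zero differences and no subgradient is
#' provided.
#'
#' @inheritParams tv_norm
#' @return Numeric matrix of the same size as `image`.
#' @export
tv_gradient <- function(image, cfg = tv_config()) {
  stopifnot(inherits(cfg, "tv_config"))
  if (cfg$epsilon <= 0) {
    stop("tv_gradient requires epsilon > 0 (smoothed TV)")
  }
  image <- as.matrix(image)
  if (nrow(image) < 2L || ncol(image) < 2L) stop("image must be at least 2x2")
  N <- nrow(image); M <- ncol(image)
  d <- .tv_diffs(image)
  e2 <- cfg$epsilon^2
  if (cfg$variant == "isotropic") {
    phi <- sqrt(d$dx^2 + d$dy^2 + e2)
    px <- d$dx / phi            # d tv / d dx_ij
    py <- d$dy / phi
  } else {
    px <- d$dx / sqrt(d$dx^2 + e2)
    py <- d$dy / sqrt(d$dy^2 + e2)
  }
  # dx_ij = x[i, j+1] - x[i, j] (0 in last column), likewise dy down rows:
  # grad = -(px + py) + shift(px, right) + shift(py, down)
  g <- -(px + py)
  g[, -1] <- g[, -1] + px[, -M, drop = FALSE]
  g[-1, ] <- g[-1, ] + py[-N, , drop = FALSE]
  g
}
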