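#' Configuration of the random anatomical phantom generator
#'
#' Phantoms emulate axial CT slices at the distributional level: an elliptical
#' soft-tissue "body" containing a random number of piecewise-constant
#' elliptical structures with sharp boundaries, all inside the inscribed
#' reconstruction circle.  Sharp object boundaries are the image feature that
#' both the streak artifacts and the trained classifier latch onto, so they
#' are the property the generator preserves.
#'
#' @param image_size Side length of the phantom grid in pixels.
#' @param n_ellipses_range Inclusive integer range for the number of interior
#'   structures per phantom.
#' @param intensity_range Range of additive structure contrasts (may be
#'   negative; the final image is clipped at 0).
#' @param body_intensity Background soft-tissue value of the body ellipse.
#' @param noise_model `"none"` or `"gaussian"` (additive noise on sinograms
#'   when building a corpus).
#' @param noise_sigma Standard deviation of the sinogram noise, in line
#'   integral units.
#' @param seed Integer seed; the same `(seed, index)` pair always yields the
#'   same phantom.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 128L,
                           n_ellipses_range = c(3L, 8L),
                           intensity_range = c(-0.4, 0.6),
                           body_intensity = 1.0,
                           noise_model = c("none", "gaussian"),
                           noise_sigma = 0,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  image_size <- as.integer(image_size)
  n_ellipses_range <- as.integer(n_ellipses_range)
  stopifnot(
    image_size >= 2L,
    length(n_ellipses_range) == 2L,
    n_ellipses_range[1] >= 0L, n_ellipses_range[1] <= n_ellipses_range[2],
    length(intensity_range) == 2L, intensity_range[1] <= intensity_range[2],
    body_intensity >= 0, noise_sigma >= 0, length(seed) == 1L
  )
  structure(
    list(image_size = image_size, n_ellipses_range = n_ellipses_range,
         intensity_range = as.numeric(intensity_range),
         body_intensity = as.numeric(body_intensity),
         noise_model = noise_model, noise_sigma = as.numeric(noise_sigma),
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Run `expr` under a private RNG stream without disturbing the caller's
# .Random.seed.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derived per-phantom seed, kept inside 32-bit integer range.
.phantom_seed <- function(config, index) {
  as.integer((abs(config$seed) * 100003 + index * 7919) %% 2147483629)
}

.add_ellipse <- function(img, cx, cy, a, b, phi, value) {
  N <- nrow(img)
  cc <- (N - 1) / 2
  x <- outer(rep(1, N), seq_len(N) - 1 - cc - cx)   # column offsets
  y <- outer(seq_len(N) - 1 - cc - cy, rep(1, N))   # row offsets
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  img[inside] <- img[inside] + value
  img
}

#' Generate one random anatomical phantom
#'
#' A deterministic function of `(config$seed, index)`: an elliptical body at
#' `body_intensity` containing `k ~ Uniform(n_ellipses_range)` ellipses with
#' random centres, semi-axes and rotations inside the body, each adding a
#' contrast drawn from `intensity_range`; the result is clipped at 0 and all
#' structure lies inside the inscribed circle.
#'
#' @param config A [phantom_config()].
#' @param index Non-negative integer identifying the phantom.
#' @return Nonnegative `image_size` x `image_size` matrix.
#' @examples
#' ph <- generate_phantom(phantom_config(image_size = 64), index = 1)
#' range(ph)
#' @export
generate_phantom <- function(config, index) {
  stopifnot(inherits(config, "phantom_config"), index >= 0)
  N <- config$image_size
  .with_seed(.phantom_seed(config, index), {
    img <- matrix(0, N, N)
    # body ellipse: semi-axes 30-42% of N, slight centre jitter
    ba <- stats::runif(1, 0.30, 0.42) * N
    bb <- stats::runif(1, 0.30, 0.42) * N
    bphi <- stats::runif(1, 0, pi)
    bcx <- stats::runif(1, -0.04, 0.04) * N
    bcy <- stats::runif(1, -0.04, 0.04) * N
    img <- .add_ellipse(img, bcx, bcy, ba, bb, bphi, config$body_intensity)
    k <- if (config$n_ellipses_range[1] == config$n_ellipses_range[2]) {
      config$n_ellipses_range[1]
    } else {
      sample(config$n_ellipses_range[1]:config$n_ellipses_range[2], 1)
    }
    for (e in seq_len(k)) {
      # centre well inside the body so the structure stays within it
      rad <- stats::runif(1, 0, 0.55) * min(ba, bb)
      ang <- stats::runif(1, 0, 2 * pi)
      a <- stats::runif(1, 0.03, 0.13) * N
      b <- stats::runif(1, 0.03, 0.13) * N
      phi <- stats::runif(1, 0, pi)
      val <- stats::runif(1, config$intensity_range[1], config$intensity_range[2])
      img <- .add_ellipse(img, bcx + rad * cos(ang), bcy + rad * sin(ang),
                          a, b, phi, val)
    }
    pmax(img, 0)
  })
}

#' Build a labelled good/bad reconstruction corpus
#'
#' For each of `n_pairs` phantoms, forward-projects with a few-view and a
#' full-view geometry (optionally adding Gaussian sinogram noise), runs
#' [fbp()] on both, and labels the few-view reconstruction 1 ("bad") and the
#' full-view reconstruction 0 ("good").  The same phantom is used for both
#' members of a pair; class balance is exact by construction.
#'
#' @param config A [phantom_config()]; `image_size` must match the geometries.
#' @param n_pairs Number of phantom pairs (>= 1).
#' @param few_view_geom,full_view_geom Two [geometry()] objects differing only
#'   in `n_views`.
#' @param start_index Index of the first phantom; use disjoint ranges for
#'   train/test corpora drawn from the same configuration.
#' @return An object of class `tomo_corpus`: a list with `images` (array
#'   `2 n_pairs` x N x N), `labels` (integer vector), `provenance` (data frame
#'   of phantom index, derived seed and `n_views` used), plus the config and
#'   geometries.
#' @export
build_corpus <- function(config, n_pairs, few_view_geom, full_view_geom,
                         start_index = 1L) {
  stopifnot(inherits(config, "phantom_config"),
            inherits(few_view_geom, "tomo_geometry"),
            inherits(full_view_geom, "tomo_geometry"))
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  same_but_views <- identical(
    unclass(few_view_geom)[c("n_bins", "angular_span_deg", "image_size", "pixel_spacing")],
    unclass(full_view_geom)[c("n_bins", "angular_span_deg", "image_size", "pixel_spacing")]
  )
  if (!same_but_views) stop("the two geometries must differ only in n_views")
  if (few_view_geom$image_size != config$image_size) {
    stop("geometry image_size does not match phantom config")
  }
  N <- config$image_size
  n <- 2L * as.integer(n_pairs)
  images <- array(0, dim = c(n, N, N))
  labels <- integer(n)
  prov <- data.frame(index = integer(n), seed = integer(n), n_views = integer(n))
  for (p in seq_len(n_pairs)) {
    idx <- start_index + p - 1L
    ph <- generate_phantom(config, idx)
    for (cls in 0:1) {
      g <- if (cls == 1L) few_view_geom else full_view_geom
      sino <- forward_project(ph, g)
      if (config$noise_model == "gaussian" && config$noise_sigma > 0) {
        noise_seed <- as.integer((.phantom_seed(config, idx) + cls + 1) %% 2147483629)
        sino$values <- sino$values + .with_seed(noise_seed, matrix(
          stats::rnorm(length(sino$values), sd = config$noise_sigma),
          nrow = nrow(sino$values)))
      }
      rec <- fbp(sino, g)
      row <- 2L * (p - 1L) + cls + 1L
      images[row, , ] <- rec
      labels[row] <- cls
      prov$index[row] <- idx
      prov$seed[row] <- .phantom_seed(config, idx)
      prov$n_views[row] <- g$n_views
    }
  }
  structure(list(images = images, labels = labels, provenance = prov,
                 config = config,
                 few_view_geom = few_view_geom, full_view_geom = full_view_geom),
            class = "tomo_corpus")
}

#' @export
#' @method print tomo_corpus
print.tomo_corpus <- function(x, ...) {
  cat(sprintf("Labelled corpus: %d images (%d per class), %dx%d\n",
              length(x$labels), sum(x$labels == 0), dim(x$images)[2],
              dim(x$images)[3]))
  invisible(x)
}

#' Streak-artifact statistic of a reconstruction
#'
#' Mean absolute discrete Laplacian outside a support mask.  Few-view FBP
#' images spray streaks across the empty background, so this statistic
#' separates the two corpus classes without any learning; it is used to
#' confirm that the classification task posed to the CNN is non-degenerate.
#'
#' @param image Reconstruction to score.
#' @param support_mask Logical mask of the object support (e.g. `phantom > 0`);
#'   the statistic is computed over its complement, restricted to the
#'   inscribed circle.
#' @return A single nonnegative number.
#' @export
streak_statistic <- function(image, support_mask) {
  image <- as.matrix(image)
  N <- nrow(image)
  stopifnot(all(dim(support_mask) == dim(image)))
  lap <- matrix(0, N, N)
  inner_r <- 2:(N - 1)
  lap[inner_r, inner_r] <-
    image[inner_r - 1, inner_r] + image[inner_r + 1, inner_r] +
    image[inner_r, inner_r - 1] + image[inner_r, inner_r + 1] -
    4 * image[inner_r, inner_r]
  sel <- !support_mask & inscribed_circle_mask(N)
  mean(abs(lap[sel]))
}
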