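#' Parallel-beam acquisition geometry
#'
#' Describes a 2-D parallel-beam scan: `n_views` equally spaced projection
#' angles covering `angular_span_deg` degrees (endpoint excluded, so a 180
#' degree span has no duplicated opposing view), a flat detector with `n_bins`
#' bins whose width equals `pixel_spacing`, and a square `image_size` x
#' `image_size` reconstruction grid.  The geometry defines the projection
#' operator applied by [forward_project()] and its adjoint [back_project()].
#'
#' Conventions: the image centre sits at pixel `((N-1)/2, (N-1)/2)` (0-based);
#' detector bin `b` has signed offset `(b - (n_bins-1)/2) * pixel_spacing`;
#' the view angle is measured from the +x axis and rays run perpendicular to
#' the detector.
#'
#' @param n_views Number of projection angles (>= 1).
#' @param n_bins Number of detector bins (>= 1).
#' @param angular_span_deg Total angular coverage in degrees, in (0, 360].
#' @param image_size Side length of the square image grid in pixels (>= 2).
#' @param pixel_spacing Physical width of one pixel (and one detector bin).
#' @return An object of class `tomo_geometry`.
#' @examples
#' g <- geometry(n_views = 45, n_bins = 128, image_size = 128)
#' g
#' @export
geometry <- function(n_views, n_bins = 128L, angular_span_deg = 180,
                     image_size = 128L, pixel_spacing = 1.0) {
  n_views <- as.integer(n_views)
  n_bins <- as.integer(n_bins)
  image_size <- as.integer(image_size)
  stopifnot(
    length(n_views) == 1L, n_views >= 1L,
    length(n_bins) == 1L, n_bins >= 1L,
    length(image_size) == 1L, image_size >= 2L,
    length(angular_span_deg) == 1L, angular_span_deg > 0,
    angular_span_deg <= 360, length(pixel_spacing) == 1L, pixel_spacing > 0
  )
  structure(
    list(n_views = n_views, n_bins = n_bins,
         angular_span_deg = as.numeric(angular_span_deg),
         image_size = image_size, pixel_spacing = as.numeric(pixel_spacing)),
    class = "tomo_geometry"
  )
}

#' @export
#' @method print tomo_geometry
print.tomo_geometry <- function(x, ...) {
  cat(sprintf(
    "Parallel-beam geometry: %d views over %g deg, %d bins, %dx%d image (spacing %g)\n",
    x$n_views, x$angular_span_deg, x$n_bins, x$image_size, x$image_size,
    x$pixel_spacing))
  invisible(x)
}

#' View angles of a geometry, in radians
#'
#' Equally spaced over the angular span with the endpoint excluded:
#' `angle_k = k * span / n_views`, `k = 0 ... n_views - 1`.
#'
#' @param geom A [geometry()].
#' @return Numeric vector of length `n_views`.
#' @export
view_angles <- function(geom) {
  stopifnot(inherits(geom, "tomo_geometry"))
  (seq_len(geom$n_views) - 1) * geom$angular_span_deg / geom$n_views * pi / 180
}

#' Sinogram container
#'
#' Couples an `n_views` x `n_bins` matrix of line integrals with the geometry
#' that produced it.
#'
#' @param values Numeric matrix, `n_views` rows by `n_bins` columns.
#' @param geom The [geometry()] the values correspond to.
#' @return An object of class `tomo_sinogram`.
#' @export
sinogram <- function(values, geom) {
  stopifnot(inherits(geom, "tomo_geometry"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(geom$n_views, geom$n_bins))) {
    stop("sinogram values must be n_views x n_bins (",
         geom$n_views, " x ", geom$n_bins, "), got ",
         paste(dim(values), collapse = " x "))
  }
  if (!all(is.finite(values))) stop("sinogram contains non-finite values")
  structure(list(values = values, geometry = geom), class = "tomo_sinogram")
}

#' @export
#' @method print tomo_sinogram
print.tomo_sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d views x %d bins, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

.check_image <- function(image, geom) {
  image <- as.matrix(image)
  if (!all(dim(image) == c(geom$image_size, geom$image_size))) {
    stop("image must be ", geom$image_size, " x ", geom$image_size,
         ", got ", paste(dim(image), collapse = " x "))
  }
  if (!all(is.finite(image))) stop("image contains non-finite values")
  image
}

# Cache of assembled system matrices, keyed by the geometry fields.  A matrix
# for a 128x128 / 360-view scan holds ~12M non-zeros (~190 MB as dgCMatrix),
# so re-assembly per call would dominate every pipeline.
.proj_cache <- new.env(parent = emptyenv())

.geom_key <- function(geom) {
  paste(geom$n_views, geom$n_bins, geom$angular_span_deg, geom$image_size,
        geom$pixel_spacing, sep = "|")
}

#' Sparse system matrix of the parallel-beam projector
#'
#' Assembles the Joseph-style ray-driven projector with linear interpolation
#' as a sparse matrix `A` of dimension `(n_views * n_bins)` x `image_size^2`
#' (rows ordered bin-fastest, pixels in column-major order).  Each ray steps
#' along its dominant axis; at each step the image is linearly interpolated
#' across the perpendicular axis and weighted by the step length along the
#' ray.  [back_project()] applies `t(A)`, so the adjoint identity
#' `<Ax, y> == <x, t(A) y>` holds to machine precision by construction.
#'
#' Matrices are cached per geometry for the lifetime of the session.
#'
#' @param geom A [geometry()].
#' @return A `dgCMatrix`.
#' @export
system_matrix <- function(geom) {
  stopifnot(inherits(geom, "tomo_geometry"))
  key <- .geom_key(geom)
  if (!is.null(.proj_cache[[key]])) return(.proj_cache[[key]])

  N <- geom$image_size
  nb <- geom$n_bins
  sp <- geom$pixel_spacing
  cc <- (N - 1) / 2                      # centre, 0-based pixel units
  s <- (seq_len(nb) - 1 - (nb - 1) / 2)  # bin offsets in pixel units
  angles <- view_angles(geom)

  ri <- vector("list", geom$n_views)
  ci <- vector("list", geom$n_views)
  wi <- vector("list", geom$n_views)
  for (k in seq_len(geom$n_views)) {
    th <- angles[k]
    ct <- cos(th); st <- sin(th)
    if (abs(ct) >= abs(st)) {
      # step over rows (y), interpolate across columns (x):
      # ray x*ct + y*st = s  =>  x = (s - y*st) / ct
      ell <- sp / abs(ct)
      y <- seq_len(N) - 1 - cc
      u <- outer(y, s, function(yy, ss) (ss - yy * st) / ct) + cc  # 0-based col
      step_idx <- row(u)                 # row index i of the pixel
      j0 <- floor(u)
      fr <- u - j0
      # neighbour (j0, weight 1-fr) and (j0+1, weight fr)
      pix_of <- function(i, j) i + j * N  # 1-based row i, 0-based col j
      keep1 <- j0 >= 0 & j0 <= N - 1
      keep2 <- j0 + 1 >= 0 & j0 + 1 <= N - 1
      bin_idx <- col(u)
      rows1 <- (k - 1L) * nb + bin_idx[keep1]
      rows2 <- (k - 1L) * nb + bin_idx[keep2]
      cols1 <- pix_of(step_idx[keep1], j0[keep1])
      cols2 <- pix_of(step_idx[keep2], j0[keep2] + 1)
      w1 <- (1 - fr[keep1]) * ell
      w2 <- fr[keep2] * ell
    } else {
      # step over columns (x), interpolate across rows (y)
      ell <- sp / abs(st)
      x <- seq_len(N) - 1 - cc
      v <- outer(x, s, function(xx, ss) (ss - xx * ct) / st) + cc  # 0-based row
      step_idx <- row(v)                 # column index j of the pixel
      i0 <- floor(v)
      fr <- v - i0
      keep1 <- i0 >= 0 & i0 <= N - 1
      keep2 <- i0 + 1 >= 0 & i0 + 1 <= N - 1
      bin_idx <- col(v)
      rows1 <- (k - 1L) * nb + bin_idx[keep1]
      rows2 <- (k - 1L) * nb + bin_idx[keep2]
      cols1 <- i0[keep1] + 1L + (step_idx[keep1] - 1L) * N
      cols2 <- i0[keep2] + 2L + (step_idx[keep2] - 1L) * N
      w1 <- (1 - fr[keep1]) * ell
      w2 <- fr[keep2] * ell
    }
    ri[[k]] <- c(rows1, rows2)
    ci[[k]] <- c(cols1, cols2)
    wi[[k]] <- c(w1, w2)
  }
  A <- Matrix::sparseMatrix(
    i = unlist(ri), j = unlist(ci), x = unlist(wi),
    dims = c(geom$n_views * nb, N * N)
  )
  .proj_cache[[key]] <- A
  A
}

#' Forward projection (Radon transform)
#'
#' Applies the projection operator `A` to an image, producing the sinogram of
#' line integrals along parallel rays at every (angle, bin).  Linear in the
#' image and exactly adjoint to [back_project()].
#'
#' @param image Numeric `image_size` x `image_size` matrix of attenuation.
#' @param geom A [geometry()].
#' @return A [sinogram()].
#' @export
forward_project <- function(image, geom) {
  stopifnot(inherits(geom, "tomo_geometry"))
  image <- .check_image(image, geom)
  A <- system_matrix(geom)
  y <- as.numeric(A %*% as.vector(image))
  # rows are ordered bin-fastest: reshape to bins x views, then transpose
  sinogram(t(matrix(y, nrow = geom$n_bins)), geom)
}

#' Backprojection (adjoint of the forward projector)
#'
#' Applies `t(A)` to a sinogram: each detector reading is smeared back along
#' its ray with the same interpolation weights used in [forward_project()],
#' so the pair satisfies the adjoint identity exactly.  This is the operator
#' needed for the gradient of the data-fidelity term `||AX - Y||^2`, which is
#' `2 t(A) (AX - Y)`; it is not, by itself, an inverse.
#'
#' @param sino A [sinogram()] (or an `n_views` x `n_bins` matrix).
#' @param geom A [geometry()]; must match the sinogram's geometry.
#' @return Numeric `image_size` x `image_size` matrix.
#' @export
back_project <- function(sino, geom) {
  stopifnot(inherits(geom, "tomo_geometry"))
  vals <- if (inherits(sino, "tomo_sinogram")) {
    if (!identical(unclass(sino$geometry), unclass(geom))) {
      stop("sinogram geometry does not match the supplied geometry")
    }
    sino$values
  } else as.matrix(sino)
  if (!all(dim(vals) == c(geom$n_views, geom$n_bins))) {
    stop("sinogram must be n_views x n_bins")
  }
  A <- system_matrix(geom)
  x <- as.numeric(Matrix::crossprod(A, as.vector(t(vals))))
  matrix(x, nrow = geom$image_size)
}

#' Filtered backprojection
#'
#' Classic parallel-beam FBP: each view is ramp-filtered along the bin axis
#' (frequency-domain Ram-Lak on rows zero-padded to at least twice the next
#' power of two, no apodization window) and backprojected with pixel-driven
#' linear interpolation; the accumulated image is scaled by
#' `pi / (2 n_views) * (angular_span_deg / 180)`.  Deterministic for a fixed
#' input.  Accurate only inside the inscribed circle (see
#' [inscribed_circle_mask()]); with few views the result shows the familiar
#' angular-aliasing streaks.
#'
#' @param sino A [sinogram()] (or matrix).
#' @param geom A [geometry()].
#' @return Numeric `image_size` x `image_size` matrix.
#' @export
fbp <- function(sino, geom) {
  stopifnot(inherits(geom, "tomo_geometry"))
  if (geom$n_bins < 2L) stop("fbp requires at least 2 detector bins")
  vals <- if (inherits(sino, "tomo_sinogram")) {
    if (!identical(unclass(sino$geometry), unclass(geom))) {
      stop("sinogram geometry does not match the supplied geometry")
    }
    sino$values
  } else as.matrix(sino)
  if (!all(dim(vals) == c(geom$n_views, geom$n_bins))) {
    stop("sinogram must be n_views x n_bins")
  }
  N <- geom$image_size
  nb <- geom$n_bins
  sp <- geom$pixel_spacing

  # Ram-Lak filtering in the frequency domain, one FFT per view.  The ramp is
  # the DFT of the band-limited spatial kernel (1/4 at 0, -1/(pi n)^2 at odd
  # lags), not a direct sampling of |f|, which would bias the low frequencies.
  P <- 2^ceiling(log2(2 * nb))
  n_idx <- c(seq(0, P / 2), seq(-P / 2 + 1, -1))
  h <- numeric(P)
  h[1] <- 1 / 4
  odd <- which(n_idx %% 2 != 0)
  h[odd] <- -1 / (pi * n_idx[odd])^2
  ramp <- 2 * Re(stats::fft(h)) / sp
  padded <- rbind(t(vals), matrix(0, P - nb, geom$n_views))
  filt <- Re(stats::mvfft(stats::mvfft(padded) * ramp, inverse = TRUE)) / P
  filt <- filt[seq_len(nb), , drop = FALSE]               # bins x views

  # Pixel-driven backprojection with linear interpolation.
  cc <- (N - 1) / 2
  xg <- rep(seq_len(N) - 1 - cc, each = N)                # column coordinate
  yg <- rep(seq_len(N) - 1 - cc, times = N)               # row coordinate
  angles <- view_angles(geom)
  acc <- numeric(N * N)
  half <- (nb - 1) / 2
  for (k in seq_len(geom$n_views)) {
    t0 <- xg * cos(angles[k]) + yg * sin(angles[k]) + half  # 0-based bin coord
    i0 <- floor(t0)
    fr <- t0 - i0
    qa <- qb <- numeric(N * N)
    ok0 <- i0 >= 0 & i0 <= nb - 1
    ok1 <- i0 + 1 >= 0 & i0 + 1 <= nb - 1
    qa[ok0] <- filt[i0[ok0] + 1L, k]
    qb[ok1] <- filt[i0[ok1] + 2L, k]
    acc <- acc + (1 - fr) * qa + fr * qb
  }
  scale <- pi / (2 * geom$n_views) * (geom$angular_span_deg / 180) * sp
  matrix(acc * scale, nrow = N)
}

#' Mask of the inscribed reconstruction circle
#'
#' FBP is only valid inside the circle inscribed in the image square; metrics
#' in this package are evaluated there.
#'
#' @param geom A [geometry()] (or a single integer image size).
#' @return Logical `image_size` x `image_size` matrix, `TRUE` inside.
#' @export
inscribed_circle_mask <- function(geom) {
  N <- if (inherits(geom, "tomo_geometry")) geom$image_size else as.integer(geom)
  cc <- (N - 1) / 2
  d <- (seq_len(N) - 1 - cc)^2
  outer(d, d, "+") <= (N / 2)^2
}

#' Root-mean-square error inside the reconstruction circle
#'
#' @param image,reference Images of identical size.
#' @param mask Optional logical mask; defaults to the inscribed circle.
#' @param relative If `TRUE`, divide by the RMS of `reference` over the mask.
#' @return A single number.
#' @export
rmse_in_circle <- function(image, reference, mask = NULL, relative = FALSE) {
  image <- as.matrix(image); reference <- as.matrix(reference)
  stopifnot(all(dim(image) == dim(reference)))
  if (is.null(mask)) mask <- inscribed_circle_mask(nrow(image))
  err <- sqrt(mean((image[mask] - reference[mask])^2))
  if (relative) err / sqrt(mean(reference[mask]^2)) else err
}
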