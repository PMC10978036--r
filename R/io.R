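#' Write an image as 32-bit float TIFF with a range sidecar
#'
#' TIFF float samples are stored normalized to [0, 1]; the affine range
#' (`lo`, `hi`) is written to a JSON sidecar `<path>.json` so that
#' [read_image()] restores the original intensity scale (to 32-bit float
#' precision).  Constant images are stored with a degenerate range and
#' restored exactly.
#'
#' @param image Numeric matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image contains non-finite values")
  lo <- min(image); hi <- max(image)
  norm <- if (hi > lo) (image - lo) / (hi - lo) else image * 0
  tiff::writeTIFF(norm, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(lo = lo, hi = hi, nrow = nrow(image),
                            ncol = ncol(image)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path TIFF path (its `.json` sidecar must sit next to it).
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing range sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  norm <- tiff::readTIFF(path)
  if (length(dim(norm)) == 3L) norm <- norm[, , 1]
  norm * (meta$hi - meta$lo) + meta$lo
}

#' Serialize a geometry to JSON
#'
#' Writes exactly the five geometry fields.
#'
#' @param geom A [geometry()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "tomo_geometry"))
  jsonlite::write_json(unclass(geom), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a geometry from JSON
#'
#' @param path JSON path written by [write_geometry()].
#' @return A [geometry()].
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  geometry(n_views = j$n_views, n_bins = j$n_bins,
           angular_span_deg = j$angular_span_deg,
           image_size = j$image_size, pixel_spacing = j$pixel_spacing)
}

#' Write a sinogram as CSV with a geometry sidecar
#'
#' The `n_views` x `n_bins` matrix is written as headerless CSV (one view per
#' row); the geometry goes to `<path>.json`.
#'
#' @param sino A [sinogram()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "tomo_sinogram"))
  utils::write.table(sino$values, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  write_geometry(sino$geometry, paste0(path, ".json"))
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path CSV path (its `.json` geometry sidecar must sit next to it).
#' @return A [sinogram()].
#' @export
read_sinogram <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing geometry sidecar: ", side)
  geom <- read_geometry(side)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  sinogram(vals, geom)
}

#' Save CNN weights and configuration as JSON
#'
#' @param model A `cnn_prior`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_cnn <- function(model, path) {
  stopifnot(inherits(model, "cnn_prior"))
  payload <- list(
    config = unclass(model$config),
    input_scale = model$input_scale,
    mode = model$mode,
    trained = model$trained,
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a CNN saved by [save_cnn()]
#'
#' @param path JSON path.
#' @return A `cnn_prior`.
#' @export
load_cnn <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- cnn_config(conv1_channels = j$config$conv1_channels,
                    conv2_channels = j$config$conv2_channels,
                    kernel_size = j$config$kernel_size,
                    use_bias = isTRUE(j$config$use_bias),
                    input_size = j$config$input_size)
  weights <- lapply(j$weights, function(w) {
    if (length(w$dim) == 2L) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  expected <- if (cfg$use_bias) c("W1", "W2", "wd", "b1", "b2", "bd")
              else c("W1", "W2", "wd")
  if (!setequal(names(weights), expected)) {
    stop("weights file does not match the declared architecture")
  }
  structure(list(config = cfg, weights = weights[expected],
                 mode = if (identical(j$mode, "score")) "score" else "classifier",
                 input_scale = j$input_scale,
                 trained = isTRUE(j$trained)),
            class = "cnn_prior")
}

#' Save a labelled corpus
#'
#' Corpora are session artifacts; they are stored as a single RDS file.
#'
#' @param corpus A `tomo_corpus`.
#' @param path Output RDS path.
#' @return `path`, invisibly.
#' @export
save_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "tomo_corpus"))
  saveRDS(corpus, path)
  invisible(path)
}

#' Load a corpus saved by [save_corpus()]
#'
#' @param path RDS path.
#' @return A `tomo_corpus`.
#' @export
load_corpus <- function(path) {
  corpus <- readRDS(path)
  if (!inherits(corpus, "tomo_corpus")) stop("not a corpus file: ", path)
  corpus
}

#' Write a reconstruction trace as CSV
#'
#' @param recon A `tomo_recon` (or its trace data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(recon, path) {
  tr <- if (inherits(recon, "tomo_recon")) recon$trace else recon
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
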