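#' Calibrated 2D fluorescence image
#'
#' A minimal container for a single-channel image with physical calibration.
#' Pixels are stored as an H x W numeric matrix (rows = y, columns = x).
#' Physical coordinates are in nanometres with the origin at the *center* of
#' pixel \code{[1, 1]}; x increases rightward (columns), y increases downward
#' (rows), so \code{x_nm = (col - 1) * pixel_size_nm}.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param pixel_size_nm pixel size in nm (> 0).
#' @param channel channel label, e.g. \code{"actin"} or \code{"vinculin"}.
#' @return an object of class \code{image2d}.
#' @export
image2d <- function(pixels, pixel_size_nm, channel = "actin") {
  pixels <- as.matrix(pixels)
  stopifnot(is.numeric(pixels), nrow(pixels) >= 1, ncol(pixels) >= 1)
  if (!all(is.finite(pixels))) stop("image2d: all pixel values must be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 || pixel_size_nm <= 0)
    stop("image2d: pixel_size_nm must be a single positive number")
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 channel = as.character(channel)),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d px, %.4g nm/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Calibrated time-lapse stack
#'
#' Frames are stored as an H x W x T array sharing one spatial calibration;
#' \code{dt_s} is the frame interval in seconds.
#'
#' @param frames numeric array H x W x T with T >= 2.
#' @param pixel_size_nm pixel size in nm.
#' @param dt_s frame interval in seconds (> 0).
#' @param channel channel label.
#' @return an object of class \code{image_stack}.
#' @export
image_stack <- function(frames, pixel_size_nm, dt_s, channel = "actin") {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] < 2) stop("image_stack: need at least 2 frames")
  if (!all(is.finite(frames))) stop("image_stack: all values must be finite")
  if (dt_s <= 0) stop("image_stack: dt_s must be positive")
  if (pixel_size_nm <= 0) stop("image_stack: pixel_size_nm must be positive")
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 dt_s = dt_s, channel = as.character(channel)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d frames of %d x %d px, %.4g nm/px, dt = %.3g s\n",
              d[3], d[1], d[2], x$pixel_size_nm, x$dt_s))
  invisible(x)
}

#' @rdname image_stack
#' @param x object to extract a frame from.
#' @param t frame index.
#' @export
get_frame <- function(x, t) {
  stopifnot(inherits(x, "image_stack"))
  image2d(x$frames[, , t], x$pixel_size_nm, x$channel)
}

# nm -> fractional (1-based) pixel index along one axis
nm_to_px <- function(nm, pixel_size_nm) nm / pixel_size_nm + 1
px_to_nm <- function(px, pixel_size_nm) (px - 1) * pixel_size_nm

#' Bilinear sampling of a pixel matrix
#'
#' Samples intensities at fractional pixel positions (1-based column/row
#' indices). Positions outside the image return \code{NA}.
#'
#' @param pixels numeric matrix.
#' @param col,row fractional 1-based indices (vectors of equal length).
#' @return numeric vector of sampled intensities.
#' @keywords internal
sample_bilinear <- function(pixels, col, row) {
  H <- nrow(pixels); W <- ncol(pixels)
  out <- rep(NA_real_, length(col))
  ok <- col >= 1 & col <= W & row >= 1 & row <= H
  if (!any(ok)) return(out)
  c0 <- pmin(floor(col[ok]), W - 1); r0 <- pmin(floor(row[ok]), H - 1)
  fc <- col[ok] - c0; fr <- row[ok] - r0
  i00 <- (c0 - 1) * H + r0         # [r0, c0]
  v <- (1 - fr) * (1 - fc) * pixels[i00] +
       fr       * (1 - fc) * pixels[i00 + 1] +
       (1 - fr) * fc       * pixels[i00 + H] +
       fr       * fc       * pixels[i00 + H + 1]
  out[ok] <- v
  out
}

# Separable Gaussian filter with replicate boundary handling.
gaussian_blur_mat <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  # rows (y), then columns (x)
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  m1 <- apply(mp, 2, function(v) stats::filter(v, k, sides = 2))[(r + 1):(r + nrow(m)), , drop = FALSE]
  mp <- m1[, pad_idx(ncol(m)), drop = FALSE]
  m2 <- t(apply(mp, 1, function(v) stats::filter(v, k, sides = 2)))[, (r + 1):(r + ncol(m)), drop = FALSE]
  m2
}

#' Write / read calibrated TIFF images
#'
#' Images are stored as 32-bit TIFF with intensities affinely mapped into
#' [0, 1]; the mapping (offset, scale) and the physical calibration are
#' recorded in a JSON sidecar manifest \code{<path>.json}, which
#' \code{read_image_tiff()} and \code{read_stack_tiff()} use to restore the
#' original intensity scale and calibration.
#'
#' @param img an \code{image2d}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "image2d"))
  .write_tiff_frames(list(img$pixels), path,
                     list(pixel_size_nm = img$pixel_size_nm, channel = img$channel))
  invisible(path)
}

#' @rdname write_image_tiff
#' @param stack an \code{image_stack}.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- lapply(seq_len(dim(stack$frames)[3]), function(t) stack$frames[, , t])
  .write_tiff_frames(frames, path,
                     list(pixel_size_nm = stack$pixel_size_nm, dt_s = stack$dt_s,
                          channel = stack$channel))
  invisible(path)
}

.write_tiff_frames <- function(frames, path, meta) {
  lo <- min(vapply(frames, min, 0)); hi <- max(vapply(frames, max, 0))
  scale <- if (hi > lo) hi - lo else 1
  scaled <- lapply(frames, function(m) (m - lo) / scale)
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta$intensity_offset <- lo
  meta$intensity_scale <- scale
  meta$n_frames <- length(frames)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_tiff_frames <- function(path) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  off <- if (!is.null(meta$intensity_offset)) meta$intensity_offset else 0
  sc <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  frames <- lapply(frames, function(m) m * sc + off)
  list(frames = frames, meta = meta)
}

#' @rdname write_image_tiff
#' @param pixel_size_nm calibration override; required when no sidecar
#'   manifest is present.
#' @export
read_image_tiff <- function(path, pixel_size_nm = NULL) {
  r <- .read_tiff_frames(path)
  px <- if (!is.null(pixel_size_nm)) pixel_size_nm else r$meta$pixel_size_nm
  if (is.null(px)) stop("read_image_tiff: pixel_size_nm not given and no sidecar manifest found")
  ch <- if (!is.null(r$meta$channel)) r$meta$channel else "unknown"
  image2d(r$frames[[1]], px, ch)
}

#' @rdname write_image_tiff
#' @param dt_s frame-interval override; required when no sidecar manifest is
#'   present.
#' @export
read_stack_tiff <- function(path, pixel_size_nm = NULL, dt_s = NULL) {
  r <- .read_tiff_frames(path)
  px <- if (!is.null(pixel_size_nm)) pixel_size_nm else r$meta$pixel_size_nm
  dt <- if (!is.null(dt_s)) dt_s else r$meta$dt_s
  if (is.null(px) || is.null(dt))
    stop("read_stack_tiff: calibration not given and no sidecar manifest found")
  H <- nrow(r$frames[[1]]); W <- ncol(r$frames[[1]])
  arr <- array(unlist(r$frames), dim = c(H, W, length(r$frames)))
  ch <- if (!is.null(r$meta$channel)) r$meta$channel else "unknown"
  image_stack(arr, px, dt, ch)
}
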