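#' Estimate the diffuse background intensity of an image
#'
#' The default estimator is the modal intensity: the center of the tallest
#' bin of a 256-bin histogram over the intensity range. The mode is robust
#' to sparse bright structure (cores occupy a small fraction of the field).
#' A median estimator is available as an alternative.
#'
#' @param img an \code{\link{image2d}}.
#' @param method \code{"mode"} (default) or \code{"median"}.
#' @param n_bins number of histogram bins for the modal estimator.
#' @return background intensity (scalar, >= 0).
#' @export
estimate_background <- function(img, method = c("mode", "median"), n_bins = 256) {
  stopifnot(inherits(img, "image2d"))
  method <- match.arg(method)
  v <- as.vector(img$pixels)
  if (method == "median") return(stats::median(v))
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])          # constant image
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' A set of detected (or ground-truth) actin cores
#'
#' A data.frame with columns \code{id}, \code{x_nm}, \code{y_nm} (weighted
#' centroids, nm), \code{peak_intensity}, and optionally \code{radius_nm}
#' plus per-direction radii \code{r_dir_0 .. r_dir_7} and \code{n_dir_used}.
#'
#' @param df data.frame with at least id, x_nm, y_nm.
#' @export
core_set <- function(df) {
  stopifnot(all(c("id", "x_nm", "y_nm") %in% names(df)))
  if (anyDuplicated(df$id)) stop("core_set: ids must be unique")
  if ("radius_nm" %in% names(df)) {
    r <- df$radius_nm[!is.na(df$radius_nm)]
    if (length(r) && any(r <= 0 | r > 1000))
      stop("core_set: radius_nm must be in (0, 1000]")
  }
  class(df) <- c("core_set", "data.frame")
  df
}

#' Detect actin cores as prominent local maxima
#'
#' Local maxima (8-connected neighborhood) of the (optionally pre-smoothed)
#' image whose height above the modal background exceeds the threshold are
#' taken as candidate cores; the default threshold is half the background
#' intensity. Maxima closer than one weight radius are merged, keeping the
#' brighter one. Each surviving maximum is refined to the intensity-weighted
#' centroid of all pixels within \code{weight_radius_nm}, iterated three
#' times with the disc re-centered on the current estimate; by default the
#' background is subtracted (and negatives clamped) before weighting so the
#' uniform background does not pull centroids toward the pixel grid.
#'
#' @param img an \code{\link{image2d}}.
#' @param prominence_threshold required height above the modal background;
#'   default \code{estimate_background(img) / 2}. Must be >= 0.
#' @param weight_radius_nm radius of the centroid-weighting disc (nm).
#' @param smooth_sigma_px Gaussian pre-smoothing (pixels) applied before
#'   maxima detection only; 0 disables.
#' @param subtract_background subtract the modal background before centroid
#'   weighting.
#' @return a \code{\link{core_set}} in nm coordinates (possibly empty).
#' @export
detect_cores <- function(img, prominence_threshold = NULL, weight_radius_nm = 200,
                         smooth_sigma_px = 1, subtract_background = TRUE) {
  stopifnot(inherits(img, "image2d"))
  bg <- estimate_background(img)
  if (is.null(prominence_threshold)) prominence_threshold <- bg / 2
  if (prominence_threshold < 0) stop("detect_cores: threshold must be >= 0")
  px <- img$pixel_size_nm
  sm <- if (smooth_sigma_px > 0) gaussian_blur_mat(img$pixels, smooth_sigma_px)
        else img$pixels
  mx <- .local_maxima_8(sm)
  keep <- which(mx & (sm - bg) >= prominence_threshold, arr.ind = TRUE)
  empty <- core_set(data.frame(id = integer(0), x_nm = numeric(0), y_nm = numeric(0),
                               peak_intensity = numeric(0)))
  if (nrow(keep) == 0) return(empty)
  vals <- sm[keep]
  ord <- order(vals, decreasing = TRUE)
  keep <- keep[ord, , drop = FALSE]; vals <- vals[ord]
  # merge maxima closer than one weight radius (keep brighter = earlier)
  merge_px <- weight_radius_nm / px
  sel <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    if (i == 1) { sel[1] <- TRUE; next }
    prev <- keep[sel, , drop = FALSE]
    d2 <- (prev[, 1] - keep[i, 1])^2 + (prev[, 2] - keep[i, 2])^2
    if (min(d2) >= merge_px^2) sel[i] <- TRUE
  }
  keep <- keep[sel, , drop = FALSE]; vals <- vals[sel]
  wmat <- if (subtract_background) pmax(img$pixels - bg, 0) else img$pixels
  H <- nrow(wmat); W <- ncol(wmat)
  r_px <- weight_radius_nm / px
  cx <- cy <- numeric(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    c0 <- keep[i, 2]; r0 <- keep[i, 1]
    for (iter in 1:3) {
      cols <- max(1, floor(c0 - r_px)):min(W, ceiling(c0 + r_px))
      rows <- max(1, floor(r0 - r_px)):min(H, ceiling(r0 + r_px))
      d2 <- outer((rows - r0)^2, (cols - c0)^2, "+")
      w <- wmat[rows, cols] * (d2 <= r_px^2)
      sw <- sum(w)
      if (sw <= 0) break
      c0 <- sum(w * rep(cols, each = length(rows))) / sw
      r0 <- sum(w * rep(rows, times = length(cols))) / sw
    }
    cx[i] <- c0; cy[i] <- r0
  }
  core_set(data.frame(id = seq_along(cx),
                      x_nm = px_to_nm(cx, px), y_nm = px_to_nm(cy, px),
                      peak_intensity = vals))
}

# strict-ish 8-neighborhood local maxima: >= all 8 neighbors and > at least one
.local_maxima_8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) return(matrix(FALSE, H, W))
  ge <- matrix(TRUE, H, W); gt <- matrix(FALSE, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- matrix(-Inf, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr); rd <- rs - dr
    cs <- max(1, 1 + dc):min(W, W + dc); cd <- cs - dc
    nb[rd, cd] <- m[rs, cs]
    ge <- ge & (m >= nb)
    gt <- gt | (m > nb)
  }
  res <- ge & gt
  res[c(1, H), ] <- FALSE; res[, c(1, W)] <- FALSE
  res
}

#' Gradient-magnitude (edge) transform of an image
#'
#' The spatial-derivative image: the 3x3 Sobel kernel pair is applied and
#' the gradient magnitude \code{sqrt(Gx^2 + Gy^2)} returned, with border
#' pixels computed under edge replication. An isotropic Gaussian spot maps
#' to an annulus whose maximum sits on the spot's inflection ring (radius =
#' sigma).
#'
#' @param img an \code{\link{image2d}} with at least 3 x 3 pixels.
#' @return an \code{\link{image2d}} with the same calibration.
#' @export
edge_transform <- function(img) {
  stopifnot(inherits(img, "image2d"))
  m <- img$pixels
  if (nrow(m) < 3 || ncol(m) < 3) stop("edge_transform: image must be at least 3 x 3")
  H <- nrow(m); W <- ncol(m)
  p <- m[c(1, seq_len(H), H), c(1, seq_len(W), W)]   # replicate pad by 1
  sh <- function(dr, dc) p[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  image2d(sqrt(gx^2 + gy^2), img$pixel_size_nm, paste0(img$channel, "_edge"))
}

#' Radial intensity profiles around a point
#'
#' Traces \code{n_directions} rays at evenly spaced angles from the center.
#' Along each ray, intensity is sampled at one-pixel steps and averaged
#' across the profile width (samples at pixel-spaced perpendicular offsets,
#' bilinear interpolation). Directions whose footprint leaves the image are
#' flagged as clipped (out-of-bounds samples are dropped from the width
#' average; fully out-of-bounds steps are NA).
#'
#' @param img an \code{\link{image2d}}.
#' @param center_nm numeric length-2 (x, y) in nm; must be inside the image.
#' @param n_directions number of rays (default 8, i.e. every 45 degrees).
#' @param length_nm ray length (default 1000 nm).
#' @param width_nm profile width (default 100 nm).
#' @return a \code{profile_set}: list with \code{distance_nm} (steps),
#'   \code{intensity} (steps x directions matrix), \code{angle_deg},
#'   \code{clipped} (per direction), \code{pixel_size_nm}.
#' @export
radial_profiles <- function(img, center_nm, n_directions = 8,
                            length_nm = 1000, width_nm = 100) {
  stopifnot(inherits(img, "image2d"), length(center_nm) == 2)
  px <- img$pixel_size_nm
  c_col <- nm_to_px(center_nm[1], px); c_row <- nm_to_px(center_nm[2], px)
  if (c_col < 1 || c_col > ncol(img$pixels) || c_row < 1 || c_row > nrow(img$pixels))
    stop("radial_profiles: center outside image")
  steps <- 0:floor(length_nm / px)
  dist_nm <- steps * px
  n_off <- 2 * floor(width_nm / (2 * px)) + 1
  offs <- if (n_off > 1) seq(-width_nm / 2, width_nm / 2, length.out = n_off) / px else 0
  angles <- (seq_len(n_directions) - 1) * 360 / n_directions
  prof <- matrix(NA_real_, length(steps), n_directions)
  clipped <- logical(n_directions)
  for (k in seq_len(n_directions)) {
    a <- angles[k] * pi / 180
    dx <- cos(a); dy <- sin(a)
    # perpendicular unit vector for width averaging
    pxv <- -dy; pyv <- dx
    cols <- outer(steps * dx, offs * pxv, "+") + c_col
    rows <- outer(steps * dy, offs * pyv, "+") + c_row
    v <- matrix(sample_bilinear(img$pixels, as.vector(cols), as.vector(rows)),
                nrow = length(steps))
    if (anyNA(v)) clipped[k] <- TRUE
    prof[, k] <- rowMeans(v, na.rm = TRUE)
  }
  prof[is.nan(prof)] <- NA
  structure(list(distance_nm = dist_nm, intensity = prof, angle_deg = angles,
                 clipped = clipped, pixel_size_nm = px),
            class = "profile_set")
}

# first local maximum of a profile, sub-step refined by 3-point parabola;
# returns distance in nm or NA when no interior local maximum exists
.first_profile_max <- function(dist_nm, p) {
  if (anyNA(p)) {
    # restrict to the leading contiguous valid run
    ok <- which(!is.na(p))
    if (length(ok) < 3 || ok[1] != 1) return(NA_real_)
    g <- which(diff(ok) > 1)
    if (length(g)) ok <- ok[seq_len(g[1])]
    p <- p[ok]; dist_nm <- dist_nm[ok]
  }
  n <- length(p)
  if (n < 3) return(NA_real_)
  for (i in 2:(n - 1)) {
    if (p[i] > p[i - 1] && p[i] >= p[i + 1]) {
      denom <- p[i - 1] - 2 * p[i] + p[i + 1]
      delta <- if (denom < 0) 0.5 * (p[i - 1] - p[i + 1]) / denom else 0
      delta <- max(-0.5, min(0.5, delta))
      step <- dist_nm[2] - dist_nm[1]
      return(dist_nm[i] + delta * step)
    }
  }
  NA_real_
}

#' Estimate a core radius from derivative-profile first maxima
#'
#' For each of the radial directions, the radius is the distance from the
#' center to the first local maximum of the gradient-magnitude (edge)
#' profile, refined to sub-step precision by a 3-point parabolic fit. The
#' core radius is the mean over directions; clipped directions and
#' directions without a maximum within the profile length are excluded and
#' flagged.
#'
#' @param edge_img the \code{\link{edge_transform}} of the frame.
#' @param center_nm core center (x, y) in nm.
#' @param n_directions,length_nm,width_nm as in \code{\link{radial_profiles}}.
#' @return list with \code{radius_nm} (mean, or NA when all directions are
#'   excluded), \code{per_direction_nm} (length \code{n_directions}, NA where
#'   excluded) and \code{n_used}.
#' @export
estimate_core_radius <- function(edge_img, center_nm, n_directions = 8,
                                 length_nm = 1000, width_nm = 100) {
  ps <- radial_profiles(edge_img, center_nm, n_directions, length_nm, width_nm)
  r <- vapply(seq_len(n_directions), function(k) {
    if (ps$clipped[k]) return(NA_real_)
    .first_profile_max(ps$distance_nm, ps$intensity[, k])
  }, 0)
  n_used <- sum(!is.na(r))
  list(radius_nm = if (n_used > 0) mean(r, na.rm = TRUE) else NA_real_,
       per_direction_nm = r, n_used = n_used)
}

#' Detect cores and estimate all radii on one frame
#'
#' Convenience wrapper: background/threshold, maxima detection, centroid
#' weighting, edge transform and per-core radius estimation.
#'
#' @inheritParams detect_cores
#' @param length_nm,width_nm radial-profile geometry.
#' @return a \code{\link{core_set}} with radius columns filled in.
#' @export
analyze_frame <- function(img, prominence_threshold = NULL, weight_radius_nm = 200,
                          length_nm = 1000, width_nm = 100) {
  cs <- detect_cores(img, prominence_threshold, weight_radius_nm)
  edge <- edge_transform(img)
  nd <- 8
  rad <- matrix(NA_real_, nrow(cs), nd)
  rmean <- rep(NA_real_, nrow(cs)); nuse <- integer(nrow(cs))
  for (i in seq_len(nrow(cs))) {
    est <- estimate_core_radius(edge, c(cs$x_nm[i], cs$y_nm[i]), nd, length_nm, width_nm)
    rad[i, ] <- est$per_direction_nm
    rmean[i] <- est$radius_nm; nuse[i] <- est$n_used
  }
  cs$radius_nm <- ifelse(!is.na(rmean) & (rmean <= 0 | rmean > 1000), NA, rmean)
  cs$n_dir_used <- nuse
  colnames(rad) <- paste0("r_dir_", 0:(nd - 1))
  core_set(cbind(as.data.frame(cs), as.data.frame(rad)))
}

#' Write / read a core table as CSV
#' @param cores a \code{\link{core_set}}.
#' @param path CSV path.
#' @export
write_cores <- function(cores, path) {
  utils::write.csv(as.data.frame(cores), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cores
#' @export
read_cores <- function(path) core_set(utils::read.csv(path))
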