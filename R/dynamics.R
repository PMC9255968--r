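#' Bleach correction by histogram matching
#'
#' Each frame's intensity histogram is monotonically remapped to match the
#' first frame's histogram (rank-based exact histogram specification: equal
#' input values map to equal outputs). Frame 1 is returned unchanged, as is
#' any constant frame.
#'
#' @param stack an \code{\link{image_stack}}.
#' @return a corrected \code{\link{image_stack}}.
#' @export
bleach_correct <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  ref <- sort(as.vector(stack$frames[, , 1]))
  n <- length(ref)
  out <- stack$frames
  for (t in 2:d[3]) {
    f <- as.vector(stack$frames[, , t])
    if (diff(range(f)) == 0) next                  # constant frame: identity
    r <- rank(f, ties.method = "average")
    out[, , t] <- matrix(ref[pmin.int(n, pmax.int(1L, round(r)))], d[1], d[2])
  }
  image_stack(out, stack$pixel_size_nm, stack$dt_s, stack$channel)
}

#' Extract per-core intensity signals from a stack
#'
#' For each core, the mean intensity over all pixels whose centers fall
#' within \code{radius_nm} of the core centroid, per frame. Disc membership
#' is computed once and reused across frames.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param cores a \code{\link{core_set}} (centroids inside the frame).
#' @param radius_nm selection radius, default 100 nm.
#' @return a \code{signal_matrix}: list with \code{ids}, \code{x_nm},
#'   \code{y_nm}, \code{signals} (cores x T matrix), \code{dt_s}.
#' @export
extract_signals <- function(stack, cores, radius_nm = 100) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  px <- stack$pixel_size_nm
  flat <- matrix(stack$frames, d[1] * d[2], d[3])
  n <- nrow(cores)
  sig <- matrix(0, n, d[3])
  for (i in seq_len(n)) {
    c0 <- nm_to_px(cores$x_nm[i], px); r0 <- nm_to_px(cores$y_nm[i], px)
    r_px <- radius_nm / px
    cols <- max(1, floor(c0 - r_px)):min(d[2], ceiling(c0 + r_px))
    rows <- max(1, floor(r0 - r_px)):min(d[1], ceiling(r0 + r_px))
    inside <- outer((rows - r0)^2, (cols - c0)^2, "+") <= r_px^2
    idx <- as.vector(outer(rows, (cols - 1) * d[1], "+"))[as.vector(inside)]
    if (!length(idx))
      stop("extract_signals: selection disc of core ", cores$id[i],
           " contains no pixel centers; increase radius_nm")
    sig[i, ] <- colMeans(flat[idx, , drop = FALSE])
  }
  structure(list(ids = cores$id, x_nm = cores$x_nm, y_nm = cores$y_nm,
                 signals = sig, dt_s = stack$dt_s),
            class = "signal_matrix")
}

.detrend <- function(x) {
  t <- seq_along(x)
  stats::lm.fit(cbind(1, t), x)$residuals
}

#' Pairwise distance-annotated synchrony table
#'
#' For every unordered core pair, the Euclidean centroid distance and the
#' zero-lag Pearson correlation of the two signals (linearly detrended by
#' default to remove residual bleaching). Pairs involving a zero-variance
#' signal get \code{NA} correlation and are dropped, with the count
#' recorded in attribute \code{n_excluded}.
#'
#' @param signals a \code{signal_matrix} with >= 2 cores and >= 3 frames.
#' @param detrend linearly detrend each signal first (default TRUE).
#' @return a \code{synchrony_table} data.frame: \code{core_i, core_j,
#'   distance_nm, pearson_r}.
#' @export
pairwise_synchrony <- function(signals, detrend = TRUE) {
  stopifnot(inherits(signals, "signal_matrix"))
  m <- signals$signals
  if (nrow(m) < 2) stop("pairwise_synchrony: need at least 2 cores")
  if (ncol(m) < 3) stop("pairwise_synchrony: need at least 3 frames")
  if (detrend) m <- t(apply(m, 1, .detrend))
  sds <- apply(m, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(m)))
  pr <- which(upper.tri(cc), arr.ind = TRUE)
  out <- data.frame(
    core_i = signals$ids[pr[, 1]], core_j = signals$ids[pr[, 2]],
    distance_nm = sqrt((signals$x_nm[pr[, 1]] - signals$x_nm[pr[, 2]])^2 +
                       (signals$y_nm[pr[, 1]] - signals$y_nm[pr[, 2]])^2),
    pearson_r = cc[pr])
  bad <- sds[pr[, 1]] == 0 | sds[pr[, 2]] == 0
  out$pearson_r[bad] <- NA
  n_excl <- sum(is.na(out$pearson_r))
  out <- out[!is.na(out$pearson_r), , drop = FALSE]
  attr(out, "n_excluded") <- n_excl
  class(out) <- c("synchrony_table", "data.frame")
  out
}

#' Distance-binned synchrony curve and half-decay distance
#'
#' Mean Pearson correlation per distance bin, and the half-decay distance:
#' the distance at which the binned mean first drops to half of its maximum,
#' linearly interpolated between bin centers (\code{NA} when the curve never
#' reaches half-maximum).
#'
#' @param table a \code{synchrony_table}.
#' @param bin_width_nm distance bin width (default 200 nm).
#' @return list with \code{curve} (data.frame \code{bin_center_nm, mean_r,
#'   n_pairs}) and \code{half_decay_nm}.
#' @export
synchrony_curve <- function(table, bin_width_nm = 200) {
  stopifnot(nrow(table) > 0)
  if (all(is.na(table$pearson_r))) stop("synchrony_curve: all correlations undefined")
  idx <- findInterval(table$distance_nm, seq(0, max(table$distance_nm) + bin_width_nm,
                                             by = bin_width_nm))
  agg <- tapply(table$pearson_r, idx, mean)
  cnt <- tapply(table$pearson_r, idx, length)
  centers <- (as.numeric(names(agg)) - 0.5) * bin_width_nm
  curve <- data.frame(bin_center_nm = centers, mean_r = as.numeric(agg),
                      n_pairs = as.integer(cnt))
  curve <- curve[order(curve$bin_center_nm), ]
  half <- max(curve$mean_r) / 2
  hd <- NA_real_
  mr <- curve$mean_r; bc <- curve$bin_center_nm
  for (i in seq_along(mr)) {
    if (mr[i] <= half) {
      if (i == 1) { hd <- bc[1] } else {
        frac <- (mr[i - 1] - half) / (mr[i - 1] - mr[i])
        hd <- bc[i - 1] + frac * (bc[i] - bc[i - 1])
      }
      break
    }
  }
  list(curve = curve, half_decay_nm = hd)
}

#' Magnitude spectrum of a core intensity signal
#'
#' Magnitude of the real-input discrete Fourier transform of the
#' mean-subtracted, linearly detrended signal; frequencies run from 0 to
#' the Nyquist frequency with spacing \code{1 / (T dt)}.
#'
#' @param x numeric signal of length >= 8.
#' @param dt_s sampling interval (s).
#' @param detrend linearly detrend first (default TRUE); the mean is always
#'   removed.
#' @return a \code{power_spectrum}: list with \code{frequency_hz},
#'   \code{magnitude}, \code{detrend}, \code{dt_s}.
#' @export
signal_spectrum <- function(x, dt_s, detrend = TRUE) {
  if (length(x) < 8) stop("signal_spectrum: need at least 8 samples")
  if (!all(is.finite(x))) stop("signal_spectrum: non-finite samples")
  y <- if (detrend) .detrend(x) else x - mean(x)
  Tn <- length(y)
  mag <- Mod(stats::fft(y))[seq_len(Tn %/% 2 + 1)]
  structure(list(frequency_hz = (seq_len(Tn %/% 2 + 1) - 1) / (Tn * dt_s),
                 magnitude = mag, detrend = detrend, dt_s = dt_s),
            class = "power_spectrum")
}

#' Natural frequencies of a spectrum
#'
#' Local maxima of the magnitude spectrum (DC excluded) exceeding
#' \code{k_median} times the median magnitude over the spectrum, returned in
#' ascending order. The threshold is relative, so detections are invariant
#' to intensity scaling.
#'
#' @param spec a \code{power_spectrum}.
#' @param k_median threshold multiplier (> 0); default 5.
#' @return numeric vector of frequencies (Hz); possibly empty.
#' @export
natural_frequencies <- function(spec, k_median = 5) {
  stopifnot(inherits(spec, "power_spectrum"), k_median > 0)
  m <- spec$magnitude[-1]; f <- spec$frequency_hz[-1]
  thr <- k_median * stats::median(m)
  n <- length(m)
  if (n < 3) return(numeric(0))
  is_peak <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n], FALSE)
  is_peak[n] <- m[n] > m[n - 1]          # Nyquist bin may be a peak
  sort(f[is_peak & m > thr])
}

#' Rate-of-change movie
#'
#' Subtracts sequential frames (\code{D_t = I_{t+1} - I_t}; positive = net
#' polymerization), then optionally applies a spatial Gaussian filter of the
#' given radius (sigma = radius / 2, the ImageJ radius convention) and a
#' centered moving temporal mean over \code{temporal_window} difference
#' frames (shorter windows at the ends).
#'
#' @param stack an \code{\link{image_stack}} with >= 2 frames.
#' @param gaussian_radius_nm smoothing radius in nm (default 64.5, i.e. 2 px
#'   at 32.25 nm/px); 0 disables.
#' @param temporal_window temporal averaging window (odd; 1 disables).
#' @return a \code{rate_map}: list with \code{rates} (H x W x (T-1) array),
#'   \code{pixel_size_nm}, \code{dt_s}, smoothing parameters.
#' @export
rate_movie <- function(stack, gaussian_radius_nm = 64.5, temporal_window = 3) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  D <- stack$frames[, , -1, drop = FALSE] - stack$frames[, , -d[3], drop = FALSE]
  nt <- d[3] - 1
  if (gaussian_radius_nm > 0) {
    sigma_px <- (gaussian_radius_nm / stack$pixel_size_nm) / 2
    for (t in seq_len(nt)) D[, , t] <- gaussian_blur_mat(D[, , t], sigma_px)
  }
  if (temporal_window > 1 && nt >= 2) {
    hw <- floor(temporal_window / 2)
    out <- D
    for (t in seq_len(nt)) {
      win <- max(1, t - hw):min(nt, t + hw)
      out[, , t] <- apply(D[, , win, drop = FALSE], c(1, 2), mean)
    }
    D <- out
  }
  structure(list(rates = D, pixel_size_nm = stack$pixel_size_nm, dt_s = stack$dt_s,
                 gaussian_radius_nm = gaussian_radius_nm,
                 temporal_window = temporal_window),
            class = "rate_map")
}

# 8-connected labeling: 4-connected pass (EBImage) + union of diagonal touches
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl <= 1) return(lab)
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  H <- nrow(lab); W <- ncol(lab)
  a <- lab[-H, -W]; b <- lab[-1, -1]        # NW-SE diagonal pairs
  c_ <- lab[-1, -W]; d_ <- lab[-H, -1]      # SW-NE diagonal pairs
  prs <- rbind(cbind(a[a > 0 & b > 0], b[a > 0 & b > 0]),
               cbind(c_[c_ > 0 & d_ > 0], d_[c_ > 0 & d_ > 0]))
  if (nrow(prs)) {
    prs <- unique(prs[prs[, 1] != prs[, 2], , drop = FALSE])
    for (k in seq_len(nrow(prs))) {
      ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nl), find, 0L)
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Segment coordinated growing / decreasing clusters
#'
#' Per difference frame, pixels above \code{+z_thresh} robust standard
#' deviations (1.4826 MAD of that frame) are labeled "growing" and below
#' \code{-z_thresh} "decreasing"; 8-connected components smaller than
#' \code{min_area_um2} are discarded.
#'
#' @param rate a \code{rate_map}.
#' @param z_thresh threshold in robust SD units (default 2).
#' @param min_area_um2 minimum component area (default 0.05).
#' @param cores optional \code{\link{core_set}}; member cores per region are
#'   reported when given.
#' @return list with \code{labels} (H x W x (T-1) array: positive integers =
#'   growing regions, negative = decreasing) and \code{regions} (data.frame
#'   \code{frame, label, class, area_um2, centroid_x_nm, centroid_y_nm,
#'   core_ids}).
#' @export
segment_rate_clusters <- function(rate, z_thresh = 2, min_area_um2 = 0.05,
                                  cores = NULL) {
  stopifnot(inherits(rate, "rate_map"))
  d <- dim(rate$rates)
  px <- rate$pixel_size_nm
  px_area_um2 <- (px / 1000)^2
  min_px <- ceiling(min_area_um2 / px_area_um2)
  labels <- array(0L, d)
  regions <- list()
  for (t in seq_len(d[3])) {
    fr <- rate$rates[, , t]
    s <- stats::mad(fr)                       # 1.4826 * MAD
    if (s == 0) next
    for (cls in c("growing", "decreasing")) {
      mask <- if (cls == "growing") fr > z_thresh * s else fr < -z_thresh * s
      if (!any(mask)) next
      lab <- .label8(mask)
      sizes <- tabulate(lab[lab > 0])
      keep <- which(sizes >= min_px)
      for (k in keep) {
        idx <- which(lab == k, arr.ind = TRUE)
        cx <- px_to_nm(mean(idx[, 2]), px); cy <- px_to_nm(mean(idx[, 1]), px)
        sgn <- if (cls == "growing") 1L else -1L
        lbl <- sgn * (length(regions) + 1L)
        labels[, , t][lab == k] <- lbl
        core_ids <- ""
        if (!is.null(cores) && nrow(cores) > 0) {
          cc <- round(nm_to_px(cores$x_nm, px)); rr <- round(nm_to_px(cores$y_nm, px))
          inb <- cc >= 1 & cc <= d[2] & rr >= 1 & rr <= d[1]
          inside <- inb & (lab[cbind(pmax(1, pmin(d[1], rr)),
                                     pmax(1, pmin(d[2], cc)))] == k)
          core_ids <- paste(cores$id[inside], collapse = ";")
        }
        regions[[length(regions) + 1L]] <- data.frame(
          frame = t, label = lbl, class = cls,
          area_um2 = sizes[k] * px_area_um2,
          centroid_x_nm = cx, centroid_y_nm = cy, core_ids = core_ids)
      }
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(frame = integer(0), label = integer(0), class = character(0),
               area_um2 = numeric(0), centroid_x_nm = numeric(0),
               centroid_y_nm = numeric(0), core_ids = character(0))
  list(labels = labels, regions = regions)
}

#' Kymograph along a polyline
#'
#' Intensity sampled at one-pixel arc-length steps along the polyline and
#' averaged across the profile width (perpendicular to the local segment
#' direction), for every frame. Rows are positions, columns time.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param polyline_nm matrix with columns x, y (nm), >= 2 vertices.
#' @param width_nm averaging width (nm).
#' @return an \code{\link{image2d}} of size (arc steps) x T; the pixel size
#'   field holds the spatial step (nm).
#' @export
kymograph <- function(stack, polyline_nm, width_nm = 100) {
  stopifnot(inherits(stack, "image_stack"))
  pl <- as.matrix(polyline_nm)
  if (nrow(pl) < 2) stop("kymograph: polyline needs at least 2 vertices")
  seg <- diff(pl)
  seg_len <- sqrt(rowSums(seg^2))
  if (sum(seg_len) == 0) stop("kymograph: degenerate (zero-length) polyline")
  px <- stack$pixel_size_nm
  total <- sum(seg_len)
  s <- seq(0, total, by = px)
  cum <- c(0, cumsum(seg_len))
  si <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(seg))
  frac <- (s - cum[si]) / seg_len[si]
  pts <- pl[si, , drop = FALSE] + seg[si, , drop = FALSE] * frac
  dirs <- seg[si, , drop = FALSE] / seg_len[si]
  n_off <- 2 * floor(width_nm / (2 * px)) + 1
  offs <- if (n_off > 1) seq(-width_nm / 2, width_nm / 2, length.out = n_off) else 0
  d <- dim(stack$frames)
  ky <- matrix(NA_real_, length(s), d[3])
  cols <- nm_to_px(outer(pts[, 1], rep(1, n_off)) + outer(-dirs[, 2], offs), px)
  rows <- nm_to_px(outer(pts[, 2], rep(1, n_off)) + outer(dirs[, 1], offs), px)
  if (any(cols < 1 | cols > d[2] | rows < 1 | rows > d[1]))
    stop("kymograph: polyline footprint leaves the frame")
  for (t in seq_len(d[3])) {
    v <- matrix(sample_bilinear(stack$frames[, , t], as.vector(cols), as.vector(rows)),
                nrow = length(s))
    ky[, t] <- rowMeans(v)
  }
  image2d(ky, px, paste0(stack$channel, "_kymograph"))
}
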