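#' Local belt orientation around a core
#'
#' The angle of the first principal axis of the neighboring core
#' coordinates (PCA), reported in degrees in (-90, 90]. Neighborhoods whose
#' principal-axis ratio (sqrt of the eigenvalue ratio) is below 1.2 are
#' nearly isotropic and flagged low-confidence.
#'
#' @param cores a \code{\link{core_set}}.
#' @param neighborhood_radius_nm neighborhood radius (nm).
#' @param ids cores to evaluate (default all).
#' @return data.frame \code{id, angle_deg, axis_ratio, n_neighbors,
#'   low_confidence}.
#' @export
local_belt_angle <- function(cores, neighborhood_radius_nm = 1500, ids = NULL) {
  df <- as.data.frame(cores)
  if (is.null(ids)) ids <- df$id
  out <- lapply(ids, function(id) {
    i <- which(df$id == id)
    d2 <- (df$x_nm - df$x_nm[i])^2 + (df$y_nm - df$y_nm[i])^2
    nb <- which(d2 <= neighborhood_radius_nm^2)
    if (length(nb) < 3)
      return(data.frame(id = id, angle_deg = NA_real_, axis_ratio = NA_real_,
                        n_neighbors = length(nb), low_confidence = TRUE))
    xy <- cbind(df$x_nm[nb], df$y_nm[nb])
    ev <- eigen(stats::cov(xy), symmetric = TRUE)
    ang <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
    ang <- ((ang + 90) %% 180) - 90
    if (ang == -90) ang <- 90
    ratio <- sqrt(max(ev$values[1], 0) / max(ev$values[2], .Machine$double.eps))
    data.frame(id = id, angle_deg = ang, axis_ratio = ratio,
               n_neighbors = length(nb), low_confidence = ratio < 1.2)
  })
  do.call(rbind, out)
}

# width-averaged line sample centered at (cx, cy) nm along angle_deg
.line_sample <- function(img, cx, cy, angle_deg, length_nm, width_nm) {
  px <- img$pixel_size_nm
  a <- angle_deg * pi / 180
  half <- floor((length_nm / 2) / px)
  steps <- (-half):half
  n_off <- 2 * floor(width_nm / (2 * px)) + 1
  offs <- if (n_off > 1) seq(-width_nm / 2, width_nm / 2, length.out = n_off) / px else 0
  cols <- nm_to_px(cx, px) + outer(steps * cos(a), offs * (-sin(a)), "+")
  rows <- nm_to_px(cy, px) + outer(steps * sin(a), offs * cos(a), "+")
  v <- matrix(sample_bilinear(img$pixels, as.vector(cols), as.vector(rows)),
              nrow = length(steps))
  list(position_nm = steps * px, intensity = rowMeans(v), clipped = anyNA(v))
}

#' Extract oriented line profiles around each core
#'
#' For each core, intensity profiles of the actin, actin-edge and marker
#' channels along two 1.5 um long, 100 nm wide lines centered on the core:
#' one longitudinal (along the local belt orientation) and one transverse.
#' Cores whose profile footprint is clipped by the image border are excluded
#' and counted in attribute \code{n_clipped}.
#'
#' @param actin,edge,marker co-registered \code{\link{image2d}} objects with
#'   equal calibration.
#' @param cores a \code{\link{core_set}}.
#' @param angles_deg per-core longitudinal angle: either a numeric vector
#'   aligned with \code{cores}, or \code{NULL} to estimate it with
#'   \code{\link{local_belt_angle}}.
#' @param length_nm,width_nm line geometry (defaults 1500 and 100 nm).
#' @return a long-format data.frame of class \code{line_profiles}:
#'   \code{core_id, orientation, channel, position_nm, intensity}.
#' @export
extract_line_profiles <- function(actin, edge, marker, cores, angles_deg = NULL,
                                  length_nm = 1500, width_nm = 100) {
  stopifnot(inherits(actin, "image2d"), inherits(edge, "image2d"),
            inherits(marker, "image2d"))
  if (actin$pixel_size_nm != edge$pixel_size_nm ||
      actin$pixel_size_nm != marker$pixel_size_nm)
    stop("extract_line_profiles: images must share calibration")
  if (is.null(angles_deg)) {
    ba <- local_belt_angle(cores)
    angles_deg <- ifelse(is.na(ba$angle_deg), 0, ba$angle_deg)
  }
  stopifnot(length(angles_deg) == nrow(cores))
  chans <- list(actin = actin, edge = edge, marker = marker)
  rows <- list(); n_clipped <- 0L
  for (i in seq_len(nrow(cores))) {
    pro <- list()
    clipped <- FALSE
    for (orient in c("longitudinal", "transverse")) {
      ang <- if (orient == "longitudinal") angles_deg[i] else angles_deg[i] + 90
      for (ch in names(chans)) {
        s <- .line_sample(chans[[ch]], cores$x_nm[i], cores$y_nm[i], ang,
                          length_nm, width_nm)
        clipped <- clipped || s$clipped
        pro[[paste(orient, ch)]] <- data.frame(
          core_id = cores$id[i], orientation = orient, channel = ch,
          position_nm = s$position_nm, intensity = s$intensity)
      }
    }
    if (clipped) { n_clipped <- n_clipped + 1L; next }
    rows[[length(rows) + 1L]] <- do.call(rbind, pro)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(core_id = integer(0), orientation = character(0),
               channel = character(0), position_nm = numeric(0),
               intensity = numeric(0))
  rownames(out) <- NULL
  attr(out, "n_clipped") <- n_clipped
  class(out) <- c("line_profiles", "data.frame")
  out
}

# median core radius over all cores/orientations from first edge-profile
# maxima on both half-profiles
.median_edge_radius <- function(profiles) {
  ep <- profiles[profiles$channel == "edge", ]
  radii <- c()
  for (key in unique(paste(ep$core_id, ep$orientation))) {
    sub <- ep[paste(ep$core_id, ep$orientation) == key, ]
    sub <- sub[order(sub$position_nm), ]
    pos <- sub$position_nm; val <- sub$intensity
    right <- pos >= 0; left <- pos <= 0
    r1 <- .first_profile_max(pos[right], val[right])
    r2 <- .first_profile_max(-rev(pos[left]), rev(val[left]))
    radii <- c(radii, r1, r2)
  }
  radii <- radii[!is.na(radii) & radii > 0]
  if (!length(radii)) stop("normalize_and_pool: no edge-profile maxima found")
  stats::median(radii)
}

#' Normalize profile lengths by the median core radius and pool
#'
#' Computes the median core radius over all cores from the first maxima of
#' the edge-channel profiles, rescales every profile's position axis so that
#' one unit equals that median radius, linearly interpolates onto a common
#' grid, takes the per-position median across cores, and min-max normalizes
#' each channel's median profile to [0, 1]. This makes profiles comparable
#' across cells with different core sizes.
#'
#' @param profiles a \code{line_profiles} data.frame.
#' @param grid_step grid spacing in normalized-radius units (default 1/8).
#' @param grid_span half-extent of the grid in units (default 6).
#' @param pool_orientations pool longitudinal and transverse profiles
#'   together (default FALSE: kept separate).
#' @return data.frame of class \code{normalized_profile}: \code{channel,
#'   orientation, position_units, intensity}; attributes
#'   \code{median_radius_nm} and \code{n_cores}.
#' @export
normalize_and_pool <- function(profiles, grid_step = 0.125, grid_span = 6,
                               pool_orientations = FALSE) {
  stopifnot(inherits(profiles, "line_profiles") || is.data.frame(profiles))
  if (nrow(profiles) == 0) stop("normalize_and_pool: empty profile set")
  r_med <- .median_edge_radius(profiles)
  grid <- seq(-grid_span, grid_span, by = grid_step)
  orients <- if (pool_orientations) list(all = c("longitudinal", "transverse"))
             else list(longitudinal = "longitudinal", transverse = "transverse")
  out <- list()
  for (ch in unique(profiles$channel)) {
    for (on in names(orients)) {
      sub <- profiles[profiles$channel == ch &
                      profiles$orientation %in% orients[[on]], ]
      if (nrow(sub) == 0) next
      keys <- unique(paste(sub$core_id, sub$orientation))
      mat <- sapply(keys, function(key) {
        s <- sub[paste(sub$core_id, sub$orientation) == key, ]
        s <- s[order(s$position_nm), ]
        stats::approx(s$position_nm / r_med, s$intensity, xout = grid,
                      rule = 1)$y
      })
      med <- apply(as.matrix(mat), 1, stats::median, na.rm = TRUE)
      rng <- range(med, na.rm = TRUE)
      nrm <- if (diff(rng) > 0) (med - rng[1]) / diff(rng) else med * 0
      out[[paste(ch, on)]] <- data.frame(channel = ch, orientation = on,
                                         position_units = grid, intensity = nrm)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "median_radius_nm") <- r_med
  attr(res, "n_cores") <- length(unique(profiles$core_id))
  class(res) <- c("normalized_profile", "data.frame")
  res
}

#' Per-core actin vs marker intensity correlation
#'
#' Mean intensity of each channel within a disc around every core (default
#' radius 1 um), normalized by the per-channel maximum over cores, and the
#' Pearson correlation across cores.
#'
#' @param actin,marker co-registered \code{\link{image2d}} objects.
#' @param cores a \code{\link{core_set}} (>= 3 for a defined correlation).
#' @param radius_nm disc radius (default 1000 nm).
#' @return list with \code{per_core} (data.frame \code{id, actin, marker},
#'   max-normalized) and \code{pearson_r} (NA when undefined).
#' @export
core_marker_correlation <- function(actin, marker, cores, radius_nm = 1000) {
  stopifnot(inherits(actin, "image2d"), inherits(marker, "image2d"))
  disc_mean <- function(img, x, y) {
    px <- img$pixel_size_nm
    c0 <- nm_to_px(x, px); r0 <- nm_to_px(y, px); r_px <- radius_nm / px
    cols <- max(1, floor(c0 - r_px)):min(ncol(img$pixels), ceiling(c0 + r_px))
    rows <- max(1, floor(r0 - r_px)):min(nrow(img$pixels), ceiling(r0 + r_px))
    inside <- outer((rows - r0)^2, (cols - c0)^2, "+") <= r_px^2
    mean(img$pixels[rows, cols][inside])
  }
  ia <- mapply(function(x, y) disc_mean(actin, x, y), cores$x_nm, cores$y_nm)
  im <- mapply(function(x, y) disc_mean(marker, x, y), cores$x_nm, cores$y_nm)
  per <- data.frame(id = cores$id, actin = ia / max(ia), marker = im / max(im))
  r <- if (nrow(per) >= 3 && stats::sd(per$actin) > 0 && stats::sd(per$marker) > 0)
    stats::cor(per$actin, per$marker) else NA_real_
  list(per_core = per, pearson_r = r)
}

#' Segment islets from an adhesion-marker image
#'
#' The adhesion channel is thresholded (Otsu by default) into a border mask;
#' connected components of the complement that do not touch the image border
#' (the unbounded outside region does) are islet candidates. Components
#' below \code{min_area_um2} are dropped. Each islet's area and the number
#' of core centroids inside it are reported.
#'
#' @param adhesion an \code{\link{image2d}} of the adhesion marker.
#' @param cores a \code{\link{core_set}} co-registered with the image.
#' @param min_area_um2 minimum islet area (default 0.2).
#' @param threshold \code{"otsu"} or a numeric intensity cutoff.
#' @return list with \code{islets} (data.frame \code{islet_id, area_um2,
#'   n_cores}), \code{core_islet} (per-core islet id, NA when outside all
#'   islets) and \code{labels} (label matrix).
#' @export
segment_islets <- function(adhesion, cores, min_area_um2 = 0.2, threshold = "otsu") {
  stopifnot(inherits(adhesion, "image2d"))
  m <- adhesion$pixels
  thr <- if (identical(threshold, "otsu")) {
    rng <- range(m)
    if (diff(rng) == 0) rng[2] + 1        # constant image: empty mask
    else EBImage::otsu(EBImage::Image((m - rng[1]) / diff(rng)), range = c(0, 1)) *
      diff(rng) + rng[1]
  } else as.numeric(threshold)
  mask <- m > thr
  px <- adhesion$pixel_size_nm
  empty <- list(islets = data.frame(islet_id = integer(0), area_um2 = numeric(0),
                                    n_cores = integer(0)),
                core_islet = rep(NA_integer_, nrow(cores)),
                labels = matrix(0L, nrow(m), ncol(m)))
  if (!any(mask)) return(empty)
  lab <- .label8(!mask)
  H <- nrow(lab); W <- ncol(lab)
  border_labels <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  sizes <- tabulate(lab[lab > 0])
  px_area_um2 <- (px / 1000)^2
  keep <- setdiff(which(sizes * px_area_um2 >= min_area_um2), border_labels)
  if (!length(keep)) return(empty)
  relab <- rep(0L, max(lab))
  relab[keep] <- seq_along(keep)
  labels <- matrix(0L, H, W)
  labels[lab > 0] <- relab[lab[lab > 0]]
  core_islet <- rep(NA_integer_, nrow(cores))
  if (nrow(cores) > 0) {
    cc <- pmax(1, pmin(W, round(nm_to_px(cores$x_nm, px))))
    rr <- pmax(1, pmin(H, round(nm_to_px(cores$y_nm, px))))
    li <- labels[cbind(rr, cc)]
    core_islet[li > 0] <- li[li > 0]
  }
  islets <- data.frame(islet_id = seq_along(keep),
                       area_um2 = sizes[keep] * px_area_um2,
                       n_cores = vapply(seq_along(keep), function(k)
                         sum(core_islet == k, na.rm = TRUE), 0L))
  list(islets = islets, core_islet = core_islet, labels = labels)
}
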