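# Independent brute-force oracles used to validate the geometric modules.

# All-triples empty-circumcircle Delaunay edges. O(n^4) but vectorized over
# triples; suitable for n <= 50.
bf_delaunay_edges <- function(xy) {
  n <- nrow(xy)
  tr <- t(utils::combn(n, 3))
  a <- xy[tr[, 1], , drop = FALSE]
  b <- xy[tr[, 2], , drop = FALSE]
  cc <- xy[tr[, 3], , drop = FALSE]
  d1x <- 2 * (b[, 1] - a[, 1]); d1y <- 2 * (b[, 2] - a[, 2])
  r1 <- rowSums(b^2) - rowSums(a^2)
  d2x <- 2 * (cc[, 1] - a[, 1]); d2y <- 2 * (cc[, 2] - a[, 2])
  r2 <- rowSums(cc^2) - rowSums(a^2)
  det <- d1x * d2y - d2x * d1y
  px <- (r1 * d2y - r2 * d1y) / det
  py <- (d1x * r2 - d2x * r1) / det
  rad2 <- (px - a[, 1])^2 + (py - a[, 2])^2
  dmin <- rep(Inf, nrow(tr))
  for (k in seq_len(n)) {
    d2k <- (px - xy[k, 1])^2 + (py - xy[k, 2])^2
    d2k[tr[, 1] == k | tr[, 2] == k | tr[, 3] == k] <- Inf
    dmin <- pmin(dmin, d2k)
  }
  scale2 <- max(rowSums(xy^2))
  ok <- is.finite(rad2) & abs(det) > 1e-12 * scale2 &
    dmin >= rad2 - 1e-9 * scale2
  e <- rbind(tr[ok, c(1, 2), drop = FALSE],
             tr[ok, c(1, 3), drop = FALSE],
             tr[ok, c(2, 3), drop = FALSE])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

# Brute-force convex hull membership: i is a hull vertex iff some line
# through i and another point has all remaining points on one side.
bf_hull_flags <- function(xy) {
  n <- nrow(xy)
  on_hull <- logical(n)
  tol <- 1e-9 * max(1, max(abs(xy)))^2
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cr <- (xy[j, 1] - xy[i, 1]) * (xy[, 2] - xy[i, 2]) -
          (xy[j, 2] - xy[i, 2]) * (xy[, 1] - xy[i, 1])
    if (all(cr <= tol) || all(cr >= -tol)) on_hull[c(i, j)] <- TRUE
  }
  on_hull
}

# Brute-force global nearest-neighbor distances.
bf_nn_dist <- function(xy) {
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

# Brute-force oriented-box assignment: rotate each localization into the
# box frame of every core and test axis-aligned bounds.
bf_assign_rz <- function(locs, cores, geom, box_length_nm = 10000, box_width_nm = 200) {
  out <- list()
  for (axis in c("along_belt", "transverse")) {
    theta <- if (axis == "along_belt") atan2(geom$u[2], geom$u[1])
             else atan2(geom$normal[2], geom$normal[1])
    R <- matrix(c(cos(-theta), -sin(-theta), sin(-theta), cos(-theta)), 2, 2,
                byrow = TRUE)
    for (i in seq_len(nrow(cores))) {
      for (k in seq_len(nrow(locs))) {
        v <- R %*% c(locs$x_nm[k] - cores$x_nm[i], locs$y_nm[k] - cores$y_nm[i])
        if (abs(v[1]) <= box_length_nm / 2 && abs(v[2]) <= box_width_nm / 2)
          out[[length(out) + 1L]] <- data.frame(
            core_id = cores$id[i], axis = axis, loc_idx = k, r_nm = v[1])
      }
    }
  }
  do.call(rbind, out)
}

# Layout holding explicitly placed cores (bypasses the cluster process).
manual_layout <- function(x, y, radius_nm = 100, base_intensity = 100,
                          field_size_nm = c(4000, 4000), islet_id = 1L) {
  layout_from_cores(x, y, radius_nm, base_intensity, field_size_nm, islet_id)
}

core_table <- function(layout) {
  core_set(data.frame(id = layout$cores$core_id, x_nm = layout$cores$x_nm,
                      y_nm = layout$cores$y_nm))
}
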