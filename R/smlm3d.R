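#' Read a 3D localization table from CSV
#'
#' @param path CSV path.
#' @param columns named mapping from the required fields \code{x_nm, y_nm,
#'   z_nm, protein, cell} to the file's column names; unmapped fields use
#'   their own name. \code{protein} and \code{cell} default to
#'   \code{"unknown"} / \code{"cell1"} when absent.
#' @return a data.frame of class \code{loc_table}.
#' @export
read_locs <- function(path, columns = NULL) {
  raw <- utils::read.csv(path)
  want <- c("x_nm", "y_nm", "z_nm", "protein", "cell")
  map <- stats::setNames(want, want)
  if (!is.null(columns)) map[names(columns)] <- unlist(columns)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in want) {
    if (map[[f]] %in% names(raw)) out[[f]] <- raw[[map[[f]]]]
    else if (f == "protein") out[[f]] <- "unknown"
    else if (f == "cell") out[[f]] <- "cell1"
    else stop("read_locs: missing required column ", map[[f]])
  }
  if (!all(is.finite(out$x_nm) & is.finite(out$y_nm) & is.finite(out$z_nm)))
    stop("read_locs: non-finite coordinates")
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Read belt geometry from a structured-text file
#'
#' Expects a CSV with columns \code{cell, angle_deg, interior_side}
#' (interior_side being +1 or -1).
#'
#' @param path CSV path.
#' @return named list of \code{\link{belt_geometry}} objects, keyed by cell.
#' @export
read_belt_geometry <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell", "angle_deg", "interior_side") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i)
    belt_geometry(df$angle_deg[i], df$interior_side[i], df$cell[i]))
  stats::setNames(out, df$cell)
}

#' Assign localizations to core-centered oriented boxes
#'
#' For every core and each of the two axes (along the belt and transverse
#' to it), localizations inside a box of the stated length and width whose
#' long axis follows that direction are converted to a signed core-relative
#' radial coordinate r: the projection onto the axis direction. For the
#' transverse axis, r is positive toward the cell interior and negative
#' toward the exterior; for the along-belt axis the sign follows a fixed
#' reference orientation of the axis (interior/exterior is undefined along
#' the belt). A localization may fall in boxes of several cores and is then
#' assigned to each.
#'
#' @param locs a \code{loc_table}.
#' @param cores a \code{\link{core_set}} in the same coordinate frame.
#' @param geom a \code{\link{belt_geometry}}, or a named list of them keyed
#'   by cell id; cells without geometry are skipped with a warning.
#' @param box_length_nm,box_width_nm box dimensions (defaults 10000 x 200 nm).
#' @return a data.frame of class \code{rz_points}: \code{r_nm, z_nm,
#'   core_id, axis, cell, protein, loc_idx}.
#' @export
assign_locs <- function(locs, cores, geom, box_length_nm = 10000, box_width_nm = 200) {
  if (inherits(geom, "belt_geometry")) {
    gl <- list(geom)
    names(gl) <- geom$cell
    # a single geometry given: apply it to all cells present
    if (length(unique(locs$cell)) == 1) names(gl) <- unique(locs$cell)
    geom <- gl
  }
  half_l <- box_length_nm / 2; half_w <- box_width_nm / 2
  out <- list()
  for (cl in unique(locs$cell)) {
    g <- geom[[cl]]
    if (is.null(g)) {
      warning("assign_locs: no belt geometry for cell '", cl, "'; skipped")
      next
    }
    sub <- locs[locs$cell == cl, , drop = FALSE]
    idx <- which(locs$cell == cl)
    for (axis in c("along_belt", "transverse")) {
      dirv <- if (axis == "along_belt") g$u else g$normal
      perp <- if (axis == "along_belt") g$normal else g$u
      for (i in seq_len(nrow(cores))) {
        dx <- sub$x_nm - cores$x_nm[i]; dy <- sub$y_nm - cores$y_nm[i]
        r <- dx * dirv[1] + dy * dirv[2]
        p <- dx * perp[1] + dy * perp[2]
        inb <- abs(r) <= half_l & abs(p) <= half_w
        if (!any(inb)) next
        out[[length(out) + 1L]] <- data.frame(
          r_nm = r[inb], z_nm = sub$z_nm[inb], core_id = cores$id[i],
          axis = axis, cell = cl, protein = sub$protein[inb],
          loc_idx = idx[inb])
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(r_nm = numeric(0), z_nm = numeric(0), core_id = integer(0),
               axis = character(0), cell = character(0), protein = character(0),
               loc_idx = integer(0))
  rownames(res) <- NULL
  class(res) <- c("rz_points", "data.frame")
  res
}

#' Signed r bin edges: fine near the core, coarse farther out
#'
#' 100 nm classes until 1 um from the core, 500 nm classes beyond, symmetric
#' about 0, half-open \code{[low, high)} so that 0 belongs to the first
#' interior-side class.
#'
#' @param inner_bin_nm,inner_extent_nm,outer_bin_nm,outer_extent_nm class
#'   geometry.
#' @return numeric vector of bin edges.
#' @export
rz_bin_edges <- function(inner_bin_nm = 100, inner_extent_nm = 1000,
                         outer_bin_nm = 500, outer_extent_nm = 5000) {
  pos <- c(seq(0, inner_extent_nm, by = inner_bin_nm),
           seq(inner_extent_nm + outer_bin_nm, outer_extent_nm, by = outer_bin_nm))
  sort(unique(c(-pos, pos)))
}

#' Bin r-z points into the variable-width class profile
#'
#' Per r-class and per cell, the median height of all points pooled over
#' that cell's cores (each cross-section direction treated independently via
#' the \code{axis} filter). Empty classes are absent from the output, not
#' zero.
#'
#' @param points an \code{rz_points} data.frame.
#' @param axis which axis to profile (default \code{"transverse"}).
#' @param edges bin edges, default \code{\link{rz_bin_edges}()}.
#' @return data.frame of class \code{rz_profile}: \code{bin_low_nm,
#'   bin_high_nm, bin_center_nm, cell, median_z_nm, n}.
#' @export
bin_rz <- function(points, axis = "transverse", edges = rz_bin_edges()) {
  stopifnot(nrow(points) > 0)
  sub <- points[points$axis == axis, , drop = FALSE]
  if (nrow(sub) == 0) stop("bin_rz: no points on axis '", axis, "'")
  bi <- findInterval(sub$r_nm, edges)             # edges[i] <= r < edges[i+1]
  ok <- bi >= 1 & bi < length(edges)
  sub <- sub[ok, , drop = FALSE]; bi <- bi[ok]
  out <- list()
  for (cl in unique(sub$cell)) {
    scl <- sub$cell == cl
    for (b in sort(unique(bi[scl]))) {
      z <- sub$z_nm[scl & bi == b]
      out[[length(out) + 1L]] <- data.frame(
        bin_low_nm = edges[b], bin_high_nm = edges[b + 1],
        bin_center_nm = (edges[b] + edges[b + 1]) / 2,
        cell = cl, median_z_nm = stats::median(z), n = length(z))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rz_profile", "data.frame")
  res
}

#' Radial and vertical distributions and median heights
#'
#' Unit-area histograms of r and z over the assigned points, plus the median
#' axial position per cell and pooled: the pooled per-protein summary is the
#' median of the per-cell medians (cells analyzed independently), alongside
#' the point-level pooled median.
#'
#' @param points an \code{rz_points} data.frame.
#' @param axis axis to use for the radial histogram (default transverse).
#' @param r_bin_nm,z_bin_nm histogram bin widths.
#' @return list with \code{radial}, \code{vertical} (data.frames
#'   \code{bin_low, bin_high, density}), \code{median_z} (per protein x cell)
#'   and \code{pooled} (per protein: median of cell medians and point-level
#'   median).
#' @export
rz_distributions <- function(points, axis = "transverse", r_bin_nm = 100, z_bin_nm = 20) {
  stopifnot(nrow(points) > 0)
  sub <- points[points$axis == axis, , drop = FALSE]
  histo <- function(v, w) {
    lo <- floor(min(v) / w) * w
    edges <- seq(lo, max(v) + w, by = w)
    ct <- tabulate(findInterval(v, edges), nbins = length(edges) - 1)
    data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
               density = ct / (sum(ct) * w))
  }
  med <- stats::aggregate(z_nm ~ protein + cell, data = points, FUN = stats::median)
  names(med)[3] <- "median_z_nm"
  med$n <- stats::aggregate(z_nm ~ protein + cell, data = points, FUN = length)$z_nm
  pooled <- do.call(rbind, lapply(split(med, med$protein), function(d)
    data.frame(protein = d$protein[1],
               median_of_cell_medians_nm = stats::median(d$median_z_nm),
               n_cells = nrow(d))))
  pooled$point_median_nm <- vapply(pooled$protein, function(p)
    stats::median(points$z_nm[points$protein == p]), 0)
  rownames(pooled) <- NULL
  list(radial = histo(sub$r_nm, r_bin_nm),
       vertical = histo(points$z_nm, z_bin_nm),
       median_z = med, pooled = pooled)
}

#' Interior/exterior symmetry index
#'
#' Per cell, on transverse-axis points with r != 0:
#' \code{(N_interior - N_exterior) / (N_interior + N_exterior)}; +1 means
#' all molecules sit on the interior side, 0 a mirror-symmetric belt.
#'
#' @param points an \code{rz_points} data.frame.
#' @return data.frame \code{cell, index, n}; cells with no off-axis
#'   transverse points get \code{NA}.
#' @export
symmetry_index <- function(points) {
  sub <- points[points$axis == "transverse" & points$r_nm != 0, , drop = FALSE]
  cells <- unique(points$cell)
  out <- lapply(cells, function(cl) {
    r <- sub$r_nm[sub$cell == cl]
    if (!length(r)) return(data.frame(cell = cl, index = NA_real_, n = 0L))
    data.frame(cell = cl, index = (sum(r > 0) - sum(r < 0)) / length(r),
               n = length(r))
  })
  do.call(rbind, out)
}
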