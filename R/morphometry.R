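#' Build the Delaunay neighbor graph of a core set
#'
#' Applies Delaunay tessellation to the core centroids, computes the
#' Euclidean length of each edge, flags vertices on the convex hull, and
#' marks as excluded every edge whose *both* endpoints lie on the hull
#' (border edges of the tessellated region are unreliable neighbor pairs;
#' hull-to-interior edges are retained). Cocircular degeneracies are broken
#' by the triangulator deterministically for a given input.
#'
#' @param cores a \code{\link{core_set}} or data.frame with \code{x_nm},
#'   \code{y_nm} and \code{id} columns; at least 3 non-collinear points.
#' @return a \code{neighbor_graph}: list with \code{vertices} (data.frame
#'   \code{id, x_nm, y_nm, hull}) and \code{edges} (data.frame
#'   \code{i, j, length_nm, excluded}; i, j are core ids).
#' @export
build_graph <- function(cores) {
  df <- as.data.frame(cores)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop("build_graph: need x_nm and y_nm columns")
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  n <- nrow(df)
  if (n < 3) stop("build_graph: need at least 3 points")
  xy <- cbind(df$x_nm, df$y_nm)
  # collinearity check via the smaller singular value of centered coordinates
  sv <- svd(scale(xy, scale = FALSE))$d
  if (sv[2] <= 1e-9 * max(sv[1], 1))
    stop("build_graph: degenerate input - all points (near-)collinear")
  dd <- deldir::deldir(df$x_nm, df$y_nm, suppressMsge = TRUE)
  seg <- dd$delsgs
  hull_idx <- grDevices::chull(xy)
  hull <- seq_len(n) %in% hull_idx
  # lengths from the input coordinates (deldir rescales internally)
  len <- sqrt((df$x_nm[seg$ind1] - df$x_nm[seg$ind2])^2 +
              (df$y_nm[seg$ind1] - df$y_nm[seg$ind2])^2)
  edges <- data.frame(i = df$id[seg$ind1], j = df$id[seg$ind2],
                      length_nm = len,
                      excluded = hull[seg$ind1] & hull[seg$ind2])
  # canonical unordered orientation: i < j by id order
  swap <- match(edges$i, df$id) > match(edges$j, df$id)
  tmp <- edges$i[swap]; edges$i[swap] <- edges$j[swap]; edges$j[swap] <- tmp
  structure(list(vertices = data.frame(id = df$id, x_nm = df$x_nm,
                                       y_nm = df$y_nm, hull = hull),
                 edges = edges),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("neighbor_graph: %d vertices (%d on hull), %d edges (%d excluded)\n",
              nrow(x$vertices), sum(x$vertices$hull),
              nrow(x$edges), sum(x$edges$excluded)))
  invisible(x)
}

.incident_included <- function(graph) {
  e <- graph$edges[!graph$edges$excluded, , drop = FALSE]
  lapply(graph$vertices$id, function(v)
    e$length_nm[e$i == v | e$j == v])
}

#' Direct-neighbor distance statistics
#'
#' Per vertex, the mean length of its included (non-hull-hull) incident
#' Delaunay edges; vertices with no included edges are reported missing.
#' The pooled distribution over all included edges and its median are also
#' returned: per-vertex means and pooled edge lengths answer slightly
#' different questions, so both are reported, with the pooled median as the
#' headline summary.
#'
#' @param graph a \code{neighbor_graph}.
#' @return list with \code{per_vertex} (data.frame \code{id, mean_nm, n_edges}),
#'   \code{pooled_nm} (included edge lengths), \code{pooled_median_nm} and
#'   \code{per_vertex_median_nm}.
#' @export
direct_neighbor_stats <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  inc <- .incident_included(graph)
  if (all(vapply(inc, length, 0L) == 0)) {
    warning("direct_neighbor_stats: no included edges")
    return(list(per_vertex = data.frame(id = graph$vertices$id,
                                        mean_nm = NA_real_, n_edges = 0L),
                pooled_nm = numeric(0), pooled_median_nm = NA_real_,
                per_vertex_median_nm = NA_real_))
  }
  pv <- data.frame(id = graph$vertices$id,
                   mean_nm = vapply(inc, function(v)
                     if (length(v)) mean(v) else NA_real_, 0),
                   n_edges = vapply(inc, length, 0L))
  pooled <- graph$edges$length_nm[!graph$edges$excluded]
  list(per_vertex = pv, pooled_nm = pooled,
       pooled_median_nm = stats::median(pooled),
       per_vertex_median_nm = stats::median(pv$mean_nm, na.rm = TRUE))
}

#' Nearest-neighbor distance statistics
#'
#' Per vertex, the minimum over its included incident Delaunay edges. For
#' interior vertices this equals the global nearest-neighbor distance (the
#' nearest-neighbor graph is a subgraph of the Delaunay triangulation).
#'
#' @param graph a \code{neighbor_graph}.
#' @return list with \code{per_vertex} (data.frame \code{id, min_nm, n_edges})
#'   and \code{median_nm} over vertices with at least one included edge.
#' @export
nearest_neighbor_stats <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  inc <- .incident_included(graph)
  if (all(vapply(inc, length, 0L) == 0)) {
    warning("nearest_neighbor_stats: no included edges")
    return(list(per_vertex = data.frame(id = graph$vertices$id,
                                        min_nm = NA_real_, n_edges = 0L),
                median_nm = NA_real_))
  }
  pv <- data.frame(id = graph$vertices$id,
                   min_nm = vapply(inc, function(v)
                     if (length(v)) min(v) else NA_real_, 0),
                   n_edges = vapply(inc, length, 0L))
  list(per_vertex = pv, median_nm = stats::median(pv$min_nm, na.rm = TRUE))
}

#' Histogram of neighbor distances with explicit bin edges
#'
#' @param values distances (nm).
#' @param bin_width_nm bin width; bins start at 0.
#' @return data.frame \code{bin_low_nm, bin_high_nm, count}; bin edges are
#'   half-open \code{[low, high)}.
#' @export
distance_histogram <- function(values, bin_width_nm = 100) {
  values <- values[!is.na(values)]
  if (!length(values)) return(data.frame(bin_low_nm = numeric(0),
                                         bin_high_nm = numeric(0), count = integer(0)))
  edges <- seq(0, (floor(max(values) / bin_width_nm) + 1) * bin_width_nm,
               by = bin_width_nm)
  idx <- findInterval(values, edges)
  cnt <- tabulate(idx, nbins = length(edges) - 1)
  data.frame(bin_low_nm = edges[-length(edges)], bin_high_nm = edges[-1],
             count = cnt)
}

#' Match detected cores against ground truth
#'
#' Maximum-cardinality bipartite matching between detections and reference
#' positions, allowing matches only within \code{max_dist_nm}. Used for
#' recall/precision benchmarking of the detector against a synthetic
#' ground-truth layout.
#'
#' @param detected,truth data.frames with \code{x_nm}, \code{y_nm}.
#' @param max_dist_nm matching radius (nm).
#' @return list with \code{pairs} (data.frame \code{det_idx, truth_idx,
#'   dist_nm}), \code{recall}, \code{precision}, \code{median_error_nm}.
#' @export
match_cores <- function(detected, truth, max_dist_nm = 150) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0 || nt == 0)
    return(list(pairs = data.frame(det_idx = integer(0), truth_idx = integer(0),
                                   dist_nm = numeric(0)),
                recall = 0, precision = if (nd == 0) NA_real_ else 0,
                median_error_nm = NA_real_))
  d2 <- outer(detected$x_nm, truth$x_nm, "-")^2 + outer(detected$y_nm, truth$y_nm, "-")^2
  ok <- which(d2 <= max_dist_nm^2, arr.ind = TRUE)
  if (nrow(ok) == 0)
    return(list(pairs = data.frame(det_idx = integer(0), truth_idx = integer(0),
                                   dist_nm = numeric(0)),
                recall = 0, precision = 0, median_error_nm = NA_real_))
  types <- c(rep(FALSE, nd), rep(TRUE, nt))
  g <- igraph::make_bipartite_graph(types,
         as.vector(rbind(ok[, 1], nd + ok[, 2])), directed = FALSE)
  m <- igraph::max_bipartite_match(g)$matching
  det_side <- m[seq_len(nd)]
  matched <- which(!is.na(det_side))
  pairs <- data.frame(det_idx = matched, truth_idx = det_side[matched] - nd)
  pairs$dist_nm <- sqrt(d2[cbind(pairs$det_idx, pairs$truth_idx)])
  list(pairs = pairs, recall = nrow(pairs) / nt, precision = nrow(pairs) / nd,
       median_error_nm = stats::median(pairs$dist_nm))
}

#' Write a neighbor graph to CSV files
#'
#' @param graph a \code{neighbor_graph}.
#' @param dir output directory; writes \code{edges.csv} and
#'   \code{vertices.csv}.
#' @export
write_graph <- function(graph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(graph$edges, file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(graph$vertices, file.path(dir, "vertices.csv"), row.names = FALSE)
  invisible(dir)
}
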