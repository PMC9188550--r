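# Nuclear-architecture graph features: Voronoi cell statistics (bounded
# cells only), Delaunay triangle statistics, Euclidean MST edge lengths
# and k-nearest-neighbour distances over nucleus centroids, each
# summarised by mean, standard deviation, min/max ratio and the disorder
# statistic 1 - 1/(1 + sd/mean). 12 measurements x 4 summaries + the
# centroid count = 49 features.

# the four summary operators applied to every measurement sequence
graph_summaries <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) < 1L)
    return(c(Mean = NA_real_, Stddev = NA_real_, MinMaxRatio = NA_real_,
             Disorder = NA_real_))
  m <- mean(v)
  s <- if (length(v) > 1L) sd(v) else 0
  c(Mean = m, Stddev = s,
    MinMaxRatio = if (max(v) > 0) min(v) / max(v) else NA_real_,
    Disorder = if (m > 0) 1 - 1 / (1 + s / m) else NA_real_)
}

# Delaunay / Voronoi tessellation measurements for a centroid set.
# Returns NULL when the tessellation is degenerate (< 4 distinct points,
# collinear points, ...).
tessellation_stats <- function(centroids, extent = NULL) {
  pts <- unique(round(cbind(centroids[, 1], centroids[, 2]), 9))
  if (nrow(pts) < 4L) return(NULL)
  x <- pts[, 2]; y <- pts[, 1]  # col -> x, row -> y
  if (qr(cbind(x - mean(x), y - mean(y)))$rank < 2L) return(NULL)
  # clipping window: the tile extent when given (cells clipped by the
  # tile are excluded), otherwise the bounding box expanded well beyond
  # the point set so that only truly unbounded (hull) cells are clipped
  # -- making the bounded-cell set, and hence the statistics, invariant
  # under rigid motions of the centroids
  rw <- if (is.null(extent)) {
    pad <- 2 * max(diff(range(x)), diff(range(y)), 1)
    c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  } else c(0, extent[2], 0, extent[1])
  dd <- tryCatch(
    suppressWarnings(deldir::deldir(x, y, rw = rw, round = FALSE,
                                    suppressMsge = TRUE)),
    error = function(e) NULL)
  if (is.null(dd)) return(NULL)

  # boundary points: on the convex hull polygon, including points lying
  # (collinearly) on a hull edge, which chull() does not report
  hull <- chull(x, y)
  hx <- x[hull]; hy <- y[hull]
  nh <- length(hull)
  scale <- max(diff(range(x)), diff(range(y)), 1)
  on_boundary <- rep(FALSE, length(x))
  for (e in seq_len(nh)) {
    x1 <- hx[e]; y1 <- hy[e]
    x2 <- hx[e %% nh + 1L]; y2 <- hy[e %% nh + 1L]
    dxe <- x2 - x1; dye <- y2 - y1
    len2 <- dxe^2 + dye^2
    if (len2 <= 0) next
    t <- pmin(1, pmax(0, ((x - x1) * dxe + (y - y1) * dye) / len2))
    d2 <- (x - (x1 + t * dxe))^2 + (y - (y1 + t * dye))^2
    on_boundary <- on_boundary | d2 < (1e-7 * scale)^2
  }
  # points Delaunay-adjacent to the boundary: their cells are shaped by
  # the ragged edge, so cell statistics use the once-eroded interior
  seg <- dd$delsgs
  near_boundary <- on_boundary
  near_boundary[c(seg$ind1[on_boundary[seg$ind2]],
                  seg$ind2[on_boundary[seg$ind1]])] <- TRUE

  # Voronoi: keep cells of eroded-interior points, unclipped by the window
  tiles <- deldir::tile.list(dd)
  bounded <- Filter(function(tl) !any(tl$bp) && !near_boundary[tl$ptNum],
                    tiles)
  vor_area <- unname(vapply(bounded, function(tl) tl$area, numeric(1)))
  vor_perim <- unname(vapply(bounded, function(tl)
    polygon_perimeter(tl$x, tl$y), numeric(1)))
  vor_maxd <- unname(vapply(bounded, function(tl)
    max(dist(cbind(tl$x, tl$y))), numeric(1)))

  # Delaunay triangles; boundary triangles (any vertex on the convex
  # hull boundary) are excluded from the statistics so a perfect lattice
  # scores exactly zero spread -- unless no interior triangle exists, in
  # which case all triangles are used
  tris <- deldir::triang.list(dd)
  interior <- Filter(function(tr) !any(on_boundary[tr$ptNum]), tris)
  if (length(interior) == 0L) interior <- tris
  tri_sides <- unlist(lapply(interior, function(tr) {
    as.vector(dist(cbind(tr$x, tr$y)))
  }))
  tri_area <- vapply(interior, function(tr) polygon_area(tr$x, tr$y),
                     numeric(1))
  tri_perim <- vapply(interior, function(tr)
    polygon_perimeter(tr$x, tr$y), numeric(1))

  # Euclidean MST: minimum spanning tree of the Delaunay edge graph
  seg <- dd$delsgs
  elen <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  g <- igraph::graph_from_edgelist(cbind(seg$ind1, seg$ind2),
                                   directed = FALSE)
  igraph::E(g)$weight <- elen
  mst_len <- igraph::E(igraph::mst(g))$weight

  # k-nearest-neighbour distances
  dm <- as.matrix(dist(cbind(x, y)))
  diag(dm) <- Inf
  sorted <- apply(dm, 1L, sort)
  knn <- lapply(c(1L, 3L, 5L, 7L, 9L), function(k) {
    if (k <= nrow(pts) - 1L) sorted[k, ] else numeric(0)
  })

  list(Voronoi_Area = vor_area, Voronoi_Perimeter = vor_perim,
       Voronoi_Max_Distance = vor_maxd, Delaunay_Sides = tri_sides,
       Delaunay_Area = tri_area, Delaunay_Perimeter = tri_perim,
       MST_Edge_Length = mst_len,
       NN_Distance_K1 = knn[[1]], NN_Distance_K3 = knn[[2]],
       NN_Distance_K5 = knn[[3]], NN_Distance_K7 = knn[[4]],
       NN_Distance_K9 = knn[[5]],
       n_points = nrow(pts))
}

#' Extract the 49 nuclear-architecture graph features
#'
#' Builds the Voronoi diagram, Delaunay triangulation, Euclidean minimum
#' spanning tree and k-nearest-neighbour distance sets of the nucleus
#' centroids, then summarises each measurement sequence by mean,
#' standard deviation, min/max ratio and disorder
#' (`1 - 1/(1 + sd/mean)`, zero for perfectly regular arrangements).
#' Unbounded Voronoi cells and cells clipped by the window are excluded
#' from cell statistics.
#'
#' @param centroids n x 2 matrix of (row, col) centroid coordinates, or a
#'   `nuclei_labels` object.
#' @param extent optional `c(height, width)` tile extent used as the
#'   Voronoi clipping window; defaults to the centroid bounding box.
#' @return named numeric vector of length 49 in registry order. Fewer
#'   than 4 distinct non-collinear centroids yield the sentinel vector
#'   (all `NA` except `Graph_Nuclei_Count`).
#' @export
extract_graph <- function(centroids, extent = NULL) {
  if (inherits(centroids, "nuclei_labels")) {
    if (is.null(extent)) extent <- dim(centroids$labels)
    centroids <- centroids$centroids
  }
  nm <- graph_feature_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  n <- if (is.null(centroids)) 0L else nrow(centroids)
  out["Graph_Nuclei_Count"] <- n
  if (n < 4L) return(out)
  st <- tessellation_stats(centroids, extent)
  if (is.null(st)) return(out)
  for (meas in graph_measurement_names()) {
    s <- graph_summaries(st[[meas]])
    out[paste0(meas, "_", names(s))] <- s
  }
  out["Graph_Nuclei_Count"] <- n
  out
}
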