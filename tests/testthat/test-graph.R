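test_that("perfect lattices have zero spread and zero disorder", {
  pts <- tri_lattice(400L, 40, margin = 20)
  f <- extract_graph(pts)
  expect_equal(unname(f["Delaunay_Sides_Stddev"]), 0, tolerance = 1e-6)
  expect_equal(unname(f["Delaunay_Area_Stddev"]), 0, tolerance = 1e-6)
  expect_equal(unname(f["Voronoi_Max_Distance_Disorder"]), 0,
               tolerance = 1e-6)
  expect_equal(unname(f["MST_Edge_Length_Disorder"]), 0, tolerance = 1e-6)
  expect_equal(unname(f["Graph_Nuclei_Count"]), nrow(pts))
})

test_that("unit-square corners give two triangles of area one half", {
  pts <- cbind(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1))
  st <- histopcr:::tessellation_stats(pts)
  expect_length(st$Delaunay_Area, 2L)
  expect_equal(st$Delaunay_Area, c(0.5, 0.5))
  f <- extract_graph(pts)
  expect_equal(unname(f["Delaunay_Area_Stddev"]), 0)
})

test_that("triangle statistics match the empty-circumcircle oracle", {
  for (s in 1:5) {
    pts <- withr::with_seed(500L + s,
                            cbind(row = runif(30, 0, 100),
                                  col = runif(30, 0, 100)))
    st <- histopcr:::tessellation_stats(pts)
    xy <- cbind(pts[, 2], pts[, 1])
    tris <- oracle_delaunay(xy)
    # boundary triangles (hull vertex) are excluded from the statistics
    hull <- chull(xy[, 1], xy[, 2])
    tris <- Filter(function(id) !any(id %in% hull), tris)
    areas <- vapply(tris, function(id)
      oracle_poly_area(xy[id, ]), numeric(1))
    expect_equal(sort(st$Delaunay_Area), sort(areas), tolerance = 1e-9)
    sides <- unlist(lapply(tris, function(id) as.vector(dist(xy[id, ]))))
    expect_equal(sort(st$Delaunay_Sides), sort(sides), tolerance = 1e-9)
  }
})

test_that("MST length matches Prim's algorithm on the complete graph", {
  for (s in 1:5) {
    pts <- withr::with_seed(600L + s,
                            cbind(row = runif(25, 0, 50),
                                  col = runif(25, 0, 50)))
    st <- histopcr:::tessellation_stats(pts)
    expect_equal(sum(st$MST_Edge_Length),
                 oracle_mst_length(cbind(pts[, 2], pts[, 1])),
                 tolerance = 1e-9)
    expect_length(st$MST_Edge_Length, nrow(pts) - 1L)
  }
})

test_that("bounded Voronoi cells match half-plane intersection", {
  pts <- withr::with_seed(77L, cbind(row = runif(20, 0, 100),
                                     col = runif(20, 0, 100)))
  st <- histopcr:::tessellation_stats(pts)
  xy <- cbind(pts[, 2], pts[, 1])
  # cell statistics cover the once-eroded interior: drop hull points and
  # points sharing a Delaunay edge with one (recomputed independently)
  hull <- chull(xy[, 1], xy[, 2])
  tris <- oracle_delaunay(xy)
  adj <- unique(unlist(lapply(tris, function(id)
    if (any(id %in% hull)) id)))
  keep <- setdiff(seq_len(nrow(xy)), union(hull, adj))
  # clipping window far beyond the point set: only unbounded cells touch
  pad <- 2 * max(diff(range(xy[, 1])), diff(range(xy[, 2])), 1)
  box <- c(min(xy[, 1]) - pad, max(xy[, 1]) + pad,
           min(xy[, 2]) - pad, max(xy[, 2]) + pad)
  areas <- c(); maxd <- c()
  for (i in keep) {
    cell <- oracle_voronoi_cell(xy, i, box)
    if (nrow(cell) >= 3L && !oracle_cell_clipped(cell, box)) {
      areas <- c(areas, oracle_poly_area(cell))
      maxd <- c(maxd, max(dist(cell)))
    }
  }
  expect_equal(unname(sort(st$Voronoi_Area)), sort(areas),
               tolerance = 1e-6)
  expect_equal(unname(sort(st$Voronoi_Max_Distance)), sort(maxd),
               tolerance = 1e-6)
})

test_that("graph features are rigid-motion invariant and scale sanely", {
  pts <- withr::with_seed(9L, cbind(row = runif(40, 0, 80),
                                    col = runif(40, 0, 80)))
  f0 <- extract_graph(pts)
  # translation
  expect_equal(extract_graph(pts + 37.5), f0, tolerance = 1e-9)
  # rotation by 33 degrees about the centroid
  th <- 33 * pi / 180
  ctr <- colMeans(pts)
  rot <- cbind(row = cos(th) * (pts[, 1] - ctr[1]) -
                 sin(th) * (pts[, 2] - ctr[2]),
               col = sin(th) * (pts[, 1] - ctr[1]) +
                 cos(th) * (pts[, 2] - ctr[2]))
  expect_equal(extract_graph(rot), f0, tolerance = 1e-9)
  # scaling: lengths scale by s, areas by s^2, ratios/disorder unchanged
  s <- 2.5
  fs <- extract_graph(pts * s)
  expect_equal(unname(fs["Delaunay_Sides_Mean"]),
               unname(s * f0["Delaunay_Sides_Mean"]), tolerance = 1e-9)
  expect_equal(unname(fs["Voronoi_Area_Mean"]),
               unname(s^2 * f0["Voronoi_Area_Mean"]), tolerance = 1e-9)
  expect_equal(unname(fs["MST_Edge_Length_Disorder"]),
               unname(f0["MST_Edge_Length_Disorder"]), tolerance = 1e-9)
  expect_equal(unname(fs["NN_Distance_K1_MinMaxRatio"]),
               unname(f0["NN_Distance_K1_MinMaxRatio"]), tolerance = 1e-9)
})

test_that("disorder lies in [0, 1) and vanishes iff the spread does", {
  for (s in 1:10) {
    pts <- withr::with_seed(700L + s,
                            cbind(row = runif(25, 0, 60),
                                  col = runif(25, 0, 60)))
    f <- extract_graph(pts)
    dis <- f[grep("_Disorder$", names(f))]
    dis <- dis[is.finite(dis)]
    expect_true(all(dis >= 0 & dis < 1))
  }
  # disorder is strictly increasing in sd/mean
  v1 <- histopcr:::graph_summaries(c(10, 10.1, 9.9))
  v2 <- histopcr:::graph_summaries(c(10, 14, 6))
  expect_gt(v2["Disorder"], v1["Disorder"])
  expect_equal(unname(histopcr:::graph_summaries(rep(3, 5))["Disorder"]), 0)
})

test_that("degenerate centroid sets yield the sentinel vector", {
  f3 <- extract_graph(cbind(row = c(1, 2, 3), col = c(1, 2, 3)))
  expect_true(all(is.na(f3[setdiff(names(f3), "Graph_Nuclei_Count")])))
  expect_equal(unname(f3["Graph_Nuclei_Count"]), 3)
  # collinear points
  fc <- extract_graph(cbind(row = 1:10, col = 2 * (1:10)))
  expect_true(all(is.na(fc[setdiff(names(fc), "Graph_Nuclei_Count")])))
})
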