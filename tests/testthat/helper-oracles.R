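# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# flood-fill connected components (8- or 4-connectivity) via BFS
oracle_components <- function(mask, connectivity = 8L) {
  mask <- mask > 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8L)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  nlab <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (mask[r0, c0] && lab[r0, c0] == 0L) {
      nlab <- nlab + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- nlab
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          r <- cur[1] + o[1]; cc <- cur[2] + o[2]
          if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
              mask[r, cc] && lab[r, cc] == 0L) {
            lab[r, cc] <- nlab
            queue[[length(queue) + 1L]] <- c(r, cc)
          }
        }
      }
    }
  }
  areas <- if (nlab > 0L) tabulate(lab[lab > 0L], nlab) else integer(0)
  list(labels = lab, n = nlab, areas = areas)
}

# GLDM by direct per-pixel dependent-neighbour enumeration
oracle_gldm <- function(G, n_levels, alpha = 0L, delta = 1L) {
  h <- nrow(G); w <- ncol(G)
  rows <- list()
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (G[r, cc] == 0L) next
    dep <- 0L
    for (dr in -delta:delta) for (dc in -delta:delta) {
      if (dr == 0L && dc == 0L) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w && G[rr, c2] > 0L &&
          abs(G[r, cc] - G[rr, c2]) <= alpha)
        dep <- dep + 1L
    }
    rows[[length(rows) + 1L]] <- c(G[r, cc], dep + 1L)
  }
  if (!length(rows)) return(matrix(0, n_levels, 1L))
  m <- do.call(rbind, rows)
  P <- matrix(0, n_levels, max(m[, 2]))
  for (k in seq_len(nrow(m))) P[m[k, 1], m[k, 2]] <- P[m[k, 1], m[k, 2]] + 1
  P
}

# the 14 GLDM features straight from the definitions, scalar loops only
oracle_gldm_features <- function(P) {
  Nz <- sum(P)
  Ng <- nrow(P); Nd <- ncol(P)
  f <- c(SDE = 0, LDE = 0, GLN = 0, DNU = 0, DNUN = 0, GLV = 0, DV = 0,
         DE = 0, LGLE = 0, HGLE = 0, SDLGLE = 0, SDHGLE = 0, LDLGLE = 0,
         LDHGLE = 0)
  mu_i <- 0; mu_j <- 0
  for (i in 1:Ng) for (j in 1:Nd) {
    mu_i <- mu_i + P[i, j] / Nz * i
    mu_j <- mu_j + P[i, j] / Nz * j
  }
  for (i in 1:Ng) for (j in 1:Nd) {
    p <- P[i, j] / Nz
    f["SDE"] <- f["SDE"] + P[i, j] / j^2 / Nz
    f["LDE"] <- f["LDE"] + P[i, j] * j^2 / Nz
    f["GLV"] <- f["GLV"] + p * (i - mu_i)^2
    f["DV"] <- f["DV"] + p * (j - mu_j)^2
    if (p > 0) f["DE"] <- f["DE"] - p * log2(p)
    f["LGLE"] <- f["LGLE"] + P[i, j] / i^2 / Nz
    f["HGLE"] <- f["HGLE"] + P[i, j] * i^2 / Nz
    f["SDLGLE"] <- f["SDLGLE"] + P[i, j] / (i^2 * j^2) / Nz
    f["SDHGLE"] <- f["SDHGLE"] + P[i, j] * i^2 / j^2 / Nz
    f["LDLGLE"] <- f["LDLGLE"] + P[i, j] * j^2 / i^2 / Nz
    f["LDHGLE"] <- f["LDHGLE"] + P[i, j] * i^2 * j^2 / Nz
  }
  for (i in 1:Ng) f["GLN"] <- f["GLN"] + sum(P[i, ])^2 / Nz
  for (j in 1:Nd) f["DNU"] <- f["DNU"] + sum(P[, j])^2 / Nz
  f["DNUN"] <- f["DNU"] / Nz
  f
}

# all Delaunay triangles of a point set by the empty-circumcircle test
# (assumes general position: no 4 cocircular, no 3 collinear)
oracle_delaunay <- function(pts) {
  n <- nrow(pts)
  tris <- list()
  combs <- combn(n, 3L)
  for (k in seq_len(ncol(combs))) {
    id <- combs[, k]
    a <- pts[id[1], ]; b <- pts[id[2], ]; d <- pts[id[3], ]
    det <- 2 * (a[1] * (b[2] - d[2]) + b[1] * (d[2] - a[2]) +
                  d[1] * (a[2] - b[2]))
    if (abs(det) < 1e-12) next
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - d[2]) +
             (b[1]^2 + b[2]^2) * (d[2] - a[2]) +
             (d[1]^2 + d[2]^2) * (a[2] - b[2])) / det
    uy <- ((a[1]^2 + a[2]^2) * (d[1] - b[1]) +
             (b[1]^2 + b[2]^2) * (a[1] - d[1]) +
             (d[1]^2 + d[2]^2) * (b[1] - a[1])) / det
    r2 <- (a[1] - ux)^2 + (a[2] - uy)^2
    inside <- FALSE
    for (m in seq_len(n)) {
      if (m %in% id) next
      if ((pts[m, 1] - ux)^2 + (pts[m, 2] - uy)^2 < r2 * (1 - 1e-12)) {
        inside <- TRUE
        break
      }
    }
    if (!inside) tris[[length(tris) + 1L]] <- id
  }
  tris
}

# total MST length by Prim's algorithm on the complete Euclidean graph
oracle_mst_length <- function(pts) {
  n <- nrow(pts)
  dm <- as.matrix(dist(pts))
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  best <- dm[1, ]
  total <- 0
  for (step in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    total <- total + best[j]
    in_tree[j] <- TRUE
    best <- pmin(best, dm[j, ])
  }
  unname(total)
}

# Voronoi cell of point i clipped to a box, by half-plane intersection
# (Sutherland-Hodgman against each perpendicular bisector)
oracle_voronoi_cell <- function(pts, i, box) {
  poly <- cbind(x = box[c(1, 2, 2, 1)], y = box[c(3, 3, 4, 4)])
  pi_ <- pts[i, ]
  clip_halfplane <- function(poly, a, b, c0) {
    # keep a*x + b*y <= c0
    if (nrow(poly) == 0L) return(poly)
    keep <- a * poly[, 1] + b * poly[, 2] <= c0 + 1e-9
    out <- NULL
    n <- nrow(poly)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      p1 <- poly[k, ]; p2 <- poly[k2, ]
      if (keep[k]) out <- rbind(out, p1)
      if (keep[k] != keep[k2]) {
        t <- (c0 - a * p1[1] - b * p1[2]) /
          (a * (p2[1] - p1[1]) + b * (p2[2] - p1[2]))
        out <- rbind(out, p1 + t * (p2 - p1))
      }
    }
    if (is.null(out)) matrix(numeric(0), 0L, 2L) else out
  }
  for (j in seq_len(nrow(pts))) {
    if (j == i) next
    pj <- pts[j, ]
    a <- pj[1] - pi_[1]; b <- pj[2] - pi_[2]
    c0 <- (sum(pj^2) - sum(pi_^2)) / 2
    poly <- clip_halfplane(poly, a, b, c0)
  }
  poly
}

# shoelace area/perimeter of an (ordered) polygon given as x/y columns
oracle_poly_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x); j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# does a polygon touch the clip box (i.e. was the true cell unbounded
# or clipped)?
oracle_cell_clipped <- function(poly, box, tol = 1e-7) {
  any(abs(poly[, 1] - box[1]) < tol | abs(poly[, 1] - box[2]) < tol |
        abs(poly[, 2] - box[3]) < tol | abs(poly[, 2] - box[4]) < tol)
}
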