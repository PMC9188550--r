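# brute-force pair/run/zone oracles local to this file
oracle_glcm <- function(G, n_levels) {
  h <- nrow(G); w <- ncol(G)
  P <- matrix(0, n_levels, n_levels)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (o in offs) for (r in seq_len(h)) for (cc in seq_len(w)) {
    r2 <- r + o[1]; c2 <- cc + o[2]
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
        G[r, cc] > 0 && G[r2, c2] > 0) {
      P[G[r, cc], G[r2, c2]] <- P[G[r, cc], G[r2, c2]] + 1
      P[G[r2, c2], G[r, cc]] <- P[G[r2, c2], G[r, cc]] + 1  # symmetric
    }
  }
  P
}

oracle_glrlm <- function(G, n_levels) {
  h <- nrow(G); w <- ncol(G)
  runs <- list()
  walk <- function(r, cc, dr, dc) {
    path <- c()
    while (r >= 1 && r <= h && cc >= 1 && cc <= w) {
      path <- c(path, G[r, cc])
      r <- r + dr; cc <- cc + dc
    }
    rl <- rle(path)
    keep <- rl$values > 0
    if (any(keep)) cbind(rl$values[keep], rl$lengths[keep])
  }
  starts <- list(
    # horizontal: every row from column 1
    lapply(seq_len(h), function(r) walk(r, 1, 0, 1)),
    # vertical
    lapply(seq_len(w), function(cc) walk(1, cc, 1, 0)),
    # down-right diagonals: first column + first row
    c(lapply(seq_len(h), function(r) walk(r, 1, 1, 1)),
      lapply(2:w, function(cc) walk(1, cc, 1, 1))),
    # down-left diagonals: first row + last column
    c(lapply(seq_len(w), function(cc) walk(1, cc, 1, -1)),
      lapply(2:h, function(r) walk(r, w, 1, -1))))
  m <- do.call(rbind, unlist(starts, recursive = FALSE))
  if (is.null(m)) return(matrix(0, n_levels, 1))
  P <- matrix(0, n_levels, max(m[, 2]))
  for (k in seq_len(nrow(m))) P[m[k, 1], m[k, 2]] <- P[m[k, 1], m[k, 2]] + 1
  P
}

oracle_glszm <- function(G, n_levels) {
  sizes <- list()
  for (lev in seq_len(n_levels)) {
    comp <- oracle_components(G == lev, connectivity = 8L)
    if (comp$n > 0) sizes[[length(sizes) + 1L]] <- cbind(lev, comp$areas)
  }
  if (!length(sizes)) return(matrix(0, n_levels, 1))
  m <- do.call(rbind, sizes)
  P <- matrix(0, n_levels, max(m[, 2]))
  for (k in seq_len(nrow(m))) P[m[k, 1], m[k, 2]] <- P[m[k, 1], m[k, 2]] + 1
  P
}

test_that("GLCM counts equal exhaustive pair enumeration", {
  # the canonical two-level checkerboard small case
  cb <- matrix(rep(c(1L, 2L), length.out = 16L), 4L, 4L)
  expect_equal(histopcr:::glcm_matrix(cb, 2L), oracle_glcm(cb, 2L))
  for (s in 1:5) {
    G <- fixture_levels(6L, 7L, 3L, p_mask = 0.8, seed = s)
    expect_equal(histopcr:::glcm_matrix(G, 3L), oracle_glcm(G, 3L))
  }
})

test_that("degenerate textures return sentinels, not zeros", {
  gray <- matrix(5, 8L, 8L)
  mask <- matrix(TRUE, 8L, 8L)
  v <- extract_texture(gray, mask)
  expect_true(is.na(v["GLCM_Correlation"]))  # undefined on constant region
  expect_equal(unname(v["FirstOrder_Entropy"]), 0)
  expect_equal(unname(v["FirstOrder_Variance"]), 0)
  # single gray level: every matrix family collapses to one gray row
  expect_equal(unname(v["GLDM_GrayLevelVariance"]), 0)
  # sub-minimal mask is a full sentinel vector
  m1 <- matrix(FALSE, 4L, 4L); m1[2, 2] <- TRUE
  expect_true(all(is.na(extract_texture(matrix(1, 4, 4), m1))))
})

test_that("GLDM closed forms hold for tiny matrices", {
  # single-pixel region: one zone, P(1,1) = 1
  G <- matrix(0L, 3L, 3L); G[2, 2] <- 1L
  P <- gldm_matrix(G, 1L)
  expect_equal(sum(P), 1)
  f <- gldm_features(P)
  expect_equal(unname(f["GLDM_SmallDependenceEmphasis"]), 1)
  expect_equal(unname(f["GLDM_DependenceNonUniformity"]), 1)
  expect_equal(unname(f["GLDM_LargeDependenceHighGrayLevelEmphasis"]), 1)
  expect_equal(unname(f["GLDM_DependenceEntropy"]), 0)
  # two equal probability cells: entropy is exactly one bit
  P2 <- matrix(0, 2, 2); P2[1, 1] <- 1; P2[2, 2] <- 1
  expect_equal(unname(gldm_features(P2)["GLDM_DependenceEntropy"]), 1)
})

test_that("GLDM matches the neighbour-enumeration oracle exhaustively", {
  # every 2x2 image over 3 gray levels (fully masked): 81 cases
  for (code in 0:80) {
    digs <- c(code %% 3, code %/% 3 %% 3, code %/% 9 %% 3, code %/% 27) + 1L
    G <- matrix(as.integer(digs), 2L, 2L)
    expect_equal(gldm_matrix(G, 3L), oracle_gldm(G, 3L))
  }
  # every 2x3 image over 2 levels with level 0 allowed (masked out): 3^6
  for (code in 0:728) {
    digs <- integer(6L)
    cc <- code
    for (k in 1:6) { digs[k] <- cc %% 3; cc <- cc %/% 3 }
    G <- matrix(as.integer(digs), 2L, 3L)
    if (all(G == 0L)) next
    expect_equal(gldm_matrix(G, 2L), oracle_gldm(G, 2L))
  }
})

test_that("all 14 GLDM features equal the oracle on random 5x5 images", {
  for (s in 1:20) {
    G <- fixture_levels(5L, 5L, 3L, p_mask = 0.85, seed = 200L + s)
    if (!any(G > 0L)) next
    P <- gldm_matrix(G, 3L)
    expect_equal(P, oracle_gldm(G, 3L))
    got <- gldm_features(P)
    want <- oracle_gldm_features(P)
    expect_equal(unname(got["GLDM_SmallDependenceEmphasis"]),
                 unname(want["SDE"]))
    expect_equal(unname(got["GLDM_LargeDependenceEmphasis"]),
                 unname(want["LDE"]))
    expect_equal(unname(got["GLDM_GrayLevelNonUniformity"]),
                 unname(want["GLN"]))
    expect_equal(unname(got["GLDM_DependenceNonUniformity"]),
                 unname(want["DNU"]))
    expect_equal(unname(got["GLDM_DependenceNonUniformityNormalized"]),
                 unname(want["DNUN"]))
    expect_equal(unname(got["GLDM_GrayLevelVariance"]), unname(want["GLV"]))
    expect_equal(unname(got["GLDM_DependenceVariance"]), unname(want["DV"]))
    expect_equal(unname(got["GLDM_DependenceEntropy"]), unname(want["DE"]))
    expect_equal(unname(got["GLDM_LowGrayLevelEmphasis"]),
                 unname(want["LGLE"]))
    expect_equal(unname(got["GLDM_HighGrayLevelEmphasis"]),
                 unname(want["HGLE"]))
    expect_equal(unname(got["GLDM_SmallDependenceLowGrayLevelEmphasis"]),
                 unname(want["SDLGLE"]))
    expect_equal(unname(got["GLDM_SmallDependenceHighGrayLevelEmphasis"]),
                 unname(want["SDHGLE"]))
    expect_equal(unname(got["GLDM_LargeDependenceLowGrayLevelEmphasis"]),
                 unname(want["LDLGLE"]))
    expect_equal(unname(got["GLDM_LargeDependenceHighGrayLevelEmphasis"]),
                 unname(want["LDHGLE"]))
  }
})

test_that("GLDM respects alpha and delta parameters", {
  withr::with_seed(5, {
    G <- matrix(sample.int(4L, 36L, replace = TRUE), 6L, 6L)
    expect_equal(gldm_matrix(G, 4L, alpha = 1L, delta = 2L),
                 oracle_gldm(G, 4L, alpha = 1L, delta = 2L))
  })
})

test_that("GLRLM counts equal explicit line walking", {
  G0 <- matrix(c(1L, 1L, 2L, 2L, 1L, 2L), 2L, 3L)
  expect_equal(histopcr:::glrlm_matrix(G0, 2L), oracle_glrlm(G0, 2L))
  for (s in 1:5) {
    G <- fixture_levels(6L, 5L, 3L, p_mask = 0.75, seed = 300L + s)
    expect_equal(histopcr:::glrlm_matrix(G, 3L), oracle_glrlm(G, 3L))
  }
})

test_that("GLSZM zone sizes equal flood-fill enumeration", {
  for (s in 1:5) {
    G <- fixture_levels(7L, 6L, 3L, p_mask = 0.8, seed = 400L + s)
    expect_equal(histopcr:::glszm_matrix(G, 3L), oracle_glszm(G, 3L))
  }
})

test_that("NGTDM features match a direct hand computation", {
  # 3x3 fully masked, two levels
  G <- matrix(c(1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L), 3L, 3L)
  f <- histopcr:::ngtdm_features(G, 2L)
  # level 2 pixel: neighbours all 1 -> s_2 = |2 - 1| = 1
  # level 1 pixels: corner/edge neighbours include the 2
  # direct recomputation:
  s1 <- abs(1 - (1 * 2 + 2) / 3) * 4 + abs(1 - (1 * 4 + 2) / 5) * 4
  s2 <- 1
  p1 <- 8 / 9; p2 <- 1 / 9
  expect_equal(unname(f["NGTDM_Coarseness"]), 1 / (p1 * s1 + p2 * s2))
  expect_equal(unname(f["NGTDM_Contrast"]),
               (p1 * p2 * 1) * (s1 + s2) / 9)  # 2/(Ngp(Ngp-1)) = 1
  # denominator sums over ordered (i, j) pairs, so each pair counts twice
  expect_equal(unname(f["NGTDM_Busyness"]),
               (p1 * s1 + p2 * s2) / (2 * abs(1 * p1 - 2 * p2)))
})

test_that("first-order statistics equal direct recomputation", {
  withr::with_seed(12, {
    v <- runif(500, 0, 255)
    f <- histopcr:::firstorder_features(v, 32L)
    expect_equal(unname(f["FirstOrder_Mean"]), mean(v))
    expect_equal(unname(f["FirstOrder_Energy"]), sum(v^2))
    expect_equal(unname(f["FirstOrder_RootMeanSquared"]),
                 sqrt(mean(v^2)))
    expect_equal(unname(f["FirstOrder_Variance"]),
                 mean((v - mean(v))^2))
    expect_equal(unname(f["FirstOrder_InterquartileRange"]),
                 unname(quantile(v, 0.75) - quantile(v, 0.25)))
    expect_equal(unname(f["FirstOrder_MeanAbsoluteDeviation"]),
                 mean(abs(v - mean(v))))
  })
})

test_that("the texture block emits exactly 93 named values", {
  withr::with_seed(3, {
    gray <- matrix(runif(400, 0, 255), 20L, 20L)
    mask <- matrix(runif(400) < 0.7, 20L, 20L)
    v <- extract_texture(gray, mask)
    expect_length(v, 93L)
    expect_identical(names(v), histopcr:::texture_feature_names())
    expect_true(all(is.finite(v)))
  })
})
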