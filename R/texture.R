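# IBSI-style texture features over a masked grayscale region.
#
# All matrix families share one discretization: gray values inside the
# mask are binned into n_levels equal-width bins over the masked min-max
# range (a constant region maps to a single level). Pixels outside the
# mask are level 0 and never pair, run, zone or neighbour with masked
# pixels. The 93-feature texture block = 18 first-order + 24 GLCM +
# 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM.

#' Discretize a masked grayscale image into equal-width gray levels
#'
#' @param gray numeric matrix.
#' @param mask logical matrix, same extent.
#' @param n_levels number of gray levels (default 32).
#' @return integer matrix with levels `1..n_levels` inside the mask and
#'   0 outside; a constant region maps entirely to level 1.
#' @export
discretize_gray <- function(gray, mask, n_levels = 32L) {
  stopifnot(all(dim(gray) == dim(mask)))
  G <- matrix(0L, nrow(gray), ncol(gray))
  v <- gray[mask]
  if (length(v) == 0L) return(G)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) {
    G[mask] <- 1L
  } else {
    G[mask] <- pmin(as.integer(n_levels),
                    as.integer(floor((v - lo) / ((hi - lo) / n_levels))) + 1L)
  }
  G
}

## ---- GLCM -----------------------------------------------------------------

# symmetric co-occurrence counts pooled over the four delta = 1 offsets
glcm_matrix <- function(G, n_levels) {
  P <- matrix(0, n_levels, n_levels)
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    S <- shift_matrix(G, o[1], o[2])
    ok <- G > 0L & S > 0L
    if (!any(ok)) next
    idx <- (G[ok] - 1L) * n_levels + S[ok]
    P <- P + matrix(tabulate(idx, n_levels * n_levels), n_levels, n_levels,
                    byrow = TRUE)
  }
  P + t(P)
}

glcm_features <- function(P) {
  out <- setNames(rep(NA_real_, 24L), glcm_feature_names())
  N <- sum(P)
  if (N <= 0) return(out)
  Ng <- nrow(P)
  p <- P / N
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(px * seq_len(Ng)); my <- sum(py * seq_len(Ng))
  sx <- sqrt(sum(px * (seq_len(Ng) - mx)^2))
  sy <- sqrt(sum(py * (seq_len(Ng) - my)^2))
  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  kps <- 2:(2 * Ng)
  pxy_sum <- vapply(kps, function(k) sum(p[i + j == k]), numeric(1))
  kpd <- 0:(Ng - 1)
  pxy_dif <- vapply(kpd, function(k) sum(p[abs(i - j) == k]), numeric(1))
  da <- sum(kpd * pxy_dif)

  out["GLCM_Autocorrelation"] <- sum(p * i * j)
  out["GLCM_JointAverage"] <- mx
  out["GLCM_ClusterProminence"] <- sum(p * (i + j - mx - my)^4)
  out["GLCM_ClusterShade"] <- sum(p * (i + j - mx - my)^3)
  out["GLCM_ClusterTendency"] <- sum(p * (i + j - mx - my)^2)
  out["GLCM_Contrast"] <- sum(p * (i - j)^2)
  out["GLCM_Correlation"] <-
    if (sx > 0 && sy > 0) (sum(p * i * j) - mx * my) / (sx * sy) else NA_real_
  out["GLCM_DifferenceAverage"] <- da
  out["GLCM_DifferenceEntropy"] <- entropy_bits(pxy_dif)
  out["GLCM_DifferenceVariance"] <- sum(pxy_dif * (kpd - da)^2)
  out["GLCM_JointEnergy"] <- sum(p^2)
  hxy <- entropy_bits(p)
  out["GLCM_JointEntropy"] <- hxy
  pxi <- px[i]; pyj <- py[j]
  pos <- p > 0 & pxi > 0 & pyj > 0
  hxy1 <- -sum(p[pos] * log2(pxi[pos] * pyj[pos]))
  posm <- pxi > 0 & pyj > 0
  hxy2 <- -sum((pxi * pyj)[posm] * log2((pxi * pyj)[posm]))
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  out["GLCM_Imc1"] <-
    if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  out["GLCM_Imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  out["GLCM_Idm"] <- sum(p / (1 + (i - j)^2))
  out["GLCM_Idmn"] <- sum(p / (1 + ((i - j) / Ng)^2))
  out["GLCM_Id"] <- sum(p / (1 + abs(i - j)))
  out["GLCM_Idn"] <- sum(p / (1 + abs(i - j) / Ng))
  off <- i != j
  out["GLCM_InverseVariance"] <- sum(p[off] / (i[off] - j[off])^2)
  out["GLCM_MaximumProbability"] <- max(p)
  out["GLCM_SumAverage"] <- sum(kps * pxy_sum)
  out["GLCM_SumEntropy"] <- entropy_bits(pxy_sum)
  out["GLCM_SumSquares"] <- sum(p * (i - mx)^2)
  keep <- px > 0
  if (sum(keep) >= 2L) {
    # Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k)); MCC = sqrt(second
    # largest eigenvalue of Q), restricted to occurring gray levels
    ps <- p[keep, keep, drop = FALSE]
    pxs <- px[keep]; pys <- py[keep]
    W <- sweep(ps, 2L, ifelse(pys > 0, pys, 1), "/")
    Q <- sweep(ps %*% t(W), 1L, pxs, "/")
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    out["GLCM_MCC"] <- sqrt(max(0, ev[2]))
  }
  out
}

## ---- run / zone / dependence matrices -------------------------------------

# counts of runs along the columns of M (levels > 0; 0 breaks runs)
runs_along_cols <- function(M) {
  r <- rle(as.vector(rbind(M, 0L)))
  keep <- r$values > 0L
  cbind(level = r$values[keep], length = r$lengths[keep])
}

# shear so that diagonals of G become columns; sign +1 = (down-right)
shear_matrix <- function(G, sign) {
  h <- nrow(G); w <- ncol(G)
  S <- matrix(0L, h, w + h - 1L)
  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  sc <- if (sign > 0) cc - rr + h else cc + rr - 1L
  S[cbind(rr, sc)] <- as.vector(G)
  S
}

# gray-level run-length counts pooled over the four 2-D directions
glrlm_matrix <- function(G, n_levels) {
  runs <- rbind(runs_along_cols(G),
                runs_along_cols(t(G)),
                runs_along_cols(shear_matrix(G, +1L)),
                runs_along_cols(shear_matrix(G, -1L)))
  if (nrow(runs) == 0L) return(matrix(0, n_levels, 1L))
  lmax <- max(runs[, "length"])
  idx <- (runs[, "level"] - 1L) * lmax + runs[, "length"]
  matrix(tabulate(idx, n_levels * lmax), n_levels, lmax, byrow = TRUE)
}

# gray-level size-zone counts; zones are 8-connected components per level
glszm_matrix <- function(G, n_levels) {
  sizes <- vector("list", n_levels)
  for (lev in seq_len(n_levels)) {
    lab <- label_components8(G == lev)
    if (lab$n > 0L) sizes[[lev]] <- lab$areas
  }
  smax <- max(1L, unlist(sizes, use.names = FALSE))
  P <- matrix(0, n_levels, smax)
  for (lev in seq_len(n_levels)) {
    s <- sizes[[lev]]
    if (length(s)) P[lev, ] <- tabulate(s, smax)
  }
  P
}

# shared feature set for level x (run length | zone size) count matrices
rl_family_features <- function(P, n_pixels, names16) {
  out <- setNames(rep(NA_real_, 16L), names16)
  Nr <- sum(P)
  if (Nr <= 0) return(out)
  Ng <- nrow(P); L <- ncol(P)
  i <- seq_len(Ng); l <- seq_len(L)
  ri <- rowSums(P); rl <- colSums(P)
  p <- P / Nr
  mu_i <- sum((ri / Nr) * i)
  mu_l <- sum((rl / Nr) * l)
  vals <- c(
    sum(rl / l^2) / Nr,                       # short emphasis
    sum(rl * l^2) / Nr,                       # long emphasis
    sum(ri^2) / Nr,                           # gray level non-uniformity
    sum(ri^2) / Nr^2,                         # ... normalized
    sum(rl^2) / Nr,                           # run/zone non-uniformity
    sum(rl^2) / Nr^2,                         # ... normalized
    Nr / n_pixels,                            # run/zone percentage
    sum((ri / Nr) * (i - mu_i)^2),            # gray level variance
    sum((rl / Nr) * (l - mu_l)^2),            # run/zone variance
    entropy_bits(as.vector(p)),               # entropy
    sum(ri / i^2) / Nr,                       # low gray level
    sum(ri * i^2) / Nr,                       # high gray level
    sum(sweep(P, 1L, i^2, "/") %*% (1 / l^2)) / Nr,
    sum(sweep(P, 1L, i^2, "*") %*% (1 / l^2)) / Nr,
    sum(sweep(P, 1L, i^2, "/") %*% (l^2)) / Nr,
    sum(sweep(P, 1L, i^2, "*") %*% (l^2)) / Nr)
  setNames(vals, names16)
}

glrlm_features <- function(P, n_pixels) {
  rl_family_features(P, n_pixels, glrlm_feature_names())
}

glszm_features <- function(P, n_pixels) {
  rl_family_features(P, n_pixels, glszm_feature_names())
}

## ---- GLDM -----------------------------------------------------------------

# Chebyshev offsets of radius delta, excluding the centre
chebyshev_offsets <- function(delta) {
  o <- expand.grid(dr = -delta:delta, dc = -delta:delta)
  as.matrix(o[!(o$dr == 0L & o$dc == 0L), , drop = FALSE])
}

#' Build a gray-level dependence matrix
#'
#' `P[i, j]` counts masked pixels of gray level `i` with `j - 1`
#' dependent neighbours, where a neighbour within Chebyshev radius
#' `delta` is dependent when its level differs by at most `alpha`.
#' The `j = count + 1` indexing puts an isolated in-mask pixel in the
#' first dependence column, so a single-pixel region yields the one-zone
#' matrix `P[1, 1] = 1`.
#'
#' @param G integer level matrix (0 outside the mask), as produced by
#'   [discretize_gray()].
#' @param n_levels number of gray levels.
#' @param alpha similarity tolerance in gray levels (default 0).
#' @param delta neighbourhood Chebyshev radius (default 1).
#' @return a matrix of dependence counts with `n_levels` rows.
#' @export
gldm_matrix <- function(G, n_levels, alpha = 0L, delta = 1L) {
  offs <- chebyshev_offsets(delta)
  dep <- matrix(0L, nrow(G), ncol(G))
  for (k in seq_len(nrow(offs))) {
    S <- shift_matrix(G, offs[k, 1], offs[k, 2])
    dep <- dep + (G > 0L & S > 0L & abs(G - S) <= alpha)
  }
  ok <- G > 0L
  nd <- max(dep[ok]) + 1L
  idx <- (G[ok] - 1L) * nd + dep[ok] + 1L
  matrix(tabulate(idx, n_levels * nd), n_levels, nd, byrow = TRUE)
}

#' Gray-level dependence matrix features
#'
#' The 14 GLDM features. In particular, with `p = P / N_z`:
#' small dependence emphasis `SDE = (1/N_z) sum P(i,j)/j^2`, dependence
#' non-uniformity `DNU = (1/N_z) sum_j (sum_i P(i,j))^2`, large
#' dependence high gray level emphasis
#' `LDHGLE = (1/N_z) sum P(i,j) i^2 j^2`, and dependence entropy
#' `DE = -sum p log2 p`.
#'
#' @param P dependence count matrix from [gldm_matrix()].
#' @return named numeric vector of the 14 GLDM features (all `NA` when
#'   the matrix is empty).
#' @export
gldm_features <- function(P) {
  out <- setNames(rep(NA_real_, 14L), gldm_feature_names())
  Nz <- sum(P)
  if (Nz <= 0) return(out)
  Ng <- nrow(P); Nd <- ncol(P)
  i <- seq_len(Ng); j <- seq_len(Nd)
  pi_ <- rowSums(P); pj <- colSums(P)
  p <- P / Nz
  mu_i <- sum((pi_ / Nz) * i)
  mu_j <- sum((pj / Nz) * j)
  out["GLDM_SmallDependenceEmphasis"] <- sum(pj / j^2) / Nz
  out["GLDM_LargeDependenceEmphasis"] <- sum(pj * j^2) / Nz
  out["GLDM_GrayLevelNonUniformity"] <- sum(pi_^2) / Nz
  out["GLDM_DependenceNonUniformity"] <- sum(pj^2) / Nz
  out["GLDM_DependenceNonUniformityNormalized"] <- sum(pj^2) / Nz^2
  out["GLDM_GrayLevelVariance"] <- sum((pi_ / Nz) * (i - mu_i)^2)
  out["GLDM_DependenceVariance"] <- sum((pj / Nz) * (j - mu_j)^2)
  out["GLDM_DependenceEntropy"] <- entropy_bits(as.vector(p))
  out["GLDM_LowGrayLevelEmphasis"] <- sum(pi_ / i^2) / Nz
  out["GLDM_HighGrayLevelEmphasis"] <- sum(pi_ * i^2) / Nz
  out["GLDM_SmallDependenceLowGrayLevelEmphasis"] <-
    sum(sweep(P, 1L, i^2, "/") %*% (1 / j^2)) / Nz
  out["GLDM_SmallDependenceHighGrayLevelEmphasis"] <-
    sum(sweep(P, 1L, i^2, "*") %*% (1 / j^2)) / Nz
  out["GLDM_LargeDependenceLowGrayLevelEmphasis"] <-
    sum(sweep(P, 1L, i^2, "/") %*% (j^2)) / Nz
  out["GLDM_LargeDependenceHighGrayLevelEmphasis"] <-
    sum(sweep(P, 1L, i^2, "*") %*% (j^2)) / Nz
  out
}

## ---- NGTDM ----------------------------------------------------------------

ngtdm_features <- function(G, n_levels) {
  out <- setNames(rep(NA_real_, 5L), ngtdm_feature_names())
  mask <- G > 0L
  np <- sum(mask)
  if (np < 2L) return(out)
  nb_sum <- matrix(0, nrow(G), ncol(G))
  nb_cnt <- matrix(0L, nrow(G), ncol(G))
  offs <- chebyshev_offsets(1L)
  for (k in seq_len(nrow(offs))) {
    S <- shift_matrix(G, offs[k, 1], offs[k, 2])
    nb_sum <- nb_sum + ifelse(S > 0L, S, 0)
    nb_cnt <- nb_cnt + (S > 0L)
  }
  valid <- mask & nb_cnt > 0L
  npv <- sum(valid)
  if (npv == 0L) return(out)
  A <- nb_sum[valid] / nb_cnt[valid]
  g <- G[valid]
  n_i <- tabulate(g, n_levels)
  s_i <- vapply(seq_len(n_levels), function(lev)
    sum(abs(g[g == lev] - A[g == lev])), numeric(1))
  p_i <- n_i / npv
  present <- which(n_i > 0L)
  ngp <- length(present)
  ii <- present
  out["NGTDM_Coarseness"] <- {
    d <- sum(p_i * s_i); if (d > 0) 1 / d else 1e6
  }
  out["NGTDM_Contrast"] <- if (ngp > 1L) {
    sum(outer(p_i[ii], p_i[ii]) * outer(ii, ii, "-")^2) /
      (ngp * (ngp - 1)) * sum(s_i) / npv
  } else 0
  den <- sum(abs(outer(ii * p_i[ii], ii * p_i[ii], "-")))
  out["NGTDM_Busyness"] <- if (den > 0) sum(p_i * s_i) / den else 0
  pi_m <- outer(p_i[ii], p_i[ii], "+")
  psi <- outer(p_i[ii] * s_i[ii], p_i[ii] * s_i[ii], "+")
  out["NGTDM_Complexity"] <-
    sum(abs(outer(ii, ii, "-")) * psi / pi_m) / npv
  st <- sum(s_i)
  out["NGTDM_Strength"] <-
    if (st > 0) sum(pi_m * outer(ii, ii, "-")^2) / st else 0
  out
}

## ---- first order ----------------------------------------------------------

firstorder_features <- function(v, n_levels = 32L) {
  out <- setNames(rep(NA_real_, 18L), firstorder_feature_names())
  n <- length(v)
  if (n < 1L) return(out)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  qs <- quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE, type = 7)
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    b <- pmin(n_levels, floor((v - lo) / ((hi - lo) / n_levels)) + 1L)
  } else b <- rep(1L, n)
  pb <- tabulate(b, n_levels) / n
  rob <- v[v >= qs[1] & v <= qs[5]]
  out["FirstOrder_Energy"] <- sum(v^2)
  out["FirstOrder_Entropy"] <- entropy_bits(pb)
  out["FirstOrder_Minimum"] <- lo
  out["FirstOrder_Percentile10"] <- qs[1]
  out["FirstOrder_Percentile90"] <- qs[5]
  out["FirstOrder_Maximum"] <- hi
  out["FirstOrder_Mean"] <- m
  out["FirstOrder_Median"] <- qs[3]
  out["FirstOrder_InterquartileRange"] <- qs[4] - qs[2]
  out["FirstOrder_Range"] <- hi - lo
  out["FirstOrder_MeanAbsoluteDeviation"] <- mean(abs(v - m))
  out["FirstOrder_RobustMeanAbsoluteDeviation"] <-
    if (length(rob)) mean(abs(rob - mean(rob))) else NA_real_
  out["FirstOrder_RootMeanSquared"] <- sqrt(mean(v^2))
  out["FirstOrder_Skewness"] <- skewness(v)
  out["FirstOrder_Kurtosis"] <- kurtosis(v)
  out["FirstOrder_Variance"] <- m2
  out["FirstOrder_Uniformity"] <- sum(pb^2)
  out["FirstOrder_StandardDeviation"] <- sqrt(m2)
  out
}

## ---- assembled texture block ----------------------------------------------

#' Extract the 93-feature texture block over a masked region
#'
#' Computes 18 first-order statistics plus GLCM (24), GLRLM (16),
#' GLSZM (16), GLDM (14) and NGTDM (5) features on the masked pixels of
#' a grayscale image, after equal-width discretization into `n_levels`
#' gray levels. Features undefined on the region (e.g. GLCM correlation
#' of a constant patch) are returned as `NA` sentinels rather than 0.
#'
#' @param gray numeric matrix (any real scale; wavelet sub-bands allowed).
#' @param mask logical matrix, same extent; `TRUE` = inside the region.
#' @param n_levels gray levels for discretization (default 32).
#' @param alpha GLDM similarity tolerance in gray levels (default 0).
#' @param delta GLDM neighbourhood Chebyshev radius (default 1).
#' @return named numeric vector of length 93, in registry order. A mask
#'   with fewer than 2 pixels yields an all-`NA` sentinel vector.
#' @export
extract_texture <- function(gray, mask, n_levels = 32L, alpha = 0L,
                            delta = 1L) {
  nm <- texture_feature_names()
  if (sum(mask) < 2L) return(setNames(rep(NA_real_, length(nm)), nm))
  G <- discretize_gray(gray, mask, n_levels)
  np <- sum(mask)
  c(firstorder_features(gray[mask], n_levels),
    glcm_features(glcm_matrix(G, n_levels)),
    glrlm_features(glrlm_matrix(G, n_levels), np),
    glszm_features(glszm_matrix(G, n_levels), np),
    gldm_features(gldm_matrix(G, n_levels, alpha, delta)),
    ngtdm_features(G, n_levels))
}
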