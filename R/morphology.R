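# Nuclear morphology and Fourier shape descriptors, averaged over nuclei.
#
# Shape statistics come from pixel counts, second-order moments of the
# pixel coordinates (major/minor axis, eccentricity) and the object
# boundary (EBImage::ocontour). Perimeter is measured on the boundary
# resampled to 64 equally spaced arclength points, which low-passes the
# rasterization staircase so a digital circle's circularity is close
# to 1. The 6 Fourier shape descriptors are band energies of the FFT of
# the resampled centroid-distance signal, normalized by total non-DC
# power.

FSD_SAMPLES <- 64L
FSD_BANDS <- 6L

# resample a closed contour (n x 2 of x, y) to m equally spaced
# arclength positions
resample_contour <- function(xy, m = FSD_SAMPLES) {
  xy <- rbind(xy, xy[1L, , drop = FALSE])
  seglen <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  if (total <= 0) return(matrix(xy[1L, ], m, 2L, byrow = TRUE))
  t_out <- seq(0, total, length.out = m + 1L)[seq_len(m)]
  cbind(approx(s, xy[, 1], t_out, ties = "ordered")$y,
        approx(s, xy[, 2], t_out, ties = "ordered")$y)
}

# band energies of the centroid-distance signal of one resampled contour
fsd_bands <- function(rc) {
  cx <- mean(rc[, 1]); cy <- mean(rc[, 2])
  r <- sqrt((rc[, 1] - cx)^2 + (rc[, 2] - cy)^2)
  f <- fft(r)
  m <- length(r)
  power <- Mod(f[2:(m / 2 + 1L)])^2  # frequencies 1 .. m/2
  nb <- FSD_BANDS
  per <- 5L  # frequencies 1..30 in 6 bands of 5
  bands <- vapply(seq_len(nb), function(b)
    sum(power[((b - 1L) * per + 1L):(b * per)]), numeric(1))
  tot <- sum(power)
  if (tot > 0) bands / tot else rep(0, nb)
}

#' Extract the 16 nuclear morphology and Fourier shape features
#'
#' Per-nucleus measurements (area, perimeter, major/minor axis length,
#' eccentricity, solidity, extent, circularity `4 pi A / P^2`,
#' equivalent diameter, aspect ratio) and 6 Fourier shape descriptor
#' band energies, averaged over all nuclei in the label map.
#'
#' @param label_map a `nuclei_labels` object.
#' @return named numeric vector of length 16 in registry order; an empty
#'   label map yields the all-`NA` sentinel vector.
#' @export
extract_morphology <- function(label_map) {
  nm <- morphology_feature_names()
  out <- setNames(rep(NA_real_, length(nm)), nm)
  n <- label_map$n_nuclei
  if (n < 1L) return(out)
  labels <- label_map$labels
  contours <- EBImage::ocontour(EBImage::Image(labels))
  idx <- which(labels > 0L, arr.ind = TRUE)
  lv <- labels[labels > 0L]
  rows_by <- split(idx[, 1], lv)
  cols_by <- split(idx[, 2], lv)
  per_nucleus <- matrix(NA_real_, n, 10L + FSD_BANDS)
  for (k in seq_len(n)) {
    rr <- rows_by[[k]]; cc <- cols_by[[k]]
    area <- length(rr)
    # second-order central moments of the pixel coordinates
    mr <- mean(rr); mc <- mean(cc)
    # + 1/12 per axis: variance of a unit pixel treated as a square
    crr <- mean((rr - mr)^2) + 1 / 12
    ccc <- mean((cc - mc)^2) + 1 / 12
    crc <- mean((rr - mr) * (cc - mc))
    tr <- crr + ccc
    dt <- sqrt(max(0, (crr - ccc)^2 + 4 * crc^2))
    l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
    major <- 4 * sqrt(max(l1, 0)); minor <- 4 * sqrt(max(l2, 0))
    ecc <- if (l1 > 0) sqrt(max(0, 1 - l2 / l1)) else 0
    ct <- contours[[k]]
    rc <- resample_contour(ct)
    per <- polygon_perimeter(rc[, 1], rc[, 2])
    hull <- chull(ct[, 1], ct[, 2])
    hull_area <- polygon_area(ct[hull, 1], ct[hull, 2]) +
      polygon_perimeter(ct[hull, 1], ct[hull, 2]) / 2 + 1
    bbox_area <- (diff(range(rr)) + 1) * (diff(range(cc)) + 1)
    per_nucleus[k, ] <- c(
      area, per, major, minor, ecc,
      min(1, area / hull_area),
      area / bbox_area,
      if (per > 0) 4 * pi * area / per^2 else NA_real_,
      sqrt(4 * area / pi),
      if (minor > 0) major / minor else NA_real_,
      fsd_bands(rc))
  }
  setNames(colMeans(per_nucleus, na.rm = TRUE), nm)
}
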