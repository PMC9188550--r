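# Tile-level nuclei mask reconstruction. A pluggable segmenter maps each
# 256 x 256 RGB patch to a probability map; overlapping patch maps are
# merged by per-pixel averaging, thresholded at 0.5 (strict >), and
# components under 50 pixels are removed. Components use 8-connectivity.

#' Split a tile into overlapping square patches
#'
#' Patches of `patch_size` pixels are laid on a stride-`stride` grid; the
#' published protocol uses 256-pixel patches with 128 pixels of overlap
#' on 768-pixel tiles, giving 25 patches with origins at
#' `{0,128,256,384,512}` on each axis.
#'
#' @param tile H x W x 3 array or H x W matrix.
#' @param patch_size patch side length in pixels (default 256).
#' @param stride grid stride in pixels (default 128).
#' @return list of patches, each `list(origin = c(row, col), image = ...)`
#'   with 0-based origins.
#' @export
patchify <- function(tile, patch_size = 256L, stride = 128L) {
  d <- dim(tile)
  h <- d[1]; w <- d[2]
  if (h < patch_size || w < patch_size)
    stop("tile (", h, "x", w, ") is smaller than the patch size ", patch_size)
  if ((h - patch_size) %% stride != 0L || (w - patch_size) %% stride != 0L)
    stop("tile dimensions must equal patch_size + k * stride")
  origins_r <- seq(0L, h - patch_size, by = stride)
  origins_c <- seq(0L, w - patch_size, by = stride)
  out <- vector("list", length(origins_r) * length(origins_c))
  k <- 1L
  for (r0 in origins_r) for (c0 in origins_c) {
    img <- if (length(d) == 3L)
      tile[r0 + seq_len(patch_size), c0 + seq_len(patch_size), , drop = FALSE]
    else tile[r0 + seq_len(patch_size), c0 + seq_len(patch_size)]
    out[[k]] <- list(origin = c(r0, c0), image = img)
    k <- k + 1L
  }
  out
}

#' Merge overlapping patch probability maps by per-pixel averaging
#'
#' Every tile pixel's value is the arithmetic mean of all patch
#' probability values covering it.
#'
#' @param patches list of `list(origin = c(row, col), prob = matrix)` with
#'   0-based origins.
#' @param tile_dim `c(height, width)` of the tile.
#' @return probability matrix of the tile extent.
#' @export
merge_probability_maps <- function(patches, tile_dim) {
  acc <- matrix(0, tile_dim[1], tile_dim[2])
  cnt <- matrix(0L, tile_dim[1], tile_dim[2])
  for (p in patches) {
    pr <- p$prob
    if (any(pr < 0 | pr > 1)) stop("probability values must lie in [0, 1]")
    r <- p$origin[1] + seq_len(nrow(pr))
    cc <- p$origin[2] + seq_len(ncol(pr))
    acc[r, cc] <- acc[r, cc] + pr
    cnt[r, cc] <- cnt[r, cc] + 1L
  }
  if (any(cnt == 0L)) stop("patch set does not cover the tile")
  acc / cnt
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is strictly greater than
#' the threshold; a pixel at exactly 0.5 is background.
#'
#' @param prob probability matrix with values in `[0, 1]`.
#' @param threshold scalar threshold (default 0.5).
#' @return logical matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (any(prob < 0 | prob > 1)) stop("probability values must lie in [0, 1]")
  prob > threshold
}

# 8-connected component labelling: EBImage's 4-connected flood fill plus a
# union-find merge of diagonally adjacent label pairs
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  n4 <- max(lab)
  if (n4 > 1L) {
    pairs <- NULL
    for (o in list(c(1L, 1L), c(1L, -1L))) {
      S <- shift_matrix(lab, o[1], o[2])
      ok <- lab > 0L & S > 0L & lab != S
      if (any(ok)) pairs <- rbind(pairs, cbind(lab[ok], S[ok]))
    }
    if (!is.null(pairs)) {
      parent <- seq_len(n4)
      find <- function(a) {
        while (parent[a] != a) {
          parent[a] <<- parent[parent[a]]
          a <- parent[a]
        }
        a
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(n4), find, integer(1))
      remap <- match(root, sort(unique(root)))
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  n <- max(lab, 0L)
  list(labels = lab, n = n,
       areas = if (n > 0L) tabulate(lab[lab > 0L], n) else integer(0))
}

#' Remove small objects and build a nuclei label map
#'
#' Labels the 8-connected components of a binary nuclei mask, eliminates
#' components with fewer than `min_area` pixels (strict: a 49-pixel blob
#' is removed at the default, a 50-pixel blob kept), and relabels the
#' survivors `1..K` with centroids and pixel areas.
#'
#' @param mask logical (or 0/1) matrix.
#' @param min_area minimum surviving component area in pixels (default 50).
#' @return an object of class `nuclei_labels`: list with `labels`
#'   (integer matrix, 0 = background), `n_nuclei`, `centroids` (n x 2
#'   matrix of row/col pixel-coordinate means) and `areas`.
#' @export
remove_small_objects <- function(mask, min_area = 50L) {
  mask <- mask > 0
  lab0 <- label_components8(mask)
  keep <- which(lab0$areas >= min_area)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  n <- length(keep)
  if (n > 0L) {
    remap <- integer(lab0$n)
    remap[keep] <- seq_len(n)
    pos <- lab0$labels > 0L
    mapped <- remap[lab0$labels[pos]]
    labels[pos] <- mapped
  }
  idx <- which(labels > 0L, arr.ind = TRUE)
  l <- labels[labels > 0L]
  if (n > 0L) {
    centroids <- cbind(row = as.vector(tapply(idx[, 1], l, mean)),
                       col = as.vector(tapply(idx[, 2], l, mean)))
    areas <- tabulate(l, n)
  } else {
    centroids <- matrix(numeric(0), 0L, 2L,
                        dimnames = list(NULL, c("row", "col")))
    areas <- integer(0)
  }
  structure(list(labels = labels, n_nuclei = n, centroids = centroids,
                 areas = areas),
            class = "nuclei_labels")
}

#' @export
print.nuclei_labels <- function(x, ...) {
  cat("nuclei label map:", x$n_nuclei, "nuclei on a", nrow(x$labels), "x",
      ncol(x$labels), "grid\n")
  invisible(x)
}

#' Classical baseline nuclei segmenter
#'
#' Deterministic stand-in satisfying the segmenter contract (RGB patch in,
#' probability map of the same extent out): luminance grayscale, Gaussian
#' smoothing, Otsu threshold on the inverted intensity (nuclei are darker
#' than stroma), then a distance-transform-scaled soft map: background 0,
#' foreground `0.5 + 0.5 * d / max(d)`. Touching nuclei are not split, so
#' merged instances are possible; acceptable for the tile-level feature
#' contract.
#'
#' @param patch H x W x 3 RGB array (0--255) or grayscale matrix.
#' @param sigma Gaussian smoothing radius in pixels (default 2).
#' @return probability matrix in `[0, 1]` of the patch extent.
#' @export
baseline_segmenter <- function(patch, sigma = 2) {
  gray <- rgb_to_gray(patch) / 255
  sm <- EBImage::gblur(gray, sigma = sigma)
  inv <- 1 - sm
  rng <- range(inv)
  if (diff(rng) < 1e-8) return(matrix(0, nrow(gray), ncol(gray)))
  th <- EBImage::otsu(EBImage::Image(inv), range = rng)
  fg <- inv > th
  if (!any(fg)) return(matrix(0, nrow(gray), ncol(gray)))
  d <- EBImage::distmap(EBImage::Image(fg * 1))
  d <- matrix(as.numeric(d), nrow(gray), ncol(gray))
  out <- matrix(0, nrow(gray), ncol(gray))
  out[fg] <- 0.5 + 0.5 * d[fg] / max(d)
  out
}

#' Segment a tile into a nuclei label map
#'
#' Full published post-processing around a pluggable segmenter: the tile
#' is split into overlapping patches, the segmenter's probability maps
#' are merged by averaging, thresholded (strict `> threshold`), and
#' components under `min_area` pixels removed.
#'
#' @param tile H x W x 3 RGB array (0--255).
#' @param segmenter function: patch -> probability matrix of equal extent.
#' @param threshold binarization threshold (default 0.5).
#' @param min_area minimum nucleus area in pixels (default 50).
#' @param patch_size,stride patch grid geometry (defaults 256 / 128).
#' @return a `nuclei_labels` object (see [remove_small_objects()]).
#' @export
segment_tile <- function(tile, segmenter = baseline_segmenter,
                         threshold = 0.5, min_area = 50L,
                         patch_size = 256L, stride = 128L) {
  patches <- patchify(tile, patch_size, stride)
  maps <- lapply(patches, function(p) {
    pr <- segmenter(p$image)
    if (!all(dim(pr) == dim(p$image)[1:2]))
      stop("segmenter output extent does not match its input patch")
    list(origin = p$origin, prob = pr)
  })
  prob <- merge_probability_maps(maps, dim(tile)[1:2])
  remove_small_objects(binarize(prob, threshold), min_area)
}

#' Dice similarity coefficient between two binary masks
#'
#' @param a,b logical matrices of equal extent.
#' @return `2|A n B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0; b <- b > 0
  s <- sum(a) + sum(b)
  if (s == 0L) return(1)
  2 * sum(a & b) / s
}
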