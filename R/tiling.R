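# Tumor-region tiling: non-overlapping 768 x 768 windows on a fixed grid
# anchored at the annotation bounding box, retained when they contain
# more than 50% tumor tissue and less than 10% white background (both
# thresholds strict). Coordinates are 0-based, row-major, with half-open
# windows [row, row + size) x [col, col + size).

#' Construct a slide region
#'
#' @param image H x W x 3 RGB array (0--255).
#' @param tumor_mask H x W logical (or 0/1) matrix derived from the
#'   tumor annotation.
#' @param id region identifier used in tile names.
#' @return an object of class `slide_region`.
#' @export
slide_region <- function(image, tumor_mask, id = "region") {
  stopifnot(length(dim(image)) == 3L,
            all(dim(image)[1:2] == dim(tumor_mask)))
  structure(list(image = image, tumor_mask = tumor_mask > 0, id = id),
            class = "slide_region")
}

#' Tumor fraction of a tile window
#'
#' @param tumor_mask logical region mask.
#' @param origin `c(row, col)` 0-based window origin.
#' @param size window side length (default 768).
#' @return number of tumor pixels in the window divided by `size^2`.
#' @export
tumor_fraction <- function(tumor_mask, origin, size = 768L) {
  r <- origin[1] + seq_len(size); cc <- origin[2] + seq_len(size)
  stopifnot(max(r) <= nrow(tumor_mask), max(cc) <= ncol(tumor_mask),
            min(r) >= 1L, min(cc) >= 1L)
  mean(tumor_mask[r, cc] > 0)
}

#' White-background fraction of a tile image
#'
#' A pixel is background iff all three channels are at least
#' `white_level` (default 220 on the 0--255 scale).
#'
#' @param tile_image H x W x 3 RGB array (0--255).
#' @param white_level per-channel white threshold (default 220).
#' @return fraction of white-background pixels.
#' @export
background_fraction <- function(tile_image, white_level = 220) {
  white <- tile_image[, , 1] >= white_level &
    tile_image[, , 2] >= white_level & tile_image[, , 3] >= white_level
  mean(white)
}

#' Lay the tile grid over an annotated region and flag retained tiles
#'
#' Tiles of `size` pixels are laid with stride `size` on a grid anchored
#' at the top-left of the tumor-mask bounding box, extending to cover
#' the box. Windows that would exceed the image are shifted inward so
#' tiles always contain real tissue ("tumor margins") rather than
#' padding; exact duplicate windows after shifting are dropped. A tile
#' is retained iff `tumor_fraction > tumor_threshold` and
#' `background_fraction < background_threshold` (strict, so a tile at
#' exactly 50% tumor or 10% background is rejected).
#'
#' @param region a `slide_region`.
#' @param size tile side length (default 768).
#' @param tumor_threshold minimum tumor fraction, exclusive (default 0.5).
#' @param background_threshold maximum white fraction, exclusive
#'   (default 0.1).
#' @param white_level per-channel white threshold (default 220).
#' @return data.frame with columns `slide`, `row`, `col` (0-based
#'   origins), `tumor_fraction`, `background_fraction`, `retained`.
#' @export
tile_grid <- function(region, size = 768L, tumor_threshold = 0.5,
                      background_threshold = 0.1, white_level = 220) {
  stopifnot(inherits(region, "slide_region"))
  h <- nrow(region$tumor_mask); w <- ncol(region$tumor_mask)
  if (h < size || w < size)
    stop("region (", h, "x", w, ") smaller than one ", size, "-pixel tile")
  if (!any(region$tumor_mask)) stop("tumor mask is empty")
  idx <- which(region$tumor_mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]) - 1L; c0 <- min(idx[, 2]) - 1L  # 0-based anchor
  r1 <- max(idx[, 1]); c1 <- max(idx[, 2])            # 1-based box end
  nr <- ceiling((r1 - r0) / size); nc <- ceiling((c1 - c0) / size)
  origins <- expand.grid(
    row = r0 + (seq_len(nr) - 1L) * size,
    col = c0 + (seq_len(nc) - 1L) * size)
  # shift windows at the image border inward onto surrounding tissue
  origins$row <- pmin(origins$row, h - size)
  origins$col <- pmin(origins$col, w - size)
  origins <- unique(origins)
  tf <- mapply(function(r, cc) tumor_fraction(region$tumor_mask, c(r, cc),
                                              size),
               origins$row, origins$col)
  bf <- mapply(function(r, cc) {
    win <- region$image[r + seq_len(size), cc + seq_len(size), ,
                        drop = FALSE]
    background_fraction(win, white_level)
  }, origins$row, origins$col)
  data.frame(slide = region$id, row = origins$row, col = origins$col,
             tumor_fraction = tf, background_fraction = bf,
             retained = tf > tumor_threshold & bf < background_threshold,
             stringsAsFactors = FALSE)
}

#' Extract one tile image from a region
#'
#' @param region a `slide_region`.
#' @param origin `c(row, col)` 0-based tile origin.
#' @param size tile side length (default 768).
#' @return `size` x `size` x 3 array.
#' @export
extract_tile_image <- function(region, origin, size = 768L) {
  region$image[origin[1] + seq_len(size), origin[2] + seq_len(size), ,
               drop = FALSE]
}
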