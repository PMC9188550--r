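# Plain-format I/O: 8-bit PNG tiles, 0/255 mask PNGs, probability-map
# PNGs (8- or 16-bit, scaled to [0, 1] on read), CSV manifests.

#' Write an RGB tile as PNG
#'
#' @param img H x W x 3 array on the 0--255 scale.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tile_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read an RGB tile PNG onto the 0--255 scale
#'
#' @param path PNG path.
#' @return H x W x 3 numeric array (0--255).
#' @export
read_tile_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  round(img * 255)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read a mask or probability-map PNG scaled to `[0, 1]`
#'
#' 8- and 16-bit grayscale PNGs are both returned on the unit scale
#' (png stores either as fractions of full scale).
#'
#' @param path PNG path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_probability_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' Write a cohort's tiles, masks and clinical table to a directory
#'
#' Tiles are written as `tiles/<patient>_<k>.png`, ground-truth masks as
#' `masks/<patient>_<k>.png` (0/255), and the clinical table (with the
#' split assignment when given) as `cohort.csv`.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @param split optional factor from [split_cohort()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, split = NULL) {
  dir.create(file.path(dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$tiles)) {
    for (k in seq_along(cohort$tiles[[pid]])) {
      tl <- cohort$tiles[[pid]][[k]]
      write_tile_png(tl$image, file.path(dir, "tiles",
                                         sprintf("%s_%d.png", pid, k)))
      write_mask_png(tl$true_mask, file.path(dir, "masks",
                                             sprintf("%s_%d.png", pid, k)))
    }
  }
  tab <- cohort$clinical
  tab$split <- if (is.null(split)) NA else as.character(split)
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
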