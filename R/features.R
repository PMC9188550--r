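# Tile-level feature extraction across all five families and
# nuclei-count-weighted aggregation to patient vectors.

#' Extract the full 549-feature pathomic vector for one tile
#'
#' Runs all five feature families on a (tile, nuclei label map) pair:
#' morphology/FSD and graph features from the label map, intensity,
#' texture and wavelet features from the grayscale tile restricted to
#' the union nuclei mask. Features undefined on a degenerate tile are
#' `NA` sentinels and are skipped (not zeroed) during patient
#' aggregation.
#'
#' @param tile H x W x 3 RGB array (0--255) or grayscale matrix.
#' @param label_map a `nuclei_labels` object for the tile.
#' @param n_levels,alpha,delta texture discretization and GLDM
#'   parameters (defaults 32, 0, 1).
#' @return named numeric vector of length 549 in registry order, with
#'   attribute `weight` = number of nuclei in the tile.
#' @export
extract_tile_features <- function(tile, label_map, n_levels = 32L,
                                  alpha = 0L, delta = 1L) {
  gray <- rgb_to_gray(tile)
  mask <- label_map$labels > 0L
  v <- c(extract_morphology(label_map),
         extract_intensity_gradient(gray, label_map),
         extract_texture(gray, mask, n_levels, alpha, delta),
         extract_graph(label_map),
         extract_wavelet(gray, mask, n_levels, alpha, delta))
  stopifnot(identical(names(v), feature_registry()$name))
  attr(v, "weight") <- label_map$n_nuclei
  v
}

#' Build a tile-level feature table
#'
#' @param features list of vectors from [extract_tile_features()].
#' @param tile_ids character vector of tile identifiers.
#' @param patient_ids character vector of patient identifiers (one per
#'   tile).
#' @return data.frame with columns `patient_id`, `tile_id`, `n_nuclei`,
#'   then the 549 feature columns in registry order.
#' @export
tile_feature_table <- function(features, tile_ids, patient_ids) {
  stopifnot(length(features) == length(tile_ids),
            length(features) == length(patient_ids))
  mat <- do.call(rbind, features)
  data.frame(patient_id = patient_ids, tile_id = tile_ids,
             n_nuclei = vapply(features, function(f)
               as.numeric(attr(f, "weight")), numeric(1)),
             mat, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Aggregate tile feature vectors to patient vectors
#'
#' Patient value for feature f is the nuclei-count-weighted mean
#' `sum_t w_t x_tf / sum_t w_t` over the patient's tiles, with sentinel
#' (`NA`) tile values excluded from both sums per feature. Reduces to
#' the plain mean when all weights are equal and is invariant to
#' rescaling all weights by a common factor.
#'
#' @param tile_table data.frame from [tile_feature_table()].
#' @return data.frame with `patient_id` then the 549 feature columns.
#' @export
aggregate_patients <- function(tile_table) {
  feats <- feature_registry()$name
  stopifnot(all(feats %in% names(tile_table)))
  patients <- unique(tile_table$patient_id)
  out <- matrix(NA_real_, length(patients), length(feats),
                dimnames = list(NULL, feats))
  for (i in seq_along(patients)) {
    rows <- tile_table[tile_table$patient_id == patients[i], , drop = FALSE]
    w <- rows$n_nuclei
    if (all(w <= 0)) stop("all tile weights are zero for patient ",
                          patients[i])
    x <- as.matrix(rows[, feats, drop = FALSE])
    ok <- is.finite(x)
    wx <- x * w
    wx[!ok] <- 0
    wm <- matrix(w, nrow(x), ncol(x))
    wm[!ok] <- 0
    den <- colSums(wm)
    out[i, ] <- ifelse(den > 0, colSums(wx) / den, NA_real_)
  }
  data.frame(patient_id = patients, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}
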