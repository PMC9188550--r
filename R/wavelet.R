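# Single-level orthonormal 2-D Haar transform and the wavelet feature
# family: the 93-feature texture block computed on each of the four
# sub-bands (LL, LH, HL, HH), minus the designated degenerate registry
# entry Wavelet_LL_FirstOrder_Minimum, for 4 x 93 - 1 = 371 features.

#' Single-level 2-D orthonormal Haar transform
#'
#' For each 2 x 2 block `[[a, b], [c, d]]` (rows = a b over c d) the four
#' sub-band coefficients are `LL = (a+b+c+d)/2`, `LH = (a-b+c-d)/2`
#' (high-pass along columns), `HL = (a+b-c-d)/2` (high-pass along rows)
#' and `HH = (a-b-c+d)/2`. The transform is orthonormal, so the sum of
#' squared coefficients over the four bands equals the sum of squared
#' pixels (Parseval).
#'
#' @param x numeric matrix with even dimensions.
#' @return list of four `H/2 x W/2` matrices: `LL`, `LH`, `HL`, `HH`.
#' @export
haar_dwt2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  if (h %% 2L != 0L || w %% 2L != 0L)
    stop("Haar transform requires even image dimensions")
  ro <- seq(1L, h, by = 2L); re <- ro + 1L
  co <- seq(1L, w, by = 2L); ce <- co + 1L
  a <- x[ro, co, drop = FALSE]; b <- x[ro, ce, drop = FALSE]
  cc <- x[re, co, drop = FALSE]; d <- x[re, ce, drop = FALSE]
  list(LL = (a + b + cc + d) / 2,
       LH = (a - b + cc - d) / 2,
       HL = (a + b - cc - d) / 2,
       HH = (a - b - cc + d) / 2)
}

# sub-band mask alignment: a half-resolution cell is inside the region
# when any pixel of its 2 x 2 block is
downsample_mask2 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  ro <- seq(1L, h, by = 2L); re <- ro + 1L
  co <- seq(1L, w, by = 2L); ce <- co + 1L
  mask[ro, co, drop = FALSE] | mask[ro, ce, drop = FALSE] |
    mask[re, co, drop = FALSE] | mask[re, ce, drop = FALSE]
}

#' Extract the 371 wavelet sub-band texture features
#'
#' Applies a single-level orthonormal Haar transform to the grayscale
#' tile, coarsens the nuclei mask to sub-band resolution (a coefficient
#' is inside the region when any pixel of its 2 x 2 block is), and
#' computes the 93-feature texture block on each of the four sub-bands.
#' The degenerate entry `Wavelet_LL_FirstOrder_Minimum` is dropped from
#' the registry, for 371 features.
#'
#' @inheritParams extract_texture
#' @return named numeric vector of length 371 in registry order; an
#'   empty mask yields the all-`NA` sentinel vector.
#' @export
extract_wavelet <- function(gray, mask, n_levels = 32L, alpha = 0L,
                            delta = 1L) {
  nm <- wavelet_feature_names()
  if (sum(mask) < 1L) return(setNames(rep(NA_real_, length(nm)), nm))
  bands <- haar_dwt2(gray)
  mask2 <- downsample_mask2(mask)
  out <- unlist(lapply(names(bands), function(b) {
    v <- extract_texture(bands[[b]], mask2, n_levels, alpha, delta)
    setNames(v, paste0("Wavelet_", b, "_", names(v)))
  }))
  out[nm]
}
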