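# Shared numeric helpers and deterministic RNG stream derivation.

#' Derive a child RNG seed from a root seed and stream indices
#'
#' Deterministic linear-congruential mix of a root seed with up to two
#' stream indices (e.g. patient and tile counters). Keeps every derived
#' seed in `[0, 2^31 - 2]` so it is always a valid R integer seed, and
#' guarantees that distinct `(root, i, j)` triples map to well-separated
#' streams without consuming the global RNG state.
#'
#' @param root integer root seed.
#' @param i,j non-negative integer stream indices.
#' @return a single integer seed.
#' @export
derive_seed <- function(root, i = 0L, j = 0L) {
  m <- 2147483647
  s <- (as.numeric(root) %% m) * 1664525 + as.numeric(i) * 22695477 +
    as.numeric(j) * 69069 + 12345
  as.integer(s %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a local seed without touching the caller's RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# sample skewness m3 / m2^1.5; NA when the variance is zero
skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (n < 1L || m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

# (non-excess) kurtosis m4 / m2^2; NA when the variance is zero
kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^4) / m2^2
}

# Shannon entropy (bits) of a histogram of x with `bins` equal-width bins
hist_entropy <- function(x, bins = 32L) {
  if (length(x) == 0L) return(NA_real_)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(0)
  b <- pmin(bins, floor((x - lo) / ((hi - lo) / bins)) + 1L)
  p <- tabulate(b, bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# entropy in bits of a probability vector (zeros dropped); the `+ 0`
# normalizes the signed zero of -sum() when a single outcome has p = 1
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(NA_real_)
  -sum(p * log2(p)) + 0
}

#' Convert an RGB image array to luminance grayscale
#'
#' Uses the Rec. 601 luminance weights 0.299 R + 0.587 G + 0.114 B.
#' Values keep the scale of the input (0--255 for 8-bit tiles).
#'
#' @param img an H x W x 3 numeric array, or an H x W matrix (returned
#'   unchanged).
#' @return an H x W numeric matrix.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  stopifnot(length(dim(img)) == 3L, dim(img)[3] >= 3L)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_matrix <- function(x, dr, dc, fill = 0L) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(fill, h, w)
  r1 <- max(1, 1 - dr):min(h, h - dr)
  c1 <- max(1, 1 - dc):min(w, w - dc)
  out[r1, c1] <- x[r1 + dr, c1 + dc]
  out
}

# polygon area (shoelace, absolute value) from vertex coordinates
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# closed polygon perimeter
polygon_perimeter <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(sqrt((x[j] - x)^2 + (y[j] - y)^2))
}
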