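# Small programmatic fixtures shared across test files.

# a tiny RGB tile with a given constant background and k dark squares
fixture_rgb <- function(h = 64L, w = 64L, value = c(200, 180, 190)) {
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- value[ch]
  img
}

# binary mask with one filled rectangle
fixture_rect_mask <- function(h, w, r1, r2, c1, c2) {
  m <- matrix(FALSE, h, w)
  m[r1:r2, c1:c2] <- TRUE
  m
}

# filled-disc label map (single nucleus) of radius r
fixture_disc_mask <- function(h, w, cy, cx, r) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

# filled ellipse (axis-aligned) mask
fixture_ellipse_mask <- function(h, w, cy, cx, ry, rx) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
}

# star-polygon mask: radius alternates between r_out and r_in with m spikes
fixture_star_mask <- function(h, w, cy, cx, r_out, r_in, m = 8L) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ang <- atan2(rr - cy, cc - cx)
  rad <- r_in + (r_out - r_in) * (cos(m * ang) + 1) / 2
  sqrt((rr - cy)^2 + (cc - cx)^2) <= rad
}

# random discretized level matrix with a random mask (level 0 = outside)
fixture_levels <- function(h, w, n_levels, p_mask = 0.8, seed = 1L) {
  withr::with_seed(seed, {
    G <- matrix(sample.int(n_levels, h * w, replace = TRUE), h, w)
    G[matrix(runif(h * w) > p_mask, h, w)] <- 0L
    G
  })
}

# patient feature table with one planted informative feature
fixture_model_table <- function(n = 60L, p = 12L, effect = 3, seed = 1L,
                                pcr_fraction = 1 / 3) {
  withr::with_seed(seed, {
    y <- rep("non-pCR", n)
    y[sample.int(n, round(n * pcr_fraction))] <- "pCR"
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- c("signal", paste0("noise", seq_len(p - 1L)))
    x[y == "pCR", "signal"] <- x[y == "pCR", "signal"] + effect
    list(x = x, y = y)
  })
}
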