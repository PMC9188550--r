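# Synthetic cohort generator. Tiles carry dark elliptical nuclei on a
# pink stroma, placed at triangular-lattice sites displaced by isotropic
# Gaussian jitter; the response classes differ by configurable shifts in
# placement jitter (nuclear spatial disorder) and intra-nucleus intensity
# noise (nuclear texture). Ground-truth masks and centroids make every
# downstream stage testable, and the clinical table follows the published
# cohort's per-class covariate marginals (149 patients, 34% pCR).

# per-class clinical covariate marginals (pooled train+test within class)
CLINICAL_MARGINALS <- list(
  pCR = list(age_mean = 49.0, age_sd = 10, pre_menopausal = 28 / 50,
             er_pos = 16 / 50, pr_pos = 14 / 50, her2_pos = 34 / 50,
             ductal = 50 / 50, grade_probs = c(1, 11, 38) / 50,
             inflammatory = 4 / 50, size_mean = 37.2, size_sd = 21.2),
  `non-pCR` = list(age_mean = 52.0, age_sd = 10, pre_menopausal = 51 / 99,
                   er_pos = 71 / 99, pr_pos = 59 / 99, her2_pos = 32 / 99,
                   ductal = 73 / 99, grade_probs = c(3, 54, 42) / 99,
                   inflammatory = 11 / 99, size_mean = 50.9, size_sd = 28.9))

# default palettes: H&E-like contrast only (dark blue-purple nuclei on
# pink-white stroma); absolute colors are configurable and immaterial
NUCLEUS_COLOR <- c(72, 48, 130)
STROMA_COLOR <- c(233, 208, 218)

#' Triangular-lattice sites inside a square tile
#'
#' Rows are spaced `spacing * sqrt(3)/2` apart with alternate rows offset
#' by `spacing / 2` (hexagonal packing).
#'
#' @param tile_size tile side length in pixels.
#' @param spacing lattice constant in pixels.
#' @param margin minimum distance from the tile border (default 20).
#' @return n x 2 matrix of (row, col) site coordinates.
#' @export
tri_lattice <- function(tile_size, spacing, margin = 20) {
  dy <- spacing * sqrt(3) / 2
  rows <- seq(margin, tile_size - margin, by = dy)
  sites <- NULL
  for (k in seq_along(rows)) {
    off <- if (k %% 2L == 0L) spacing / 2 else 0
    cols <- seq(margin + off, tile_size - margin, by = spacing)
    sites <- rbind(sites, cbind(row = rows[k], col = cols))
  }
  sites
}

# rasterize an ellipse; returns pixel indices (cbind(row, col)) inside
ellipse_pixels <- function(center, semi_a, semi_b, theta, tile_size) {
  rad <- ceiling(max(semi_a, semi_b)) + 1L
  rr <- max(1L, floor(center[1] - rad)):min(tile_size, ceiling(center[1] + rad))
  cc <- max(1L, floor(center[2] - rad)):min(tile_size, ceiling(center[2] + rad))
  dy <- outer(rr - center[1], rep(1, length(cc)))
  dx <- outer(rep(1, length(rr)), cc - center[2])
  u <- (dx * cos(theta) + dy * sin(theta)) / semi_a
  v <- (-dx * sin(theta) + dy * cos(theta)) / semi_b
  inside <- u^2 + v^2 <= 1
  cbind(row = rep(rr, length(cc))[inside],
        col = rep(cc, each = length(rr))[inside])
}

#' Generate one synthetic histology tile with ground truth
#'
#' Nuclei are filled ellipses (random orientation, axis lengths sampled
#' in `axis_range`) placed at triangular-lattice sites displaced by
#' isotropic Gaussian jitter of standard deviation `placement_jitter`.
#' A candidate that would touch an already placed nucleus (8-adjacency,
#' one-pixel separation) is re-sampled up to 50 times, then placed with
#' minimal axes at the undisplaced site; this keeps the connected
#' component count of the mask exactly equal to the number of centroids.
#' Nuclei render darker than the stroma with additive intra-nucleus
#' Gaussian noise of standard deviation `texture_noise`.
#'
#' @param n_nuclei number of nuclei to place.
#' @param placement_jitter jitter SD in pixels.
#' @param texture_noise intra-nucleus intensity noise SD (0--255 scale).
#' @param seed integer seed; output is a pure function of the arguments.
#' @param tile_size tile side length (default 768).
#' @param axis_range full axis length range in pixels (default 9--16,
#'   keeping every nucleus above the 50-pixel size filter).
#' @param spacing lattice constant; `NULL` (default) chooses the largest
#'   spacing whose capacity holds `n_nuclei`.
#' @return an object of class `synthetic_tile`: list with `image`
#'   (H x W x 3, 0--255), `true_mask` (logical), `centroids` (n x 2
#'   row/col), `placement_jitter`, `texture_noise`.
#' @export
generate_tile <- function(n_nuclei, placement_jitter, texture_noise, seed,
                          tile_size = 768L, axis_range = c(9, 16),
                          spacing = NULL) {
  stopifnot(n_nuclei >= 0L, placement_jitter >= 0, texture_noise >= 0,
            axis_range[1] >= 8)
  margin <- axis_range[2] / 2 + 4
  if (is.null(spacing)) {
    # largest lattice constant (>= non-touching minimum) that fits n
    spacing <- max(axis_range[2] + 4,
                   sqrt(2 * (tile_size - 2 * margin)^2 /
                          (sqrt(3) * max(n_nuclei, 1))))
    while (spacing > axis_range[2] + 4 &&
           nrow(tri_lattice(tile_size, spacing, margin)) < n_nuclei)
      spacing <- spacing * 0.97
  }
  sites <- tri_lattice(tile_size, spacing, margin)
  if (n_nuclei > nrow(sites))
    stop("cannot place ", n_nuclei, " nuclei: lattice capacity is ",
         nrow(sites), " at spacing ", round(spacing, 1))
  ts <- as.integer(tile_size)
  with_seed(seed, {
    take <- if (n_nuclei < nrow(sites))
      sort(sample.int(nrow(sites), n_nuclei)) else seq_len(nrow(sites))
    sites <- sites[take, , drop = FALSE]
    # linear-index pixel bookkeeping; `occupied` is the mask dilated by
    # one pixel, enforcing the 8-adjacency separation rule
    mask <- logical(ts * ts)
    occupied <- logical(ts * ts)
    centroids <- matrix(NA_real_, n_nuclei, 2L,
                        dimnames = list(NULL, c("row", "col")))
    pix_list <- vector("list", n_nuclei)
    for (k in seq_len(n_nuclei)) {
      placed <- FALSE
      for (attempt in seq_len(50L)) {
        ctr <- sites[k, ] + rnorm(2L, 0, placement_jitter)
        ctr <- pmin(pmax(ctr, margin), ts - margin)
        ax <- sort(runif(2L, axis_range[1], axis_range[2]),
                   decreasing = TRUE)
        th <- runif(1L, 0, pi)
        px <- ellipse_pixels(ctr, ax[1] / 2, ax[2] / 2, th, ts)
        lin <- (px[, 2] - 1L) * ts + px[, 1]
        if (!any(occupied[lin])) {
          placed <- TRUE
          break
        }
      }
      if (!placed) {  # minimal-axes fallback at the undisplaced site
        ctr <- sites[k, ]
        px <- ellipse_pixels(ctr, axis_range[1] / 2, axis_range[1] / 2, 0,
                             ts)
        lin <- (px[, 2] - 1L) * ts + px[, 1]
        if (any(occupied[lin]))
          stop("could not place nucleus ", k,
               " without touching an existing nucleus")
      }
      mask[lin] <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        pr <- pmin(pmax(px[, 1] + dr, 1L), ts)
        pc <- pmin(pmax(px[, 2] + dc, 1L), ts)
        occupied[(pc - 1L) * ts + pr] <- TRUE
      }
      centroids[k, ] <- ctr
      pix_list[[k]] <- lin
    }
    # render: pink-white stroma, dark blue-purple nuclei
    bg_noise <- rnorm(ts * ts, 0, 3)
    chans <- lapply(1:3, function(ch) STROMA_COLOR[ch] + bg_noise)
    for (k in seq_len(n_nuclei)) {
      lin <- pix_list[[k]]
      shade <- rnorm(1L, 0, 8)
      tex <- rnorm(length(lin), 0, texture_noise)
      for (ch in 1:3)
        chans[[ch]][lin] <- NUCLEUS_COLOR[ch] + shade + tex
    }
    img <- array(round(pmin(pmax(unlist(chans), 0), 255)),
                 dim = c(ts, ts, 3L))
    structure(list(image = img, true_mask = matrix(mask, ts, ts),
                   centroids = centroids,
                   placement_jitter = placement_jitter,
                   texture_noise = texture_noise),
              class = "synthetic_tile")
  })
}

#' @export
print.synthetic_tile <- function(x, ...) {
  cat("synthetic tile:", nrow(x$centroids), "nuclei,",
      nrow(x$true_mask), "x", ncol(x$true_mask),
      "px, jitter", x$placement_jitter, "px\n")
  invisible(x)
}

#' Specify a synthetic cohort
#'
#' Defaults emulate the published study conditions: 149 patients with a
#' 50/149 pCR fraction. `disorder_effect` shifts the nucleus-placement
#' jitter and `texture_effect` the intra-nucleus noise of pCR patients
#' relative to the non-pCR baseline (both zero by default, i.e. a null
#' cohort).
#'
#' @param n_patients cohort size (default 149).
#' @param pcr_fraction pCR prevalence in (0, 1) (default 50/149).
#' @param tiles_per_patient tiles simulated per patient (default 2).
#' @param nuclei_per_tile_range integer range of nuclei per tile
#'   (default 80--140).
#' @param disorder_effect jitter shift in pixels for pCR patients.
#' @param texture_effect intra-nucleus noise shift for pCR patients.
#' @param base_jitter baseline placement jitter SD in pixels (default 3).
#' @param base_texture_noise baseline noise SD (default 6).
#' @param patient_effect_sd SD of an optional per-patient random effect
#'   added to both jitter and noise (default 0).
#' @param tile_size tile side length (default 768).
#' @param seed root integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 149L, pcr_fraction = 50 / 149,
                        tiles_per_patient = 2L,
                        nuclei_per_tile_range = c(80L, 140L),
                        disorder_effect = 0, texture_effect = 0,
                        base_jitter = 3, base_texture_noise = 6,
                        patient_effect_sd = 0, tile_size = 768L,
                        seed = 1L) {
  stopifnot(n_patients >= 2L, pcr_fraction > 0, pcr_fraction < 1,
            round(n_patients * pcr_fraction) >= 1,
            tiles_per_patient >= 1L,
            nuclei_per_tile_range[1] <= nuclei_per_tile_range[2])
  structure(as.list(environment()), class = "cohort_spec")
}

# sample one clinical covariate profile from the per-class marginals
sample_clinical_profile <- function(label, seed) {
  m <- CLINICAL_MARGINALS[[label]]
  with_seed(seed, {
    data.frame(
      age = round(max(25, min(85, rnorm(1, m$age_mean, m$age_sd))), 1),
      menopausal = if (runif(1) < m$pre_menopausal) "pre" else "post",
      tumor_size_mm = round(max(5, rnorm(1, m$size_mean, m$size_sd)), 1),
      histology = if (runif(1) < m$ductal) "ductal" else "lobular",
      grade = sample.int(3L, 1L, prob = m$grade_probs),
      inflammatory = if (runif(1) < m$inflammatory) "yes" else "no",
      er = if (runif(1) < m$er_pos) "+" else "-",
      pr = if (runif(1) < m$pr_pos) "+" else "-",
      her2 = if (runif(1) < m$her2_pos) "+" else "-",
      stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic cohort
#'
#' Assigns exactly `round(n_patients * pcr_fraction)` pCR labels, samples
#' each patient's clinical profile from the per-class covariate
#' marginals, and simulates each patient's tiles with the class-shifted
#' jitter and texture noise. All randomness flows from the root seed
#' through per-patient/per-tile derived streams (see [derive_seed()]),
#' so identical specs give byte-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return list with `clinical` (data.frame: `patient_id`, covariates,
#'   `label`) and `tiles` (named list of per-patient `synthetic_tile`
#'   lists).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  n_pcr <- round(n * spec$pcr_fraction)
  perm <- with_seed(derive_seed(spec$seed, 0L, 1L), sample.int(n))
  labels <- rep("non-pCR", n)
  labels[perm[seq_len(n_pcr)]] <- "pCR"
  ids <- sprintf("P%03d", seq_len(n))
  clinical <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(patient_id = ids[i],
          sample_clinical_profile(labels[i], derive_seed(spec$seed, i, 0L)),
          label = labels[i], stringsAsFactors = FALSE)))
  tiles <- vector("list", n)
  names(tiles) <- ids
  for (i in seq_len(n)) {
    is_pcr <- labels[i] == "pCR"
    pe <- if (spec$patient_effect_sd > 0)
      with_seed(derive_seed(spec$seed, i, 900000L),
                rnorm(2L, 0, spec$patient_effect_sd)) else c(0, 0)
    jit <- max(0, spec$base_jitter + is_pcr * spec$disorder_effect + pe[1])
    tex <- max(0, spec$base_texture_noise + is_pcr * spec$texture_effect +
                 pe[2])
    tiles[[i]] <- lapply(seq_len(spec$tiles_per_patient), function(t) {
      ts <- derive_seed(spec$seed, i, t)
      nn <- with_seed(derive_seed(spec$seed, i, 1000L + t),
                      sample(seq(spec$nuclei_per_tile_range[1],
                                 spec$nuclei_per_tile_range[2]), 1L))
      generate_tile(nn, jit, tex, ts, tile_size = spec$tile_size)
    })
  }
  list(clinical = clinical, tiles = tiles)
}

#' Stratified train/test split of a cohort
#'
#' The training set holds `floor(train_fraction * n)` patients,
#' apportioned across response classes by largest remainder so both
#' splits keep the cohort's class mix (149 patients at 0.75 give the
#' published 111 train / 38 test). Assignment within a class is random
#' under `seed`.
#'
#' @param labels character vector of class labels, or a cohort list from
#'   [generate_cohort()].
#' @param train_fraction fraction of patients in the training set,
#'   in (0, 1) (default 0.75).
#' @param seed integer seed.
#' @return factor of `"train"` / `"test"` per patient.
#' @export
split_cohort <- function(labels, train_fraction = 0.75, seed = 1L) {
  if (is.list(labels) && !is.null(labels$clinical))
    labels <- labels$clinical$label
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- length(labels)
  classes <- sort(unique(labels))
  sizes <- table(labels)[classes]
  if (any(sizes < 2L))
    stop("every class needs at least 2 members to split")
  n_train <- floor(train_fraction * n)
  quota <- train_fraction * as.numeric(sizes)
  base <- floor(quota)
  rem <- n_train - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  if (any(base < 1L) || any(as.numeric(sizes) - base < 1L))
    stop("train_fraction ", train_fraction,
         " would empty a class in one of the splits")
  split <- rep("test", n)
  for (k in seq_along(classes)) {
    members <- which(labels == classes[k])
    pick <- with_seed(derive_seed(seed, k, 77L),
                      sample(members, base[k]))
    split[pick] <- "train"
  }
  factor(split, levels = c("train", "test"))
}
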