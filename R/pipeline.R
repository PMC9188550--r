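# Pipeline orchestration: simulate -> segment -> extract -> aggregate ->
# train -> evaluate as a resumable, manifest-tracked run. All published
# constants (tile 768, patches 256/128, thresholds 0.5/0.1, min area 50,
# GBM 0.1/10/2000, 5 folds) live in the config, never in stage logic.

#' Default pipeline run configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param seed root seed for every stochastic stage.
#' @param n_patients,tiles_per_patient,disorder_effect,texture_effect
#'   cohort simulation settings (see [cohort_spec()]).
#' @param subsets experiments to run (default all seven).
#' @return nested config list.
#' @export
default_config <- function(out_dir = "histopcr_run", seed = 1L,
                           n_patients = 40L, tiles_per_patient = 2L,
                           disorder_effect = 0, texture_effect = 0,
                           subsets = c("clinical", "morphology",
                                       "intensity", "texture", "graph",
                                       "wavelet", "all")) {
  list(
    paths = list(out_dir = out_dir),
    seed = as.integer(seed),
    simulate = list(n_patients = n_patients, pcr_fraction = 50 / 149,
                    tiles_per_patient = tiles_per_patient,
                    nuclei_per_tile_range = c(80L, 140L),
                    disorder_effect = disorder_effect,
                    texture_effect = texture_effect,
                    tile_size = 768L, train_fraction = 0.75),
    tiling = list(tile_size = 768L, tumor_threshold = 0.5,
                  background_threshold = 0.1, white_level = 220),
    segmentation = list(threshold = 0.5, min_area = 50L,
                        patch_size = 256L, stride = 128L),
    features = list(n_levels = 32L, alpha = 0L, delta = 1L),
    model = list(learning_rate = 0.1, max_depth = 10L,
                 n_estimators = 2000L, folds = 5L, subsets = subsets))
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_config()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return config list.
#' @export
load_run_config <- function(path) {
  user <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
  else yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(base, user, prefix = "") {
    for (k in names(user)) {
      if (!k %in% names(base))
        stop("unknown config key: ", prefix, k)
      if (is.list(base[[k]]) && is.list(user[[k]]))
        base[[k]] <- merge_cfg(base[[k]], user[[k]], paste0(prefix, k, "."))
      else base[[k]] <- user[[k]]
    }
    base
  }
  merge_cfg(base, user)
}

# checksum of a file set, recorded in and verified against the manifest
file_checksums <- function(paths) {
  ok <- file.exists(paths)
  sums <- rep(NA_character_, length(paths))
  sums[ok] <- unname(tools::md5sum(paths[ok]))
  setNames(sums, basename(paths))
}

# a stage is current when its recorded outputs exist and their checksums
# match the manifest; existing outputs whose checksums differ indicate a
# corrupted artifact and abort the run naming the file
stage_current <- function(manifest, stage, paths) {
  if (is.null(manifest$stages[[stage]])) return(FALSE)
  rec <- unlist(manifest$stages[[stage]]$checksums)
  cur <- file_checksums(paths)
  if (anyNA(cur)) return(FALSE)
  bad <- names(cur)[unname(cur) != unname(rec[names(cur)])]
  if (length(bad))
    stop("checksum mismatch for ", paste(bad, collapse = ", "),
         " (stage ", stage, "): artifact corrupted or externally modified")
  TRUE
}

#' Build the patient-level modelling table for a simulated cohort
#'
#' Runs the image stages in memory: each tile is segmented (published
#' post-processing around the chosen segmenter, or the ground-truth mask
#' when `use_true_masks = TRUE`), the 549 pathomic features are
#' extracted, and tiles are aggregated to patients with nuclei-count
#' weights. The result joins the clinical covariates, label and split,
#' ready for [run_experiment()].
#'
#' @param cohort list from [generate_cohort()].
#' @param split factor from [split_cohort()].
#' @param use_true_masks bypass the segmenter and label the ground-truth
#'   masks directly (default `FALSE`).
#' @param segmenter segmenter function (default [baseline_segmenter()]).
#' @param threshold,min_area,patch_size,stride segmentation parameters.
#' @param n_levels,alpha,delta feature extraction parameters.
#' @return data.frame with `patient_id`, clinical columns, `label`,
#'   `split` and the 549 feature columns.
#' @export
cohort_patient_table <- function(cohort, split, use_true_masks = FALSE,
                                 segmenter = baseline_segmenter,
                                 threshold = 0.5, min_area = 50L,
                                 patch_size = 256L, stride = 128L,
                                 n_levels = 32L, alpha = 0L, delta = 1L) {
  feats <- list(); tids <- character(); pids <- character()
  for (pid in names(cohort$tiles)) {
    for (k in seq_along(cohort$tiles[[pid]])) {
      tl <- cohort$tiles[[pid]][[k]]
      lm <- if (use_true_masks) remove_small_objects(tl$true_mask, min_area)
      else segment_tile(tl$image, segmenter, threshold, min_area,
                        patch_size, stride)
      feats[[length(feats) + 1L]] <-
        extract_tile_features(tl$image, lm, n_levels, alpha, delta)
      tids <- c(tids, sprintf("%s_%d", pid, k))
      pids <- c(pids, pid)
    }
  }
  pat <- aggregate_patients(tile_feature_table(feats, tids, pids))
  tab <- cohort$clinical
  tab$split <- as.character(split)
  merge(tab, pat, by = "patient_id", sort = TRUE)
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate, segment, extract (tile features), aggregate
#' (patient features) and model stages in order, writing each stage's
#' artifacts plus a manifest with config snapshot, per-stage file
#' checksums and timings. Completed stages whose outputs still match
#' their recorded checksums are skipped, so interrupted runs resume;
#' identical config and seed give identical artifact checksums.
#'
#' @param config list from [default_config()] or [load_run_config()].
#' @return the run manifest (also written to `manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  else list(version = as.character(utils::packageVersion("histopcr")),
            stages = list())
  # a config change invalidates all recorded stages
  cfg_now <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  if (!is.null(manifest$config) &&
      !identical(as.character(jsonlite::toJSON(manifest$config,
                                               auto_unbox = TRUE,
                                               digits = NA)),
                 as.character(cfg_now)))
    manifest$stages <- list()
  manifest$config <- config

  record <- function(stage, paths, t0) {
    manifest$stages[[stage]] <<-
      list(checksums = as.list(file_checksums(paths)),
           seconds = round(as.numeric(proc.time()[3] - t0), 2))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  # -- simulate ---------------------------------------------------------
  cohort_csv <- file.path(out, "cohort.csv")
  sim <- config$simulate
  spec <- cohort_spec(n_patients = sim$n_patients,
                      pcr_fraction = sim$pcr_fraction,
                      tiles_per_patient = sim$tiles_per_patient,
                      nuclei_per_tile_range = sim$nuclei_per_tile_range,
                      disorder_effect = sim$disorder_effect,
                      texture_effect = sim$texture_effect,
                      tile_size = sim$tile_size, seed = config$seed)
  cohort <- generate_cohort(spec)
  split <- split_cohort(cohort, sim$train_fraction,
                        derive_seed(config$seed, 0L, 42L))
  if (!stage_current(manifest, "simulate", cohort_csv)) {
    t0 <- proc.time()[3]
    write_cohort(cohort, out, split)
    record("simulate", cohort_csv, t0)
    message("stage simulate: ", spec$n_patients, " patients, ",
            sum(cohort$clinical$label == "pCR"), " pCR")
  } else message("stage simulate: up to date, skipped")

  # -- segment + extract ------------------------------------------------
  tile_csv <- file.path(out, "tile_features.csv")
  if (!stage_current(manifest, "extract", tile_csv)) {
    t0 <- proc.time()[3]
    seg <- config$segmentation
    fx <- config$features
    feats <- list(); tids <- character(); pids <- character()
    kept <- 0L; removed <- 0L
    for (pid in names(cohort$tiles)) {
      for (k in seq_along(cohort$tiles[[pid]])) {
        tl <- cohort$tiles[[pid]][[k]]
        lm <- segment_tile(tl$image, baseline_segmenter,
                           threshold = seg$threshold,
                           min_area = seg$min_area,
                           patch_size = seg$patch_size,
                           stride = seg$stride)
        kept <- kept + lm$n_nuclei
        feats[[length(feats) + 1L]] <-
          extract_tile_features(tl$image, lm, n_levels = fx$n_levels,
                                alpha = fx$alpha, delta = fx$delta)
        tids <- c(tids, sprintf("%s_%d", pid, k))
        pids <- c(pids, pid)
      }
    }
    tile_tab <- tile_feature_table(feats, tids, pids)
    write.csv(tile_tab, tile_csv, row.names = FALSE)
    record("extract", tile_csv, t0)
    message("stage extract: ", nrow(tile_tab), " tiles, ", kept,
            " nuclei kept")
  } else {
    tile_tab <- read.csv(tile_csv, check.names = FALSE)
    message("stage extract: up to date, skipped")
  }

  # -- aggregate --------------------------------------------------------
  patient_csv <- file.path(out, "patient_features.csv")
  if (!stage_current(manifest, "aggregate", patient_csv)) {
    t0 <- proc.time()[3]
    pat <- aggregate_patients(tile_tab)
    write.csv(pat, patient_csv, row.names = FALSE)
    record("aggregate", patient_csv, t0)
    message("stage aggregate: ", nrow(pat), " patients")
  } else pat <- read.csv(patient_csv, check.names = FALSE)

  # -- model ------------------------------------------------------------
  report_json <- file.path(out, "experiments.json")
  if (!stage_current(manifest, "model", report_json)) {
    t0 <- proc.time()[3]
    tab <- cohort$clinical
    tab$split <- as.character(split)
    ptab <- merge(tab, pat, by = "patient_id", sort = TRUE)
    cfg <- gbm_config(config$model$learning_rate, config$model$max_depth,
                      config$model$n_estimators)
    res <- run_all_experiments(ptab, seed = config$seed, config = cfg,
                               folds = config$model$folds,
                               subsets = config$model$subsets)
    out_reports <- lapply(res$reports, function(r)
      list(subset = r$subset, seed = r$seed, k = r$selection$k,
           selected = r$selection$selected,
           gains = r$selection$ranking$gain[
             seq_len(min(15L, nrow(r$selection$ranking)))],
           cv_mean = as.list(r$cv$mean), cv_ci = as.list(r$cv$ci),
           test = r$test[c("accuracy", "sensitivity", "specificity",
                           "auc")]))
    jsonlite::write_json(out_reports, report_json, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    write.csv(res$summary, file.path(out, "experiment_summary.csv"),
              row.names = FALSE)
    record("model", report_json, t0)
    message("stage model: ", length(res$reports), " experiments")
  } else message("stage model: up to date, skipped")

  invisible(jsonlite::read_json(manifest_path, simplifyVector = TRUE))
}
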