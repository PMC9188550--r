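# Gradient-boosting response-prediction protocol: min-max normalization
# fitted on training rows, importance-gain feature selection, SMOTE
# doubling of the minority (pCR) class, GBM with fixed hyperparameters
# (learning rate 0.1, depth 10, 2000 estimators), stratified five-fold
# cross-validation, and held-out evaluation at the 0.5 cut-off with pCR
# as the positive class.

#' GBM hyperparameter configuration
#'
#' The published protocol fixes the learning rate, maximum depth and
#' number of estimators and leaves the remaining knobs at the reference
#' gradient-boosting implementation's defaults. The one default that
#' matters at cohort scale is the minimum leaf occupancy (20 samples in
#' the reference tool): without it a depth-10 tree can memorize a small
#' training set through a single-feature staircase, concentrating the
#' entire importance gain on one feature. `min_child_weight = 5`
#' reproduces that constraint on the logistic-hessian scale
#' (20 samples x 0.25 hessian).
#'
#' @param learning_rate shrinkage (default 0.1).
#' @param max_depth maximum tree depth (default 10).
#' @param n_estimators number of boosting rounds (default 2000).
#' @param min_child_weight minimum summed hessian per leaf (default 5,
#'   the reference implementation's 20-sample minimum leaf size).
#' @return a `gbm_config` list.
#' @export
gbm_config <- function(learning_rate = 0.1, max_depth = 10L,
                       n_estimators = 2000L, min_child_weight = 5) {
  stopifnot(learning_rate > 0, max_depth > 0, n_estimators > 0,
            min_child_weight >= 0)
  structure(list(learning_rate = learning_rate, max_depth = max_depth,
                 n_estimators = n_estimators,
                 min_child_weight = min_child_weight,
                 objective = "binary:logistic"),
            class = "gbm_config")
}

# per-subset default selected-feature counts
default_selected_k <- function() {
  c(clinical = 6L, morphology = 9L, intensity = 10L, texture = 5L,
    graph = 5L, wavelet = 9L, all = 7L)
}

#' Encode clinical covariates as a numeric matrix
#'
#' Age (years), tumor size (mm) and grade (1--3) stay numeric; the
#' binary covariates are coded menopausal post = 1, histology
#' lobular = 1, inflammatory yes = 1, ER/PR/HER2 `+` = 1.
#'
#' @param clinical data.frame with the cohort's covariate columns.
#' @return numeric matrix with 9 named columns.
#' @export
encode_clinical <- function(clinical) {
  cbind(age = as.numeric(clinical$age),
        tumor_size = as.numeric(clinical$tumor_size_mm),
        menopausal = as.numeric(clinical$menopausal == "post"),
        histology = as.numeric(clinical$histology == "lobular"),
        grade = as.numeric(clinical$grade),
        inflammatory = as.numeric(clinical$inflammatory == "yes"),
        er = as.numeric(clinical$er == "+"),
        pr = as.numeric(clinical$pr == "+"),
        her2 = as.numeric(clinical$her2 == "+"))
}

#' Fit per-feature min-max normalization ranges on training rows
#'
#' @param x numeric training matrix (rows = patients).
#' @return data.frame of per-feature `min` and `max`.
#' @export
normalize_minmax <- function(x) {
  data.frame(feature = colnames(x),
             min = apply(x, 2L, min, na.rm = TRUE),
             max = apply(x, 2L, max, na.rm = TRUE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply fitted min-max ranges to a table
#'
#' Values are affinely mapped with the training ranges and clipped to
#' `[0, 1]`; a feature constant on the training rows maps to 0.
#'
#' @param ranges data.frame from [normalize_minmax()].
#' @param x numeric matrix whose columns include the fitted features.
#' @return normalized matrix over the fitted features, in range order.
#' @export
apply_minmax <- function(ranges, x) {
  x <- x[, ranges$feature, drop = FALSE]
  out <- x
  for (k in seq_len(nrow(ranges))) {
    span <- ranges$max[k] - ranges$min[k]
    out[, k] <- if (is.finite(span) && span > 0)
      pmin(1, pmax(0, (x[, k] - ranges$min[k]) / span)) else 0
  }
  out
}

# labels -> numeric response with pCR as the positive class
label_to_binary <- function(y) as.numeric(y == "pCR")

fit_gbm <- function(x, y01, config, seed) {
  d <- xgboost::xgb.DMatrix(as.matrix(x), label = y01, nthread = 1L)
  xgboost::xgb.train(
    params = list(objective = config$objective, eta = config$learning_rate,
                  max_depth = config$max_depth,
                  min_child_weight = config$min_child_weight %||% 5,
                  nthread = 1L, seed = as.integer(seed)),
    data = d, nrounds = config$n_estimators, verbose = 0L)
}

predict_gbm <- function(booster, x) {
  as.numeric(predict(booster,
                     xgboost::xgb.DMatrix(as.matrix(x), nthread = 1L)))
}

#' Rank features by GBM importance gain
#'
#' Fits a GBM on the candidate features and ranks them by the total
#' split-gain attributed to each feature; features never used in a
#' split receive gain 0 and are ranked last (alphabetically among
#' themselves).
#'
#' @param x numeric feature matrix (normalized training rows).
#' @param y character labels (`"pCR"` / `"non-pCR"`).
#' @param config a [gbm_config()].
#' @param seed integer seed for the ranking fit.
#' @return data.frame of `feature`, `gain`, sorted by decreasing gain.
#' @export
rank_by_gain <- function(x, y, config = gbm_config(), seed = 1L) {
  if (length(unique(y)) < 2L)
    stop("gain ranking needs both response classes present")
  booster <- fit_gbm(x, label_to_binary(y), config, seed)
  imp <- xgboost::xgb.importance(model = booster)
  gains <- setNames(rep(0, ncol(x)), colnames(x))
  if (!is.null(imp) && nrow(imp) > 0L)
    gains[imp$Feature] <- imp$Gain
  data.frame(feature = names(gains), gain = as.numeric(gains),
             stringsAsFactors = FALSE,
             row.names = NULL)[order(-gains, names(gains)), , drop = FALSE]
}

#' Choose how many top-ranked features to keep
#'
#' Either a fixed `k` (the per-subset defaults of
#' `default_selected_k()`), or the gap rule operationalizing "meaningful
#' difference in gain": the largest relative drop between consecutive
#' gains among the top 15 non-zero entries.
#'
#' Features with zero gain (never used in a split) are not selected
#' while any non-zero gain exists; if every gain is zero -- possible on
#' tiny or uninformative training sets -- the top of the (deterministic)
#' ranking is kept with a warning so the protocol can still run.
#'
#' @param ranking data.frame from [rank_by_gain()].
#' @param k fixed number of features; `NULL` to use the gap rule.
#' @return list with `k`, `selected` (character) and `ranking`.
#' @export
select_features <- function(ranking, k = NULL) {
  nz <- ranking[ranking$gain > 0, , drop = FALSE]
  if (nrow(nz) == 0L) {
    warning("no feature obtained a non-zero gain; ",
            "keeping the top of the ranking")
    k <- max(1L, min(if (is.null(k)) 1L else k, nrow(ranking)))
    return(list(k = k, selected = ranking$feature[seq_len(k)],
                ranking = ranking))
  }
  if (is.null(k)) {
    m <- min(15L, nrow(nz))
    g <- nz$gain[seq_len(m)]
    if (m == 1L) k <- 1L
    else k <- which.max((g[-m] - g[-1]) / g[-m])
  }
  k <- min(k, nrow(nz))
  list(k = k, selected = nz$feature[seq_len(k)], ranking = ranking)
}

#' SMOTE oversampling of the minority class
#'
#' Doubles the minority rows: for each original row `x_i` one synthetic
#' row `x_i + lambda (x_nn - x_i)` is added, with `lambda ~ U(0, 1)` and
#' `x_nn` one of the `k_neighbors` nearest minority neighbours of `x_i`.
#'
#' @param x numeric matrix of minority-class rows.
#' @param k_neighbors neighbourhood size (default 5); reduced to
#'   `nrow(x) - 1` with a warning when the minority is smaller.
#' @param seed integer seed.
#' @return matrix with `2 * nrow(x)` rows (originals first).
#' @export
smote_oversample <- function(x, k_neighbors = 5L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 1L) stop("no minority rows to oversample")
  if (n == 1L) return(rbind(x, x))
  if (n <= k_neighbors) {
    warning("minority count ", n, " <= k_neighbors ", k_neighbors,
            "; using k = ", n - 1L)
    k_neighbors <- n - 1L
  }
  dm <- as.matrix(dist(x))
  diag(dm) <- Inf
  with_seed(seed, {
    synth <- matrix(NA_real_, n, ncol(x),
                    dimnames = list(NULL, colnames(x)))
    for (i in seq_len(n)) {
      nn <- order(dm[i, ])[seq_len(k_neighbors)]
      j <- nn[sample.int(k_neighbors, 1L)]
      lam <- runif(1L)
      synth[i, ] <- x[i, ] + lam * (x[j, ] - x[i, ])
    }
    rbind(x, synth)
  })
}

# normalized + SMOTE-augmented design matrix for one training portion
augment_training <- function(x_norm, y, smote_k, seed) {
  y01 <- label_to_binary(y)
  counts <- table(factor(y01, levels = c(0, 1)))
  minority <- if (counts["1"] <= counts["0"]) 1 else 0
  xm <- x_norm[y01 == minority, , drop = FALSE]
  aug <- smote_oversample(xm, smote_k, seed)
  x_aug <- rbind(x_norm[y01 != minority, , drop = FALSE], aug)
  y_aug <- c(rep(1 - minority, sum(y01 != minority)),
             rep(minority, nrow(aug)))
  list(x = x_aug, y = y_aug)
}

## ---- evaluation -----------------------------------------------------------

#' Empirical ROC curve
#'
#' @param scores numeric prediction scores.
#' @param y character labels; `"pCR"` is the positive class.
#' @return data.frame of (`fpr`, `tpr`) from (0, 0) to (1, 1), one point
#'   per distinct score threshold.
#' @export
roc_curve <- function(scores, y) {
  pos <- y == "pCR"
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[!pos] >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

# trapezoidal area under an ROC curve
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Evaluate prediction scores against labels
#'
#' Predicted positive iff `score > cutoff` (strict). AUC is the
#' trapezoidal area under the empirical ROC curve; with only one class
#' present AUC is `NA` while the threshold metrics are still computed.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param y character labels; positive class `"pCR"`.
#' @param cutoff decision threshold (default 0.5).
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc` and
#'   the `roc` data.frame.
#' @export
evaluate_scores <- function(scores, y, cutoff = 0.5) {
  pos <- y == "pCR"
  pred <- scores > cutoff
  list(accuracy = mean(pred == pos),
       sensitivity = if (any(pos)) mean(pred[pos]) else NA_real_,
       specificity = if (any(!pos)) mean(!pred[!pos]) else NA_real_,
       auc = if (any(pos) && any(!pos))
         auc_trapezoid(roc_curve(scores, y)) else NA_real_,
       roc = if (any(pos) && any(!pos)) roc_curve(scores, y) else NULL)
}

# stratified fold assignment (balanced class counts per fold)
stratified_folds <- function(y, folds, seed) {
  if (any(table(y) < folds))
    stop("every class needs at least ", folds,
         " members for stratified ", folds, "-fold CV")
  assignment <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      members <- sample(which(y == cls))
      assignment[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  assignment
}

#' Stratified k-fold cross-validation of the full protocol
#'
#' Within each round, normalization ranges and (optionally) the feature
#' selection are refit on the fold-training portion only, the minority
#' class of that portion is SMOTE-doubled, a GBM is trained and the
#' held-out fold scored -- the leakage-safe reading of the protocol.
#' With `selection = "once"` a selection fixed beforehand (`selected`)
#' is reused in every fold.
#'
#' @param x raw (unnormalized) candidate feature matrix, training rows.
#' @param y character labels.
#' @param config a [gbm_config()].
#' @param folds number of folds (default 5).
#' @param seed integer seed driving folds, SMOTE and GBM fits.
#' @param k fixed selection size (`NULL` = gap rule) when
#'   `selection = "per-fold"`.
#' @param selection `"per-fold"` (default) or `"once"`.
#' @param selected character vector of features, required for
#'   `selection = "once"`.
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @return list with per-fold metrics, their means and 95% CIs
#'   (`mean +- 1.96 sd / sqrt(folds)`), the fold assignment, and the
#'   out-of-fold scores (`oof_scores`, aligned to the input rows; the
#'   AUC of these pooled scores is the lower-variance pooled reading of
#'   the cross-validated AUC).
#' @export
cross_validate <- function(x, y, config = gbm_config(), folds = 5L,
                           seed = 1L, k = NULL,
                           selection = c("per-fold", "once"),
                           selected = NULL, smote_k = 5L) {
  selection <- match.arg(selection)
  if (selection == "once" && is.null(selected))
    stop("selection = \"once\" requires a fixed `selected` feature set")
  assignment <- stratified_folds(y, folds, derive_seed(seed, 0L, 5L))
  metrics <- vector("list", folds)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- assignment != f
    sel <- if (selection == "once") selected else {
      # ranking is fitted on the SMOTE-augmented fold-training portion:
      # the minority class is oversampled "in each round", and the
      # reference GBM's leaf constraint needs the augmented sample size
      ranges_f <- normalize_minmax(x[tr, , drop = FALSE])
      xn <- apply_minmax(ranges_f, x[tr, , drop = FALSE])
      aug_f <- augment_training(xn, y[tr], smote_k,
                                derive_seed(seed, f, 4L))
      select_features(rank_by_gain(aug_f$x,
                                   ifelse(aug_f$y == 1, "pCR", "non-pCR"),
                                   config, derive_seed(seed, f, 1L)),
                      k)$selected
    }
    ranges <- normalize_minmax(x[tr, sel, drop = FALSE])
    xn_tr <- apply_minmax(ranges, x[tr, , drop = FALSE])
    aug <- augment_training(xn_tr, y[tr], smote_k, derive_seed(seed, f, 2L))
    booster <- fit_gbm(aug$x, aug$y, config, derive_seed(seed, f, 3L))
    scores <- predict_gbm(booster, apply_minmax(ranges,
                                                x[!tr, , drop = FALSE]))
    oof[!tr] <- scores
    metrics[[f]] <- evaluate_scores(scores, y[!tr])[
      c("accuracy", "sensitivity", "specificity", "auc")]
  }
  m <- do.call(rbind, lapply(metrics, function(z)
    unlist(z, use.names = TRUE)))
  mm <- colMeans(m, na.rm = TRUE)
  ci <- 1.96 * apply(m, 2L, sd, na.rm = TRUE) / sqrt(folds)
  list(fold_metrics = as.data.frame(m), mean = mm, ci = ci,
       folds = assignment, oof_scores = oof)
}

#' Train the final response model on the full training set
#'
#' Normalization is fitted on all training rows over the selected
#' features, the minority class is SMOTE-doubled, and the GBM is fitted
#' with the configured hyperparameters.
#'
#' @param x raw training feature matrix containing the selected columns.
#' @param y character labels.
#' @param selected character vector of selected feature names.
#' @param config a [gbm_config()].
#' @param seed integer seed.
#' @param smote_k SMOTE neighbourhood size (default 5).
#' @return an object of class `pcr_model`.
#' @export
train_final <- function(x, y, selected, config = gbm_config(), seed = 1L,
                        smote_k = 5L) {
  missing <- setdiff(selected, colnames(x))
  if (length(missing))
    stop("training table lacks selected features: ",
         paste(missing, collapse = ", "))
  ranges <- normalize_minmax(x[, selected, drop = FALSE])
  xn <- apply_minmax(ranges, x)
  aug <- augment_training(xn, y, smote_k, derive_seed(seed, 0L, 11L))
  booster <- fit_gbm(aug$x, aug$y, config, derive_seed(seed, 0L, 12L))
  structure(list(booster = booster, features = selected, ranges = ranges,
                 config = config, seed = seed),
            class = "pcr_model")
}

#' @export
predict.pcr_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop("newdata lacks model features: ", paste(missing, collapse = ", "))
  predict_gbm(object$booster,
              apply_minmax(object$ranges, as.matrix(newdata)))
}

#' @export
print.pcr_model <- function(x, ...) {
  cat("pCR response GBM:", length(x$features), "features (",
      paste(head(x$features, 5L), collapse = ", "),
      if (length(x$features) > 5L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

## ---- experiments ----------------------------------------------------------

# assemble the candidate feature matrix for a subset
subset_feature_matrix <- function(patient_table, subset) {
  reg <- feature_registry()
  if (subset == "clinical") return(encode_clinical(patient_table))
  fam <- reg$name[reg$family == subset]
  if (subset == "all")
    return(cbind(encode_clinical(patient_table),
                 as.matrix(patient_table[, reg$name, drop = FALSE])))
  if (length(fam) == 0L) stop("unknown feature subset: ", subset)
  as.matrix(patient_table[, fam, drop = FALSE])
}

#' Run one feature-subset experiment end-to-end
#'
#' One of the seven modelling experiments: restrict to a feature subset
#' (`clinical`, one of the five pathomic families, or `all` = clinical +
#' pathomic), rank by importance gain on the normalized training rows,
#' keep the subset's default top-k (6/9/10/5/5/9/7) or the gap rule,
#' cross-validate the protocol on the training split, train the final
#' model and evaluate it on the held-out test split.
#'
#' @param patient_table data.frame with `patient_id`, clinical columns,
#'   `label`, `split`, and the 549 feature columns.
#' @param subset one of `clinical`, `morphology`, `intensity`,
#'   `texture`, `graph`, `wavelet`, `all`.
#' @param seed integer experiment seed.
#' @param config a [gbm_config()].
#' @param folds CV folds (default 5).
#' @param k selection size; `NULL` uses the subset default,
#'   `"gap"` the gap rule.
#' @param cv_selection `"per-fold"` (default) or `"once"`.
#' @return report list: `subset`, `seed`, `selection`, `cv`, `test`
#'   metrics, and sizes.
#' @export
run_experiment <- function(patient_table, subset, seed = 1L,
                           config = gbm_config(), folds = 5L, k = NULL,
                           cv_selection = "per-fold") {
  stopifnot(all(c("label", "split") %in% names(patient_table)))
  x <- subset_feature_matrix(patient_table, subset)
  y <- patient_table$label
  tr <- patient_table$split == "train"
  k_fixed <- if (is.null(k)) unname(default_selected_k()[subset])
             else if (identical(k, "gap")) NULL else k
  # selection for the final model: fitted once on the full training set,
  # with the minority class SMOTE-doubled as in every other GBM fit
  ranges_tr <- normalize_minmax(x[tr, , drop = FALSE])
  aug_tr <- augment_training(apply_minmax(ranges_tr, x[tr, , drop = FALSE]),
                             y[tr], 5L, derive_seed(seed, 0L, 20L))
  ranking <- rank_by_gain(aug_tr$x,
                          ifelse(aug_tr$y == 1, "pCR", "non-pCR"),
                          config, derive_seed(seed, 0L, 21L))
  sel <- select_features(ranking, k_fixed)
  cv <- cross_validate(x[tr, , drop = FALSE], y[tr], config, folds, seed,
                       k = k_fixed, selection = cv_selection,
                       selected = if (cv_selection == "once") sel$selected)
  model <- train_final(x[tr, , drop = FALSE], y[tr], sel$selected, config,
                       seed)
  scores <- predict(model, x[!tr, , drop = FALSE])
  test <- evaluate_scores(scores, y[!tr])
  list(subset = subset, seed = seed, selection = sel, cv = cv,
       model = model, test = test, n_train = sum(tr), n_test = sum(!tr))
}

#' Run all seven feature-subset experiments
#'
#' @inheritParams run_experiment
#' @param subsets experiments to run (default all seven).
#' @return list with per-experiment `reports` and a `summary` data.frame
#'   shaped like a results table (one row per experiment: selected
#'   feature count, CV metrics with CI, test metrics).
#' @export
run_all_experiments <- function(patient_table, seed = 1L,
                                config = gbm_config(), folds = 5L,
                                subsets = c("clinical", "morphology",
                                            "intensity", "texture",
                                            "graph", "wavelet", "all"),
                                cv_selection = "per-fold") {
  reports <- lapply(subsets, function(s)
    run_experiment(patient_table, s, seed, config, folds,
                   cv_selection = cv_selection))
  names(reports) <- subsets
  summary <- do.call(rbind, lapply(reports, function(r) {
    data.frame(subset = r$subset, n_features = r$selection$k,
               val_acc = r$cv$mean["accuracy"],
               val_acc_ci = r$cv$ci["accuracy"],
               val_auc = r$cv$mean["auc"], val_auc_ci = r$cv$ci["auc"],
               val_sen = r$cv$mean["sensitivity"],
               val_spec = r$cv$mean["specificity"],
               test_acc = r$test$accuracy, test_auc = r$test$auc,
               test_sen = r$test$sensitivity,
               test_spec = r$test$specificity,
               row.names = NULL)
  }))
  list(reports = reports, summary = summary)
}
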