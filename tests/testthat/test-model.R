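fast_config <- gbm_config(n_estimators = 200L)

test_that("min-max normalization follows the published convention", {
  x <- cbind(f1 = c(2, 4, 6), f2 = c(1, 1, 1))
  r <- normalize_minmax(x)
  n <- apply_minmax(r, x)
  expect_equal(unname(n[, "f1"]), c(0, 0.5, 1))
  expect_equal(unname(n[, "f2"]), c(0, 0, 0))  # constant features map to 0
  # out-of-range application values clip to [0, 1]
  test <- cbind(f1 = c(0, 8), f2 = c(5, -2))
  nt <- apply_minmax(r, test)
  expect_equal(unname(nt[, "f1"]), c(0, 1))
  withr::with_seed(3, {
    x2 <- matrix(runif(60, -5, 9), 20L, 3L,
                 dimnames = list(NULL, c("a", "b", "c")))
    n2 <- apply_minmax(normalize_minmax(x2), x2)
    for (j in 1:3) {
      expect_equal(unname(n2[, j]),
                   (x2[, j] - min(x2[, j])) / (max(x2[, j]) - min(x2[, j])))
    }
  })
})

test_that("gain ranking finds a planted signal and zero-gain features", {
  for (s in 1:5) {
    fix <- fixture_model_table(n = 60L, p = 8L, effect = 4, seed = s)
    xn <- apply_minmax(normalize_minmax(fix$x), fix$x)
    rk <- rank_by_gain(xn, fix$y, fast_config, seed = s)
    expect_equal(rk$feature[1], "signal")
    expect_true(all(rk$gain >= 0))
  }
  # a constant feature can never split and is never selected
  fix <- fixture_model_table(n = 60L, p = 6L, effect = 4, seed = 9)
  fix$x[, "noise1"] <- 1
  xn <- apply_minmax(normalize_minmax(fix$x), fix$x)
  rk <- rank_by_gain(xn, fix$y, fast_config, seed = 1)
  expect_equal(rk$gain[rk$feature == "noise1"], 0)
  sel <- select_features(rk, k = 5L)
  expect_false("noise1" %in% sel$selected)
  # single-class labels are an explicit failure
  expect_error(rank_by_gain(xn, rep("pCR", 60L), fast_config), "classes")
})

test_that("the gap rule picks the largest relative drop", {
  rk <- data.frame(feature = paste0("f", 1:6),
                   gain = c(0.5, 0.45, 0.04, 0.008, 0.002, 0))
  sel <- select_features(rk, k = NULL)
  expect_equal(sel$k, 2L)  # 0.45 -> 0.04 is the largest relative drop
  expect_equal(sel$selected, c("f1", "f2"))
})

test_that("SMOTE doubles the minority exactly (39 -> 78)", {
  withr::with_seed(1, {
    x <- matrix(rnorm(39 * 5), 39L, 5L,
                dimnames = list(NULL, paste0("f", 1:5)))
    out <- smote_oversample(x, k_neighbors = 5L, seed = 2L)
    expect_equal(nrow(out), 78L)
    expect_identical(out[1:39, ], x)
  })
})

test_that("SMOTE interpolates on segments between minority neighbours", {
  withr::with_seed(4, {
    x <- matrix(runif(10 * 3), 10L, 3L,
                dimnames = list(NULL, c("a", "b", "c")))
    out <- smote_oversample(x, k_neighbors = 3L, seed = 7L)
    synth <- out[11:20, , drop = FALSE]
    for (i in seq_len(10L)) {
      s <- synth[i, ]
      # exhaustive segment membership over all ordered pairs
      on_segment <- FALSE
      for (a in seq_len(10L)) for (b in seq_len(10L)) {
        if (a == b) next
        d <- x[b, ] - x[a, ]
        lam <- if (abs(d[1]) > 1e-12) (s[1] - x[a, 1]) / d[1] else NA
        if (!is.na(lam) && lam >= -1e-9 && lam <= 1 + 1e-9 &&
            max(abs(x[a, ] + lam * d - s)) < 1e-9)
          on_segment <- TRUE
      }
      expect_true(on_segment)
    }
    # synthetic rows stay inside the feature-wise min/max hull
    expect_true(all(synth >= rep(apply(x, 2, min), each = 10L) - 1e-12))
    expect_true(all(synth <= rep(apply(x, 2, max), each = 10L) + 1e-12))
  })
})

test_that("SMOTE degenerate cases behave as documented", {
  x2 <- matrix(c(1, 2, 1, 2), 2L, 2L,
               dimnames = list(NULL, c("a", "b")))
  x2[2, ] <- x2[1, ]  # two identical points
  expect_warning(out <- smote_oversample(x2, k_neighbors = 5L, seed = 1L),
                 "k_neighbors")
  expect_equal(nrow(out), 4L)
  expect_true(all(out[3:4, 1] == x2[1, 1]))  # zero-length segments
})

test_that("ROC evaluation matches its closed forms and rank identity", {
  # perfect separation
  ev <- evaluate_scores(c(0.9, 0.8, 0.1, 0.2),
                        c("pCR", "pCR", "non-pCR", "non-pCR"))
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$roc$fpr[1], 0)
  expect_equal(ev$roc$tpr[nrow(ev$roc)], 1)
  # all-equal scores: chance AUC by the trapezoid on a single point
  ev2 <- evaluate_scores(rep(0.5, 6), rep(c("pCR", "non-pCR"), 3))
  expect_equal(ev2$auc, 0.5)
  # Mann-Whitney identity on random scores
  withr::with_seed(11, {
    y <- rep(c("pCR", "non-pCR"), c(12L, 20L))
    s <- runif(32)
    ev3 <- evaluate_scores(s, y)
    u <- sum(outer(s[y == "pCR"], s[y != "pCR"],
                   function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(ev3$auc, u / (12 * 20))
    # AUC is invariant under strictly increasing transforms
    ev4 <- evaluate_scores(plogis(5 * s - 2), y)
    expect_equal(ev4$auc, ev3$auc)
    # complementing labels and scores swaps sensitivity and specificity
    yc <- ifelse(y == "pCR", "non-pCR", "pCR")
    ev5 <- evaluate_scores(1 - s, yc)
    expect_equal(ev5$sensitivity, ev3$specificity)
    expect_equal(ev5$specificity, ev3$sensitivity)
    expect_equal(ev5$auc, ev3$auc)
    # agreement with an independent ROC implementation
    expect_equal(ev3$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, levels = c("non-pCR", "pCR"),
                                                direction = "<", quiet = TRUE))))
  })
})

test_that("monotone transforms of scores do not change the ROC points", {
  withr::with_seed(13, {
    y <- rep(c("pCR", "non-pCR"), c(8L, 10L))
    s <- runif(18)
    r1 <- roc_curve(s, y)
    r2 <- roc_curve(s^3, y)
    expect_equal(r1, r2)
  })
})

test_that("stratified folds partition every class evenly", {
  y <- rep(c("pCR", "non-pCR"), c(15L, 30L))
  f <- histopcr:::stratified_folds(y, 5L, seed = 3L)
  expect_equal(length(f), 45L)
  expect_true(all(table(f) == 9L))
  for (k in 1:5) expect_equal(sum(y[f == k] == "pCR"), 3L)
  expect_error(histopcr:::stratified_folds(rep(c("pCR", "non-pCR"),
                                               c(3L, 30L)), 5L, 1L),
               "at least")
})

test_that("cross-validation separates a planted signal and not noise", {
  fix <- fixture_model_table(n = 60L, p = 10L, effect = 4, seed = 21)
  cv <- cross_validate(fix$x, fix$y, fast_config, folds = 5L, seed = 1L,
                       k = 3L)
  expect_gte(cv$mean[["auc"]], 0.95)
  # every record scored exactly once across validation folds
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), 60L)
})

test_that("permuted labels yield chance-level cross-validated AUC", {
  fix <- fixture_model_table(n = 60L, p = 10L, effect = 4, seed = 22)
  aucs <- vapply(1:10, function(r) {
    yp <- withr::with_seed(1000L + r, sample(fix$y))
    cross_validate(fix$x, yp, fast_config, folds = 5L, seed = r,
                   k = 3L)$mean[["auc"]]
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("the final model is reproducible and checks its inputs", {
  fix <- fixture_model_table(n = 50L, p = 6L, effect = 3, seed = 31)
  m1 <- train_final(fix$x, fix$y, c("signal", "noise1"), fast_config,
                    seed = 5L)
  m2 <- train_final(fix$x, fix$y, c("signal", "noise1"), fast_config,
                    seed = 5L)
  expect_equal(predict(m1, fix$x), predict(m2, fix$x))
  # a table missing a selected feature is rejected
  expect_error(predict(m1, fix$x[, c("signal", "noise2"), drop = FALSE]),
               "lacks model features")
  expect_error(train_final(fix$x, fix$y, "absent", fast_config),
               "lacks selected")
})

test_that("run_experiment wires selection, CV and held-out evaluation", {
  fix <- fixture_model_table(n = 80L, p = 549L, effect = 4, seed = 41)
  reg_names <- feature_registry()$name
  colnames(fix$x) <- reg_names
  # plant the signal in a graph feature
  gsig <- "Delaunay_Sides_Stddev"
  fix$x[, gsig] <- fix$x[, "Morphology_Area_Mean"]
  fix$x[fix$y == "pCR", gsig] <- fix$x[fix$y == "pCR", gsig] + 4
  tab <- data.frame(patient_id = sprintf("P%02d", 1:80),
                    age = 50, menopausal = "post", tumor_size_mm = 40,
                    histology = "ductal", grade = 2L, inflammatory = "no",
                    er = "+", pr = "+", her2 = "-",
                    label = fix$y,
                    split = rep(c("train", "test"), c(60L, 20L)),
                    fix$x, check.names = FALSE)
  rep_g <- run_experiment(tab, "graph", seed = 1L, config = fast_config,
                          folds = 3L, k = 3L)
  expect_equal(rep_g$selection$selected[1], gsig)
  expect_gte(rep_g$test$auc, 0.9)
  expect_equal(rep_g$n_train, 60L)
  expect_equal(rep_g$n_test, 20L)
})
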