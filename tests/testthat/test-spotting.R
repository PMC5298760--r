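# build a labelled candidate-feature table directly for classifier tests
toy_rows <- function(n_pos = 20, n_neg = 20, axis = "X", seed = 31) {
  set.seed(seed)
  n <- n_pos + n_neg
  label <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  amp <- ifelse(label, 2, 0.1)
  rows <- data.frame(
    session_id = "toy", frame_index = 1L, axis = axis,
    start = 0L, end = 10L, i_low = 1L, i_high = 2L,
    global_start = seq_len(n) * 20L, global_end = seq_len(n) * 20L + 12L,
    stringsAsFactors = FALSE)
  feats <- t(vapply(amp, function(a) {
    s <- a * sin(seq(0, pi, length.out = 12)) + rnorm(12, 0, 0.01)
    unlist(extract_features(s, 40))
  }, numeric(9)))
  cbind(rows, as.data.frame(feats), label = label)
}

test_that("candidate labelling uses the Jaccard overlap rule", {
  cand <- data.frame(global_start = c(100L, 0L, 100L),
                     global_end = c(160L, 60L, 160L))
  # rows: exact match, disjoint, Jaccard 1/3
  lab <- label_candidates(cand, annotations("s", 100, 160))
  expect_true(lab$label[1])
  expect_false(lab$label[2])
  lab2 <- label_candidates(cand[3, ], annotations("s", 130, 190))
  expect_false(lab2$label)  # intersection 30 / union 90 < 0.5
})

test_that("all three classifier kinds separate a separable training set", {
  rows <- toy_rows()
  for (cl in c("NB", "kNN", "SVM")) {
    model <- train_spotter(rows, cl, seed = 1)
    seg <- spot(model, rows)
    ord <- order(rows$global_start)
    expect_equal(seg$spotted$decision, rows$label[ord],
                 label = paste(cl, "training decisions"))
  }
})

test_that("kNN unanimous vote and NB prior-following behave as designed", {
  # 5 identical positive neighbours around the query -> positive
  X <- data.frame(a = c(rep(1, 5), rep(-1, 2)), b = 0)
  y <- c(rep(TRUE, 5), rep(FALSE, 2))
  fit <- sigspot:::fit_classifier("kNN", X, y)
  expect_true(as.logical(sigspot:::predict_classifier(fit, data.frame(a = 1, b = 0))))

  # NB with identical class-conditionals follows the class prior
  set.seed(8)
  Xp <- data.frame(a = rnorm(300))
  yp <- rep(c(TRUE, FALSE), times = c(240, 60))
  fitp <- sigspot:::fit_classifier("NB", Xp, yp)
  pred <- sigspot:::predict_classifier(fitp, data.frame(a = rnorm(50)))
  expect_gt(mean(pred), 0.8)  # majority prior dominates
})

test_that("NB wrapper posterior equals the e1071 reference prediction", {
  rows <- toy_rows(15, 15)
  fit <- sigspot:::fit_classifier("NB", rows[, feature_names()], rows$label)
  newd <- toy_rows(6, 6, seed = 77)[, feature_names()]
  ours <- attr(sigspot:::predict_classifier(fit, newd), "score")
  ref <- stats::predict(fit$model, newd, type = "raw")[, "TRUE"]
  expect_equal(ours, unname(ref), tolerance = 1e-10)
})

test_that("single-class partitions fall back with a warning in metadata", {
  rows <- toy_rows()
  rows$label <- TRUE
  model <- train_spotter(rows, "SVM", seed = 1)
  expect_match(paste(model$metadata$warnings, collapse = ";"), "single-class")
  seg <- spot(model, rows)
  expect_true(all(seg$spotted$decision))

  # sparse axis partition: falls back to pooled model
  rows2 <- toy_rows()
  rows2$axis[rows2$label == FALSE][1:18] <- "Y"  # X keeps only 2 negatives
  model2 <- train_spotter(rows2, "kNN", seed = 1)
  expect_false("X" %in% names(model2$per_axis))
})

test_that("spotting an empty candidate set yields an empty segmentation", {
  model <- train_spotter(toy_rows(), "SVM", seed = 1)
  empty <- toy_rows()[0, ]
  seg <- spot(model, empty, session_id = "none")
  expect_equal(nrow(seg$spotted), 0L)
})

test_that("scalers are fitted on training rows only (no test leakage)", {
  rows <- toy_rows()
  fit <- sigspot:::fit_classifier("SVM", rows[, feature_names()], rows$label)
  sc_before <- fit$scaler
  # perturbing test rows must not change the stored scaler or its output
  newd <- toy_rows(5, 5, seed = 99)[, feature_names()]
  p1 <- sigspot:::predict_classifier(fit, newd)
  expect_identical(fit$scaler, sc_before)
  newd2 <- newd; newd2[1, ] <- newd2[1, ] * 100
  p2 <- sigspot:::predict_classifier(fit, newd2)
  expect_identical(p1[-1], p2[-1])  # other rows unaffected by row 1
})

test_that("model archives round-trip through save/load", {
  model <- train_spotter(toy_rows(), "kNN", seed = 1)
  p <- withr::local_tempfile(fileext = ".rds")
  save_spotter(model, p)
  back <- load_spotter(p)
  expect_equal(back$classifier_kind, "kNN")
  rows <- toy_rows(3, 3, seed = 55)
  expect_equal(spot(back, rows)$spotted, spot(model, rows)$spotted)
})

test_that("full pipeline is deterministic and empty on an all-zero recording", {
  cfg <- clean_config(seed = 5)
  ds <- generate_dataset(cfg, 2)
  tables <- sigspot:::session_tables(ds, boundary_params(9, 12))
  train <- do.call(rbind, lapply(tables, `[[`, "rows"))
  model <- train_spotter(train, "SVM", seed = 1)

  seg1 <- run_pipeline(ds[[1]]$recording, model, boundary_params(9, 12))
  seg2 <- run_pipeline(ds[[1]]$recording, model, boundary_params(9, 12))
  expect_identical(seg1, seg2)

  zero <- recording(matrix(0, nrow = 800, ncol = 3), 40, session_id = "flat")
  segz <- run_pipeline(zero, model, boundary_params(9, 12))
  expect_equal(nrow(segz$spotted[segz$spotted$decision, ]), 0L)
})
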