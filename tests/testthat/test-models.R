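# small configs keep the unit tests fast; the shipped defaults are
# exercised in the acceptance suite
fast_gbr <- function(...) gbr_config(n_estimators = 100, ...)
fast_gbc <- function(...) gbc_config(n_estimators = 100, ...)

test_that("configs default to the shipped hyperparameters", {
  cfg <- gbr_config()
  expect_equal(cfg[c("alpha", "learning_rate", "max_depth",
                     "min_samples_leaf", "n_estimators", "random_state")],
               list(alpha = 0.01, learning_rate = 0.1, max_depth = 2,
                    min_samples_leaf = 10, n_estimators = 50000,
                    random_state = 100))
  expect_equal(cfg$loss, "squared_error")
  ccfg <- gbc_config()
  expect_equal(ccfg$n_estimators, 50000)
  expect_true(ccfg$warm_start)
})

test_that("regression on a constant target predicts the constant", {
  d <- make_planted_dataset(60, schema = "gbr1", seed = 2)
  d$angle_deg <- -46
  m <- train_gbr(d, "gbr1", fast_gbr())
  expect_equal(predict(m, d[1:5, ]), rep(-46, 5), tolerance = 1e-6)
})

test_that("training is deterministic for fixed data and config", {
  d <- make_planted_dataset(150, schema = "gbr1", seed = 4)
  m1 <- train_gbr(d, "gbr1", fast_gbr())
  m2 <- train_gbr(d, "gbr1", fast_gbr())
  probe <- make_planted_dataset(30, schema = "gbr1", seed = 5)
  expect_identical(predict(m1, probe), predict(m2, probe))
})

test_that("tree-ensemble predictions stay inside the training target range", {
  d <- make_planted_dataset(200, schema = "gbr1", seed = 6)
  m <- train_gbr(d, "gbr1", fast_gbr())
  probe <- make_planted_dataset(100, schema = "gbr1", seed = 7,
                                weights = 4)
  p <- predict(m, probe)
  expect_true(all(p >= m$target_range[1] - 1e-6))
  expect_true(all(p <= m$target_range[2] + 1e-6))
})

test_that("schema mismatches are refused", {
  d <- make_planted_dataset(60, schema = "gbr1", seed = 2)
  m <- train_gbr(d, "gbr1", fast_gbr())
  x151 <- matrix(0, 1, 151)
  expect_error(predict(m, x151), "151 columns.*needs 52")
  expect_error(train_gbr(d[1:5, ], "gbr1", gbr_config()), "Too few")
})

test_that("angles classify into normal and outlier bands, ties owned once", {
  expect_equal(as.character(classify_angle(c(-45, -39.9, -50.1))),
               c("normal", "max_outlier", "min_outlier"))
  # boundary ownership: the normal range is inclusive on both ends
  expect_equal(as.character(classify_angle(c(-40, -50))),
               c("normal", "normal"))
  expect_error(classify_angle(NA_real_))
})

test_that("gated predictions dispatch to exactly the classified regressor", {
  d <- make_planted_dataset(600, schema = "gbr1",
                            class_mix = c(0.2, 0.6, 0.2), seed = 8)
  g <- train_gated(d, "gbr1", fast_gbc(), fast_gbr())
  probe <- make_planted_dataset(80, schema = "gbr1",
                                class_mix = c(0.2, 0.6, 0.2), seed = 9)
  both <- predict(g, probe, type = "both")
  expect_equal(nrow(both), 80)
  x <- features_from_records(probe, g$schema)
  for (lv in levels(both$.class)) {
    rows <- which(both$.class == lv)
    if (length(rows) == 0) next
    direct <- predict(g$fit$regressors[[lv]]$booster,
                      xgboost::xgb.DMatrix(x[rows, , drop = FALSE],
                                           nthread = 1))
    expect_equal(both$.pred[rows], direct, tolerance = 1e-12)
  }
  expect_identical(predict(g, probe), both$.pred)
  expect_identical(predict(g, probe, type = "class"), both$.class)
})

test_that("gating refuses training sets with an underpopulated class", {
  d <- make_planted_dataset(200, schema = "gbr1", noise_sd = 0.5, seed = 3)
  # essentially all angles are normal; outlier classes are near-empty
  expect_error(train_gated(d, "gbr1", fast_gbc(), fast_gbr()),
               "widen the data or disable gating")
})

test_that("MLP baseline trains, predicts finitely, and is seed-sensitive", {
  d <- make_planted_dataset(300, schema = "gbr1", seed = 10)
  m1 <- suppressWarnings(train_mlp(d, "gbr1", max_iter = 300, seed = 1))
  m2 <- suppressWarnings(train_mlp(d, "gbr1", max_iter = 300, seed = 2))
  probe <- make_planted_dataset(40, schema = "gbr1", seed = 11)
  p1 <- predict(m1, probe); p2 <- predict(m2, probe)
  expect_true(all(is.finite(p1)), all(is.finite(p2)))
  expect_false(identical(p1, p2))
  expect_error(predict(m1, matrix(0, 1, 151)), "needs 52")
})

test_that("model bundles survive serialization and refuse wrong schemas", {
  d <- make_planted_dataset(150, schema = "gbr2", seed = 12)
  m <- train_gbr(d, "gbr2", fast_gbr())
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  back <- load_model(tf, schema = "gbr2")
  probe <- make_planted_dataset(20, schema = "gbr2", seed = 13)
  expect_equal(predict(back, probe), predict(m, probe), tolerance = 1e-12)
  expect_error(load_model(tf, schema = "gbr4"), "gbr2, not gbr4")

  g <- train_gated(make_planted_dataset(600, schema = "gbr1",
                                        class_mix = c(0.2, 0.6, 0.2),
                                        seed = 8),
                   "gbr1", fast_gbc(), fast_gbr())
  tg <- withr::local_tempfile(fileext = ".rds")
  save_model(g, tg)
  gprobe <- make_planted_dataset(15, schema = "gbr1",
                                 class_mix = c(0.2, 0.6, 0.2), seed = 9)
  expect_equal(predict(load_model(tg), gprobe), predict(g, gprobe),
               tolerance = 1e-12)
})

test_that("cross-validation predicts every record once per repeat", {
  recs <- make_planted_dataset(20, schema = "gbr1", seed = 14)
  cv <- cross_validate(recs, "gbr1",
                       gbr_config(n_estimators = 30, min_samples_leaf = 2),
                       folds = 20, seed = 1)
  expect_equal(nrow(cv$predictions), 20)
  expect_setequal(cv$predictions$id, recs$id)
  expect_equal(sort(table(cv$predictions$fold)), sort(rep(1L, 20)),
               ignore_attr = TRUE)

  cv2 <- cross_validate(recs, "gbr1",
                        gbr_config(n_estimators = 30, min_samples_leaf = 2),
                        folds = 20, seed = 1)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(cross_validate(recs, "gbr1", folds = 1), "folds")
  expect_error(cross_validate(recs[1:5, ], "gbr1", folds = 10),
               "at least as many")
})

test_that("repeats repartition independently and pool per repeat", {
  recs <- make_planted_dataset(40, schema = "gbr1", seed = 15)
  cv <- cross_validate(recs, "gbr1",
                       gbr_config(n_estimators = 30, min_samples_leaf = 2),
                       folds = 4, repeats = 2, seed = 2)
  expect_equal(nrow(cv$predictions), 80)
  byrep <- split(cv$predictions$fold, cv$predictions$rep)
  expect_false(identical(byrep[[1]], byrep[[2]]))
  expect_equal(nrow(cv$fold_metrics), 8)
})
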