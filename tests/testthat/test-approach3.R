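test_that("feature tables carry 18 features and normalized lengths", {
  coh <- small_cohort(n_subjects = 4, total_beats = 32, noise_sd = 0, seed = 9)
  s <- coh[[1]]
  pb <- delineate_record(s$prone)
  sb <- delineate_record(s$supine)
  tab <- build_feature_table(pb[[1]], sb[[1]], s$covariates, "QRS")
  feat_cols <- grep("^prone_|^male$|^age$|^height$|^weight$|^chest$|^waist$",
                    names(tab), value = TRUE)
  expect_length(feat_cols, 18)
  expect_equal(nrow(tab), 60)
  expect_false(anyNA(tab[feat_cols]))
  expect_equal(nrow(build_feature_table(pb[[1]], sb[[1]], s$covariates, "PR")), 50)
  expect_equal(nrow(build_feature_table(pb[[1]], sb[[1]], s$covariates, "STT")), 200)

  cov_bad <- s$covariates
  cov_bad$waist <- NULL
  expect_error(build_feature_table(pb[[1]], sb[[1]], cov_bad, "QRS"),
               class = "pronecg_missingcovariate")
  expect_error(build_feature_table(s$prone, sb[[1]], s$covariates, "QRS"),
               class = "pronecg_undelineatedbeat")
})

test_that("participant splits are exact, disjoint and reproducible", {
  ids <- sprintf("S%03d", 1:70)
  sp <- participant_split(ids, 0.8, seed = 1)
  expect_length(sp$train, 56)
  expect_length(sp$test, 14)
  for (seed in 1:5) {
    s2 <- participant_split(ids, 0.8, seed = seed)
    expect_length(intersect(s2$train, s2$test), 0)
    expect_setequal(c(s2$train, s2$test), ids)
  }
  expect_identical(participant_split(ids, 0.8, seed = 3),
                   participant_split(ids, 0.8, seed = 3))
  expect_error(participant_split(ids, 1.2), class = "pronecg_configerror")
})

test_that("the leakage guard rejects overlapping splits", {
  expect_error(pronecg:::assert_no_leakage(c("a", "b"), c("b", "c")),
               class = "pronecg_leakageerror")
})

test_that("omitted hyperparameters fall back to the published defaults", {
  tab <- random_feature_table(300, seed = 2)
  tabs <- list(QRS = tab)
  rf <- train_segment_models(tabs, "random_forest", seed = 1,
                             leads = "V1", segments = "QRS")
  expect_equal(rf$params$ntree, 500)
  expect_equal(rf$params$mtry, 6)
  xgb <- train_segment_models(tabs, "gradient_boosted_trees", seed = 1,
                              leads = "V1", segments = "QRS")
  expect_equal(xgb$params$eta, 0.1)
  expect_equal(xgb$params$max_depth, 2)
  expect_equal(xgb$params$gamma, 0.001)
  expect_equal(xgb$params$colsample_bytree, 0.4)
  expect_equal(xgb$params$nrounds, 500)
})

test_that("both ensembles learn the noise-free conversion on held-out subjects", {
  coh <- small_cohort(n_subjects = 12, total_beats = 100, noise_sd = 0, seed = 7)
  tabs <- small_tables(coh)
  sp <- participant_split(unique(tabs$QRS$group), 0.8, seed = 3)
  held <- tabs$QRS[tabs$QRS$group %in% sp$test, ]
  r2 <- list()
  for (algo in c("random_forest", "gradient_boosted_trees")) {
    bundle <- train_segment_models(
      tabs, algo, params = list(ntree = 200, nrounds = 400), seed = 3,
      train_ids = sp$train, test_ids = sp$test, segments = "QRS")
    for (lead in paste0("V", 1:5)) {
      pred <- predict_segment(bundle, held, "QRS", lead)
      r2[[paste(algo, lead)]] <-
        regression_metrics(held[[paste0("target_", lead)]], pred)$r2
      expect_gte(r2[[paste(algo, lead)]], 0.95)
    }
  }
  # forest and boosting agree closely on this recoverable problem
  for (lead in paste0("V", 1:5)) {
    expect_lt(abs(r2[[paste("random_forest", lead)]] -
                  r2[[paste("gradient_boosted_trees", lead)]]), 0.05)
  }
})

test_that("training is deterministic under a fixed seed", {
  tab <- random_feature_table(400, seed = 4)
  tabs <- list(QRS = tab)
  newdata <- random_feature_table(50, seed = 5)
  for (algo in c("random_forest", "gradient_boosted_trees")) {
    b1 <- train_segment_models(tabs, algo, params = list(ntree = 100,
                                                         nrounds = 100),
                               seed = 11, leads = "V1", segments = "QRS")
    b2 <- train_segment_models(tabs, algo, params = list(ntree = 100,
                                                         nrounds = 100),
                               seed = 11, leads = "V1", segments = "QRS")
    expect_identical(predict_segment(b1, newdata, "QRS", "V1"),
                     predict_segment(b2, newdata, "QRS", "V1"))
  }
})

test_that("grouped cross-validation partitions subjects and summarizes folds", {
  coh <- small_cohort(n_subjects = 12, total_beats = 100, noise_sd = 0, seed = 7)
  tabs <- small_tables(coh)
  cv <- crossvalidate(tabs["QRS"], algo = "gradient_boosted_trees",
                      params = list(nrounds = 60), k = 4, seed = 2,
                      leads = "V1", segments = "QRS")
  expect_equal(nrow(cv$folds), 4)
  # the reported mean must equal recomputation from the per-fold values
  expect_equal(cv$summary$r2_mean, mean(cv$folds$r2))
  expect_equal(cv$summary$r2_sd, sd(cv$folds$r2))
  expect_error(crossvalidate(tabs["QRS"], k = 13, leads = "V1",
                             segments = "QRS"),
               class = "pronecg_toomanyfolds")
})

test_that("full-beat prediction is smooth, segment-local and accurate", {
  coh <- small_cohort(n_subjects = 12, total_beats = 100, noise_sd = 0, seed = 7)
  tabs <- small_tables(coh)
  sp <- participant_split(unique(tabs$QRS$group), 0.8, seed = 3)
  bundle <- train_segment_models(tabs, "random_forest",
                                 params = list(ntree = 150), seed = 3,
                                 train_ids = sp$train)
  s <- Filter(function(x) x$subject_id %in% sp$test, coh)[[1]]
  pb <- delineate_record(s$prone)
  beat <- predict_full_beat(bundle, pb[[2]], s$covariates)
  fid <- beat$fid
  sig <- beat$rec$signals[, "V2"]
  # zero outside the beat, no large jumps at segment boundaries
  expect_equal(sig[fid$p_onset - 1], 0)
  expect_equal(sig[fid$t_offset + 1], 0)
  for (b in c(fid$qrs_onset, fid$qrs_offset)) {
    expect_lt(abs(sig[b] - sig[b - 1]), 0.05)
  }
  # accuracy against the true supine record within the beat span
  span <- fid$p_onset:(fid$t_offset - 1)
  for (lead in paste0("V", 1:5)) {
    r2 <- regression_metrics(s$supine$signals[span, lead],
                             beat$rec$signals[span, lead])$r2
    expect_gte(r2, 0.95)
  }
  # swapping only the ST-T model leaves QRS samples outside the blend alone
  bundle2 <- bundle
  bundle2$models$STT <- train_segment_models(
    tabs, "random_forest", params = list(ntree = 40), seed = 99,
    train_ids = sp$train, segments = "STT")$models$STT
  beat2 <- predict_full_beat(bundle2, pb[[2]], s$covariates)
  qrs_core <- fid$qrs_onset:(fid$qrs_offset - 1)
  expect_identical(beat$rec$signals[qrs_core, "V3"],
                   beat2$rec$signals[qrs_core, "V3"])
  expect_gt(max(abs(beat$rec$signals[, "V3"] - beat2$rec$signals[, "V3"])), 0)
})

test_that("feature importance ranks the truly informative feature first", {
  tab <- random_feature_table(600, target_from = "prone_V4", seed = 6)
  tabs <- list(QRS = tab)
  for (algo in c("random_forest", "gradient_boosted_trees")) {
    bundle <- train_segment_models(tabs, algo,
                                   params = list(ntree = 200, nrounds = 200),
                                   seed = 1, leads = "V1", segments = "QRS")
    imp <- feature_importance(bundle)
    expect_true(all(imp$importance >= 0))
    expect_true(all(is.finite(imp$importance)))
    expect_identical(imp$feature[1], "prone_V4")
    expect_identical(feature_importance(bundle), imp)  # deterministic
  }
})
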