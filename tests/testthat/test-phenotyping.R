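test_that("feature matrix assembly is rectangular, ordered and subsettable", {
  feats <- make_synth_features(n_per_group = 2, weeks = 1:2, n_feat = 3)
  m <- assemble_feature_matrix(feats)
  expect_equal(dim(m$values), c(4, 6)) # 4 cultures x (2 weeks x 3 features)
  expect_equal(m$columns$week, rep(1:2, each = 3))
  expect_false(any(is.na(m$values)))

  fc <- attr(feats, "feature_class")
  fc[c("f01", "f02")] <- "burst"
  attr(feats, "feature_class") <- fc
  mb <- assemble_feature_matrix(feats, classes = "burst")
  expect_true(all(mb$columns$class == "burst"))
  expect_equal(ncol(mb$values), 4)
  expect_error(assemble_feature_matrix(feats, classes = "nope"),
               class = "InvalidSelection")
})

test_that("missing culture-weeks are imputed from same-group medians and flagged", {
  feats <- make_synth_features(n_per_group = 3, weeks = 1:2, n_feat = 2)
  drop <- which(feats$culture_id == "WT_01" & feats$week == 2)
  feats2 <- feats[-drop, ]
  attr(feats2, "feature_class") <- attr(feats, "feature_class")
  m <- assemble_feature_matrix(feats2)
  i <- which(m$rows$culture_id == "WT_01")
  j <- which(m$columns$week == 2 & m$columns$feature == "f01")
  expect_true(m$imputed[i, j])
  same_group <- feats2[feats2$group == "WT" & feats2$week == 2, "f01"]
  expect_equal(m$values[i, j], median(same_group))
})

test_that("batchwise z-scoring uses train-only parameters", {
  feats <- make_synth_features(n_per_group = 3, weeks = 1, n_feat = 2)
  m <- assemble_feature_matrix(feats)
  m$rows$batch <- "b1"
  m$values[, 1] <- c(1, 2, 3, 10, 20, 30)
  m$values[, 2] <- 5 # constant column
  nz <- batch_zscore(m, train_rows = 1:3)
  expect_equal(nz$values[1:3, 1], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(nz$values[, 2], rep(0, 6), ignore_attr = TRUE)
  # test rows transformed with the train mean/sd (1..3), not their own
  expect_equal(nz$values[4:6, 1], c(8, 18, 28), ignore_attr = TRUE)
  # train rows have per-batch mean 0 / sd 1 for non-degenerate columns
  expect_equal(mean(nz$values[1:3, 1]), 0)
  expect_equal(sd(nz$values[1:3, 1]), 1)
})

test_that("LOO classification separates designed groups and not identical ones", {
  feats <- make_synth_features(effect = 3, seed = 5)
  m <- assemble_feature_matrix(feats)
  res <- classify_loo(m, seed = 3)
  expect_gte(res$accuracy, 0.9)
  expect_equal(nrow(res$predictions), 20)

  # identical cultures with opposite labels cannot be learned
  feats2 <- make_synth_features(n_per_group = 2, weeks = 1, effect = 0,
                                noise = 0, seed = 1)
  m2 <- assemble_feature_matrix(feats2)
  m2$values[] <- 1
  m2$rows$batch <- "b"
  res2 <- suppressWarnings(classify_loo(m2, seed = 1))
  expect_lte(res2$accuracy, 0.5)

  expect_error(classify_loo(m, labels = rep("A", 20)),
               class = "InvalidLabels")
})

test_that("permutation importance singles out the informative feature", {
  feats <- make_synth_features(effect = 3, n_feat = 8, seed = 7)
  m <- assemble_feature_matrix(feats)
  res <- classify_loo(m, seed = 11)
  imp <- permutation_importance(res$model)
  expect_equal(sort(imp$feature), sort(sprintf("f%02d", 1:8)))
  expect_equal(imp$feature[1], "f01")
  by_wk <- permutation_importance(res$model, by_time = TRUE)
  expect_equal(nrow(by_wk), ncol(m$values))
})

test_that("hyperparameter search is seeded and returns the argmax", {
  feats <- make_synth_features(n_per_group = 5, weeks = 1:2, effect = 2,
                               seed = 9)
  m <- assemble_feature_matrix(feats)
  one <- tune_hyperparameters(m, budget = 1, seed = 4)
  expect_equal(nrow(one$trace), 1)
  a <- tune_hyperparameters(m, budget = 5, seed = 4)
  b <- tune_hyperparameters(m, budget = 5, seed = 4)
  expect_identical(a$best, b$best)
  expect_equal(a$best$score, max(a$trace$score))
  expect_error(tune_hyperparameters(m, budget = 0), class = "InvalidParameter")
})

test_that("age regression beats the mean baseline only when features carry age", {
  feats <- make_synth_features(effect = 0, age_slope = 0.2, noise = 0.3,
                               seed = 13)
  rm_ <- recording_feature_matrix(feats)
  res <- predict_age(rm_, n_trees = 200, seed = 2)
  expect_lt(res$mae_days, res$baseline_mae_days)
  expect_equal(sort(res$per_week$week), sort(unique(feats$week)))

  null_feats <- make_synth_features(effect = 0, age_slope = 0, seed = 14)
  null_res <- predict_age(recording_feature_matrix(null_feats),
                          n_trees = 200, seed = 2)
  expect_gt(null_res$mae_days, 0.7 * null_res$baseline_mae_days)
})

test_that("pretrained models transfer with schema checks and optimism", {
  feats <- make_synth_features(effect = 3, seed = 21)
  m <- assemble_feature_matrix(feats)
  res <- classify_loo(m, seed = 8)
  self <- apply_pretrained(res$model, m)
  train_acc <- mean(self$predicted == m$rows$group)
  expect_gte(train_acc, res$accuracy)

  # treated cultures generated with the opposite group parameters flip
  flipped <- make_synth_features(effect = 3, seed = 22,
                                 groups = c("A53T", "WT"))
  flipped$treatment <- "LNA"
  attr(flipped, "feature_class") <- attr(feats, "feature_class")
  mf <- assemble_feature_matrix(flipped)
  pred <- apply_pretrained(res$model, mf)
  # cultures labeled WT here carry the designed A53T effect and vice versa
  expect_gte(mean(pred$predicted != mf$rows$group), 0.8)
  expect_true(all(mf$rows$batch %in% attr(pred, "batch_flags")))

  m_sub <- m
  m_sub$values <- m$values[, -1, drop = FALSE]
  expect_error(apply_pretrained(res$model, m_sub), class = "SchemaError")
})

test_that("embedding purity reflects group separation", {
  feats <- make_synth_features(effect = 4, n_feat = 4, seed = 31)
  m <- assemble_feature_matrix(feats)
  emb <- embed_and_purity(m, seed = 6)
  expect_gte(emb$purity, 0.95)
  expect_equal(nrow(emb$coords), 20)

  one <- embed_and_purity(m, labels = rep("WT", 20), k = 2, seed = 6)
  expect_equal(one$purity, 1.0)
  expect_error(embed_and_purity(m, k = 50), class = "InvalidParameter")

  expect_equal(cluster_purity(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(cluster_purity(c(1, 1, 1, 1), c("a", "a", "b", "b")), 0.5)
})
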