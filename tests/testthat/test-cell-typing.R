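# two-archetype simulated cultures: narrow small vs broad large waveforms
archetype_sim <- function(seed = 1, n_units = 40, n_cultures = 2) {
  cfg <- sim_config(n_cultures_per_group = n_cultures, groups = "WT",
                    weeks = 1, n_units = n_units, duration_s = 120,
                    waveform_jitter = 0.03, group_effects = list(),
                    developmental_trend = list())
  simulate_culture_series(cfg, seed = seed)
}

test_that("Louvain clustering recovers the waveform archetypes exactly", {
  sim <- archetype_sim(seed = 2)
  tab <- unit_feature_table(sim$recordings, mode = "waveform")
  cl <- cluster_units(tab, seed = 5)
  truth <- merge(cl$units, sim$truth$units,
                 by = c("culture_id", "unit_id"))
  expect_equal(mclust::adjustedRandIndex(truth$cluster, truth$archetype), 1)
  expect_true(all(diff(cl$sizes) <= 0)) # relabeled by descending size

  cl2 <- cluster_units(tab, seed = 5)
  expect_identical(cl$units$cluster, cl2$units$cluster)
})

test_that("cluster labels are stable under row permutation of the table", {
  sim <- archetype_sim(seed = 3)
  tab <- unit_feature_table(sim$recordings, mode = "waveform")
  cl1 <- cluster_units(tab, seed = 7)
  perm <- withr::with_seed(1, sample(nrow(tab)))
  cl2 <- cluster_units(tab[perm, ], seed = 7)
  m <- merge(cl1$units, cl2$units, by = c("culture_id", "unit_id"))
  expect_equal(m$cluster.x, m$cluster.y)
})

test_that("near-identical units collapse to one cluster; small inputs error", {
  tab <- data.frame(culture_id = "c", unit_id = 1:20,
                    a = rep(1, 20) + withr::with_seed(1, rnorm(20, 0, 1e-9)),
                    b = rep(2, 20))
  cl <- cluster_units(tab, k_neighbors = 5, seed = 1)
  expect_equal(length(unique(cl$units$cluster)), 1)
  expect_error(cluster_units(tab[1:5, ], seed = 1), class = "InvalidParameter")
  expect_error(cluster_units(tab, k_neighbors = 30, seed = 1),
               class = "InvalidParameter")
})

test_that("the cluster classifier is near-diagonal on separated archetypes", {
  sim <- archetype_sim(seed = 4)
  tab <- unit_feature_table(sim$recordings, mode = "waveform")
  cl <- cluster_units(tab, seed = 2)
  fit <- train_cluster_classifier(tab, cl, seed = 9)
  expect_gte(fit$cv_accuracy, 0.95)
  off_diag <- sum(fit$confusion) - sum(diag(fit$confusion))
  expect_lte(off_diag / sum(fit$confusion), 0.05)
  expect_setequal(fit$importance$feature, fit$schema)

  # shuffled labels are unlearnable: accuracy near class frequency
  shuffled <- withr::with_seed(3, sample(cl$units$cluster))
  fit0 <- train_cluster_classifier(tab, shuffled, seed = 9)
  freq <- max(table(shuffled)) / length(shuffled)
  expect_lt(fit0$cv_accuracy, freq + 0.15)
})

test_that("composition prediction is normalized and archetype-faithful", {
  sim <- archetype_sim(seed = 6, n_cultures = 2)
  tab <- unit_feature_table(sim$recordings, mode = "waveform")
  cl <- cluster_units(tab, seed = 2)
  fit <- train_cluster_classifier(tab, cl, seed = 3)

  comp <- predict_composition(fit$model, tab)
  sums <- tapply(comp$fraction, comp$culture_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # a culture drawn from a single archetype maps to one dominant cluster
  cfg1 <- sim_config(n_cultures_per_group = 1, groups = "WT", weeks = 1,
                     n_units = 25, duration_s = 120, waveform_jitter = 0.03,
                     archetype_mix = c(1, 0), group_effects = list(),
                     developmental_trend = list())
  pure <- simulate_culture_series(cfg1, seed = 8)
  ptab <- unit_feature_table(pure$recordings, mode = "waveform")
  pcomp <- predict_composition(fit$model, ptab)
  expect_gte(max(pcomp$fraction), 0.9)

  expect_error(predict_composition(fit$model, tab[0, ]), class = "EmptyInput")
  expect_error(predict_composition(fit$model, tab[, 1:4]),
               class = "SchemaError")
})

test_that("perturbation responses are mapped with the rate-ratio criterion", {
  base <- test_recording(list(test_unit(1L, seq(0.1, 10, by = 0.1)),
                              test_unit(2L, seq(0.1, 10, by = 0.2))))
  post <- test_recording(list(test_unit(1L, seq(0.1, 10, by = 0.2)),
                              test_unit(2L, seq(0.1, 10, by = 0.2))))
  res <- map_perturbation_response(base, post)
  u1 <- res$units[res$units$unit_id == 1, ]
  expect_equal(u1$fr_ratio, 0.5, tolerance = 0.02)
  expect_true(u1$responder)
  expect_false(res$units$responder[res$units$unit_id == 2])

  # responder calling is monotone in the threshold
  frac <- vapply(c(0.05, 0.2, 0.4, 0.6),
                 function(th) map_perturbation_response(
                   base, post, decrease_threshold = th)$responder_fraction,
                 numeric(1))
  expect_true(all(diff(frac) <= 0))
})

test_that("designed responder fractions are recovered from simulated QP data", {
  cfg <- sim_config(n_cultures_per_group = 1, groups = "WT", weeks = 1,
                    n_units = 40, duration_s = 300, burst_rate_per_min = 0,
                    baseline_rate_hz = 3,
                    waveform_archetypes = within(default_archetypes(),
                                                 responder_prob <- c(0.5, 0.5)),
                    group_effects = list(), developmental_trend = list())
  sim <- simulate_culture_series(cfg, seed = 12)
  rec <- sim$recordings[[1]]
  post <- simulate_perturbation(rec, sim$truth, 0.5, seed = 19)
  res <- map_perturbation_response(rec, post)
  designed <- mean(sim$truth$units$responder)
  expect_lt(abs(res$responder_fraction - designed), 0.1)
})
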