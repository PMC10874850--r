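test_that("population binning sums units and conserves spikes", {
  u1 <- test_unit(1L, c(0.35, 2.0))
  u2 <- test_unit(2L, c(0.31, 5.0))
  rec <- test_recording(list(u1, u2), duration = 10)
  pop <- bin_population(rec)
  expect_equal(pop$counts[4], 2) # both units spike in bin 4 ([0.3, 0.4))
  expect_equal(sum(pop$counts), 4)
  expect_equal(length(pop$counts), 100)
})

test_that("smoothed population rate tracks the generating burst envelope", {
  cfg <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 25,
                    duration_s = 300, burst_rate_per_min = 6, burst_gain = 8,
                    group_effects = list(), developmental_trend = list())
  sim <- simulate_culture_series(cfg, seed = 17)
  rec <- sim$recordings[[1]]
  pop <- bin_population(rec)
  p <- meaphys:::effective_params(cfg, "WT", 1, 1, 1)
  env <- withr::with_seed(meaphys:::child_seed(meaphys:::child_seed(17, 1), 1),
                          meaphys:::burst_envelope(300, p))
  env_binned <- env$e[round(seq(1, length(env$e), length.out = length(pop$counts)))]
  expect_gt(cor(pop$rate_hz, env_binned), 0.9)
})

test_that("burst detection finds injected bursts and their spacing", {
  cfg <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 25,
                    duration_s = 300, burst_rate_per_min = 2, burst_gain = 8,
                    burst_ibi_shape = 50, group_effects = list(),
                    developmental_trend = list())
  sim <- simulate_culture_series(cfg, seed = 23)
  rec1 <- sim$recordings[[1]]
  bs <- detect_network_bursts(bin_population(rec1))
  truth <- sim$truth$bursts[sim$truth$bursts$culture_id == rec1$culture_id, ]
  expect_lt(abs(nrow(bs$bursts) - nrow(truth)), 2)
  expect_lt(abs(bs$MIB - mean(diff(truth$start_s))) / mean(diff(truth$start_s)),
            0.1)
  expect_true(all(bs$bursts$start_s < bs$bursts$peak_s))
  expect_true(all(bs$bursts$peak_s <= bs$bursts$end_s))
})

test_that("stationary population and empty input yield no bursts", {
  cfg <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 25,
                    duration_s = 300, burst_rate_per_min = 0,
                    group_effects = list(), developmental_trend = list())
  rec <- simulate_culture_series(cfg, seed = 31)$recordings[[1]]
  bs <- detect_network_bursts(bin_population(rec))
  expect_equal(nrow(bs$bursts), 0)
  expect_true(is.na(bs$MIB)) # not-available, never zero

  empty <- test_recording(list(test_unit(1L, c(1, 2))), duration = 10)
  empty$units <- list()
  pop0 <- structure(list(counts = rep(0L, 100), rate_hz = rep(0, 100),
                         bin_s = 0.1, n_units = 0, duration_s = 10),
                    class = "mea_population")
  expect_equal(nrow(detect_network_bursts(pop0)$bursts), 0)
})

test_that("STTC matches closed forms and is symmetric and scale-invariant", {
  st <- withr::with_seed(5, sort(runif(200, 0, 60)))
  expect_equal(sttc(st, st, 60), 1)

  # worked example: single distant spikes
  expect_equal(sttc(1.0, 5.0, 10, delta_t_s = 0.1), -0.02)

  a <- poisson_train(3, 30, 101)
  b <- poisson_train(3, 30, 102)
  expect_equal(sttc(a, b, 30), sttc(b, a, 30))
  c_ <- 2.5
  expect_equal(sttc(a * c_, b * c_, 30 * c_, delta_t_s = 0.01 * c_),
               sttc(a, b, 30), tolerance = 1e-12)
})

test_that("CCG jitter test calls a causal pair and skips a lone unit", {
  a <- poisson_train(5, 120, 201)
  b <- sort(a + 0.002) # B fires 2 ms after every A spike
  rec <- test_recording(list(test_unit(1L, a), test_unit(2L, b)),
                        duration = 121)
  g <- infer_connectivity_ccg(rec, n_jitter = 50, seed = 3)
  expect_true(g$adjacency[1, 2])
  expect_true(g$directed)

  solo <- test_recording(list(test_unit(1L, a)), duration = 121)
  g1 <- infer_connectivity_ccg(solo, seed = 3)
  expect_equal(sum(g1$adjacency), 0)
})

test_that("graph features match closed forms and the igraph oracle", {
  k4 <- structure(list(nodes = 1:4,
                       adjacency = matrix(TRUE, 4, 4) & !diag(4),
                       directed = FALSE), class = "mea_graph")
  expect_equal(compute_graph_features(k4), list(DEC = 1, GEC = 1))

  path3 <- structure(list(nodes = 1:3,
                          adjacency = matrix(c(F, T, F, T, F, T, F, T, F), 3),
                          directed = FALSE), class = "mea_graph")
  f <- compute_graph_features(path3)
  expect_equal(f$DEC, 2 / 3)
  expect_equal(f$GEC, (1 + 1 + 0.5) / 3)

  edgeless <- structure(list(nodes = 1:5, adjacency = matrix(FALSE, 5, 5),
                             directed = FALSE), class = "mea_graph")
  expect_equal(compute_graph_features(edgeless), list(DEC = 0, GEC = 0))

  for (seed in 1:10) {
    n <- 8
    A <- withr::with_seed(seed, matrix(runif(n * n) < 0.3, n, n))
    A <- A | t(A); diag(A) <- FALSE
    g <- structure(list(nodes = 1:n, adjacency = A, directed = FALSE),
                   class = "mea_graph")
    ours <- compute_graph_features(g)
    ig <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(ours$DEC, igraph::edge_density(ig))
    expect_equal(ours$GEC, igraph::global_efficiency(ig))
  }
})

test_that("network time-series features equal the single-unit series for one unit", {
  st <- poisson_train(4, 60, 301)
  rec <- test_recording(list(test_unit(1L, st)), duration = 60)
  pop <- bin_population(rec)
  nts <- extract_network_timeseries_features(pop)
  sts <- extract_timeseries_features(bin_spikes(st, 60))
  expect_equal(unname(unlist(nts)), unname(unlist(sts)))

  # population envelope with period 20 bins: nRF = 0.05 cycles/bin
  lam <- 2 + 1.8 * sin(2 * pi * (1:600) / 20)
  counts <- withr::with_seed(9, rpois(600, lam))
  f <- extract_timeseries_features(counts)
  expect_equal(f$RF, 1 / 20, tolerance = 1 / 600 + 1e-9)
})
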