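test_that("simulation is deterministic and burst-free when configured so", {
  cfg <- sim_config(n_cultures_per_group = 1, weeks = 1:2, n_units = 6,
                    duration_s = 60)
  a <- simulate_culture_series(cfg, seed = 42)
  b <- simulate_culture_series(cfg, seed = 42)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$truth$bursts, b$truth$bursts)

  quiet <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 6,
                      duration_s = 60, burst_rate_per_min = 0,
                      group_effects = list(), developmental_trend = list())
  sq <- simulate_culture_series(quiet, seed = 1)
  expect_equal(nrow(sq$truth$bursts), 0)
})

test_that("burst windows follow the generating gamma process", {
  # 6 bursts/min over 10 min: ~60 windows, mean IBI ~ 10 s within 20%
  cfg <- sim_config(n_cultures_per_group = 1, groups = "WT", weeks = 1,
                    n_units = 5, duration_s = 600, burst_rate_per_min = 6,
                    group_effects = list(), developmental_trend = list())
  truth <- simulate_culture_series(cfg, seed = 2)$truth
  nb <- nrow(truth$bursts)
  expect_gt(nb, 45)
  expect_lt(nb, 75)
  ibi <- mean(diff(truth$bursts$start_s))
  expect_lt(abs(ibi - 10) / 10, 0.2)
  expect_true(all(truth$bursts$start_s < truth$bursts$peak_s))
  expect_true(all(truth$bursts$peak_s <= truth$bursts$end_s))
  expect_true(all(diff(truth$bursts$start_s) > 0))
})

test_that("realized firing rates converge to the configured rates", {
  cfg <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 12,
                    duration_s = 900, burst_rate_per_min = 0,
                    unit_rate_sd_log = 0, baseline_rate_hz = 2,
                    group_effects = list(), developmental_trend = list(),
                    batch_rate_sd_log = 0)
  rec <- simulate_culture_series(cfg, seed = 9)$recordings[[1]]
  rates <- vapply(rec$units,
                  function(u) length(u$spike_times_s) / rec$duration_s,
                  numeric(1))
  expect_true(all(abs(rates - 2) / 2 < 0.1))
})

test_that("the burst envelope integrates to its closed form", {
  p <- list(burst_rate_per_min = 2, burst_ibi_shape = 5, burst_rise_s = 0.3,
            burst_decay_s = 1, burst_gain = 6)
  env <- withr::with_seed(3, meaphys:::burst_envelope(300, p))
  n_bursts <- nrow(env$bursts)
  r <- p$burst_rise_s; d <- p$burst_decay_s
  t_pk <- r * d / (d - r) * log(d / r)
  h_max <- exp(-t_pk / d) - exp(-t_pk / r)
  expected <- n_bursts * (p$burst_gain - 1) * (d - r) / h_max
  integral <- sum(env$e - 1) * env$dt
  expect_lt(abs(integral - expected) / expected, 0.05)
})

test_that("regularity controls the ISI coefficient of variation", {
  for (reg in c(0, 0.75)) {
    cfg <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 5,
                      duration_s = 600, burst_rate_per_min = 0,
                      baseline_rate_hz = 4, regularity = reg,
                      group_effects = list(), developmental_trend = list())
    rec <- simulate_culture_series(cfg, seed = 21)$recordings[[1]]
    cvs <- vapply(rec$units, function(u) {
      isi <- diff(u$spike_times_s)
      sd(isi) / mean(isi)
    }, numeric(1))
    expect_lt(abs(mean(cvs) - sqrt(1 - reg)), 0.1)
  }
})

test_that("zero group effect leaves group rate distributions indistinguishable", {
  pvals <- vapply(1:5, function(seed) {
    cfg <- sim_config(n_cultures_per_group = 8, weeks = 1, n_units = 8,
                      duration_s = 60, group_effects = list(),
                      developmental_trend = list(), batch_rate_sd_log = 0)
    sim <- simulate_culture_series(cfg, seed = seed)
    rate_of <- function(rec) mean(vapply(rec$units, function(u)
      length(u$spike_times_s) / rec$duration_s, numeric(1)))
    rates <- vapply(sim$recordings, rate_of, numeric(1))
    grp <- vapply(sim$recordings, function(r) r$group, character(1))
    suppressWarnings(ks.test(rates[grp == "WT"],
                             rates[grp == "A53T"]))$p.value
  }, numeric(1))
  # a single tail event among seeds is compatible with the null
  expect_gte(sum(pvals > 0.01), 4)
})

test_that("perturbation thins responders only, by the configured ratio", {
  cfg <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 10,
                    duration_s = 300, burst_rate_per_min = 0,
                    baseline_rate_hz = 4, group_effects = list(),
                    developmental_trend = list())
  sim <- simulate_culture_series(cfg, seed = 6)
  rec <- sim$recordings[[1]]
  post <- simulate_perturbation(rec, sim$truth, 0.5, seed = 13)
  ut <- sim$truth$units
  for (i in seq_along(rec$units)) {
    n0 <- length(rec$units[[i]]$spike_times_s)
    n1 <- length(post$units[[i]]$spike_times_s)
    resp <- ut$responder[match(rec$units[[i]]$unit_id, ut$unit_id)]
    if (resp) {
      expect_lt(abs(n1 / n0 - 0.5), 0.1) # binomial thinning around ratio
    } else {
      expect_identical(post$units[[i]]$spike_times_s,
                       rec$units[[i]]$spike_times_s)
    }
  }
  same <- simulate_perturbation(rec, sim$truth, 1.0, seed = 13)
  expect_identical(same$units, rec$units)
  expect_error(simulate_perturbation(rec, sim$truth, 1.5, seed = 1),
               class = "InvalidParameter")
})

test_that("degenerate configurations are rejected", {
  cfg <- sim_config(n_cultures_per_group = 1, weeks = 1, n_units = 3,
                    duration_s = 10, baseline_rate_hz = 0,
                    burst_rate_per_min = 0, group_effects = list(),
                    developmental_trend = list())
  expect_error(simulate_culture_series(cfg, seed = 1),
               class = "DegenerateConfig")
})
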