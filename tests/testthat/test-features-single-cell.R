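test_that("waveform features are read off the peak electrode", {
  # single -50 uV trough on electrode 7, zeros elsewhere
  tp <- matrix(0, 8, 60)
  tt <- (0:59) / 20 # ms at 20 kHz
  tp[7, ] <- -50 * exp(-(tt - 1.0)^2 / (2 * 0.1^2))
  u <- mea_unit(1L, c(0.1, 0.2), tp, cbind(seq_len(8) * 17.5, 0))
  f <- extract_waveform_features(u)
  expect_equal(f$trough_amplitude_uV, min(tp[7, ]))
  expect_equal(f$trough_amplitude_uV, -50)

  # constructed biphasic wave: trough -40 at 1.0 ms, peak +20 at 1.5 ms
  tp2 <- matrix(0, 2, 60)
  tp2[1, 21] <- -40 # sample 21 = 1.0 ms
  tp2[1, 31] <- 20  # sample 31 = 1.5 ms
  u2 <- mea_unit(2L, c(0.1, 0.2), tp2, cbind(c(0, 17.5), 0))
  f2 <- extract_waveform_features(u2)
  expect_equal(f2$trough_to_peak_ms, 0.5)
  expect_equal(f2$peak_trough_ratio, 0.5)
  expect_equal(f2$peak_amplitude_uV, 20)

  u3 <- mea_unit(3L, c(0.1), matrix(0, 2, 60), cbind(c(0, 17.5), 0))
  expect_error(extract_waveform_features(u3), class = "NoSignal")
})

test_that("waveform features recover the simulator's generating parameters", {
  cfg <- sim_config()
  um <- data.frame(trough_uv = 80, trough_to_peak_ms = 0.6,
                   half_width_ms = 0.25, spatial_decay_um = 30,
                   x_um = 0, y_um = 0) # exactly on electrode 1
  tp <- meaphys:::make_template(cfg, um)
  u <- mea_unit(1L, c(0.1, 0.2), tp$template, tp$positions)
  f <- extract_waveform_features(u, cfg$sampling_rate_hz)
  expect_lt(abs(f$trough_amplitude_uV - (-80)) / 80, 0.01)
  expect_lt(abs(f$trough_to_peak_ms - 0.6), 1000 / cfg$sampling_rate_hz)
  expect_lt(abs(f$half_width_ms - 0.25), 2 * 1000 / cfg$sampling_rate_hz)
  expect_lt(f$trough_amplitude_uV, 0)
  expect_gt(f$trough_to_peak_ms, 0)
})

test_that("spike-time features match closed forms", {
  dur <- 10
  f_reg <- extract_spike_time_features(seq(0.1, 9.9, by = 0.1), dur)
  expect_equal(f_reg$MIS, 0.1)
  expect_equal(f_reg$CVI, 0)

  f2 <- extract_spike_time_features(cumsum(c(1, 0.1, 0.3)), dur)
  expect_equal(f2$MIS, 0.2)
  expect_equal(f2$CVI, sd(c(0.1, 0.3)) / 0.2)
  expect_equal(round(f2$CVI, 4), 0.7071)

  # exponential ISIs: CVI ~ 1
  isi <- withr::with_seed(4, rexp(10000, rate = 5))
  f3 <- extract_spike_time_features(cumsum(isi), sum(isi) + 1)
  expect_lt(abs(f3$CVI - 1), 0.05)

  f4 <- extract_spike_time_features(c(1), dur)
  expect_true(is.na(f4$MIS) && is.na(f4$CVI))
  expect_equal(f4$firing_rate_hz, 0.1)
})

test_that("CVI is scale-invariant and MIS scales linearly", {
  st <- withr::with_seed(8, cumsum(rgamma(500, 2, 10)))
  f1 <- extract_spike_time_features(st, max(st) + 1)
  f2 <- extract_spike_time_features(st * 3, (max(st) + 1) * 3)
  expect_equal(f2$CVI, f1$CVI)
  expect_equal(f2$MIS, 3 * f1$MIS)
  expect_equal(f2$isi_pacf1, f1$isi_pacf1)
})

test_that("time-series metric examples hold", {
  # longest above-mean stretch on the literal example
  expect_equal(meaphys:::ts_pam(c(1, 1, 1, 0, 0, 0)), 3)

  # sinusoid with period 10 bins: RF at 0.1 cycles/bin
  x <- sin(2 * pi * (1:200) / 10) + withr::with_seed(1, rnorm(200, 0, 0.01))
  f <- extract_timeseries_features(x)
  expect_equal(f$RF, 0.1)

  # constant series: z-dependent metrics are flagged not-available
  fc <- extract_timeseries_features(rep(3, 100))
  expect_true(is.na(fc$SES))
  expect_true(is.na(fc$MD5))
  expect_true(is.na(fc$RF))
  expect_equal(fc$PAM, 0)

  expect_error(extract_timeseries_features(1:10), class = "InvalidParameter")
})

test_that("z-scored metrics are invariant to affine transforms of the series", {
  x <- oracle_test_series(7)
  a <- 3.7; b <- -11
  f1 <- extract_timeseries_features(x)
  f2 <- extract_timeseries_features(a * x + b)
  for (m in c("RF", "EAF", "PAM", "SES", "MD5", "MD10", "TRS", "PDE")) {
    expect_equal(f2[[m]], f1[[m]], tolerance = 1e-10, label = m)
  }
})

test_that("culture aggregation averages over units and tracks n", {
  tab <- data.frame(CVI = c(0.4, 0.6), MIS = c(1, 3))
  agg <- aggregate_culture(tab)
  expect_equal(agg$value[["CVI"]], 0.5)
  expect_equal(agg$n_units[["CVI"]], 2L)

  tab2 <- data.frame(CVI = c(0.4, 0.6, 0.8), isi_pacf1 = c(0.1, NA, 0.3))
  agg2 <- aggregate_culture(tab2)
  expect_equal(agg2$value[["isi_pacf1"]], 0.2)
  expect_equal(agg2$n_units[["isi_pacf1"]], 2L)

  tab3 <- tab[c(1, 1), ]
  expect_equal(aggregate_culture(tab3)$value[["CVI"]], 0.4)

  empty <- aggregate_culture(tab[0, ])
  expect_true(all(is.na(empty$value)))
})
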