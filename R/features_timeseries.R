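#' Bin spike times into a count series
#'
#' Bins are left-closed, right-open, anchored at t = 0; a final partial bin
#' is dropped, so the series has `floor(duration_s / bin_s)` entries.
#'
#' @param spike_times_s numeric spike times in seconds.
#' @param duration_s recording duration in seconds.
#' @param bin_s bin width in seconds (default 0.1, i.e. 100 ms).
#' @return Integer vector of per-bin spike counts.
#' @export
bin_spikes <- function(spike_times_s, duration_s, bin_s = 0.1) {
  n_bins <- floor(duration_s / bin_s)
  idx <- floor(spike_times_s / bin_s) + 1L
  tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
}

#' Names of the 22 time-series metrics
#' @return Character vector of metric abbreviations.
#' @export
timeseries_feature_names <- function() {
  c("RF", "RM", "EAF", "AMI", "SFR", "LPF", "MEF", "PAM", "EFD", "CCD",
    "TCT", "SES", "CFS", "SFD", "MD5", "MD10", "FMA", "FMI", "TRS", "TEA",
    "RFT", "PDE")
}

#' Extract the 22 time-series metrics from a binned count series
#'
#' The metric set spans distributional, autocorrelation, spectral,
#' symbolic-dynamics and forecasting properties of the binned activity, in
#' the spirit of canonical time-series feature collections. The series is
#' z-scored internally (sample sd) before every metric that operates on the
#' standardized series; `PAM` and `PDE` are defined on the raw counts (they
#' are invariant to affine rescaling anyway). A constant series yields `NA`
#' for every z-score-dependent metric.
#'
#' Definitions (z = z-scored series, x = raw series, n = length):
#' * `RF` — frequency (cycles/bin) of the periodogram maximum,
#'   `P(k/n) = |FFT(z)_k|^2 / n`, `k = 1..floor(n/2)`.
#' * `RM` — periodogram power at `RF`.
#' * `EAF` — smallest lag (bins) at which the autocorrelation function drops
#'   below `1/e`.
#' * `AMI` — automutual information (nats) at lag 1 from a 5x5 joint
#'   histogram with equal-width bins spanning the range of z.
#' * `SFR` — rescaled-range fluctuation analysis: the proportion of the
#'   log-spaced window-size axis before the breakpoint of the best
#'   two-segment linear fit to log F(tau) vs log tau, where F(tau) is the
#'   mean range of linearly detrended windows of the cumulative sum.
#' * `LPF` — fraction of periodogram power in the lowest fifth of
#'   frequencies.
#' * `MEF` — sample sd of the residuals of a rolling 3-sample-mean forecast.
#' * `PAM` — longest run of consecutive values above the series mean (bins).
#' * `EFD` — mean absolute difference between the density histogram
#'   (10 bins) of successive distances in the 2-D lag-`tau` embedding of z
#'   (`tau` = `EAF`, capped at `n/10`) and the exponential density with the
#'   same mean.
#' * `CCD` — ratio of the first zero-crossing lag of the ACF of the first
#'   difference of z to that of z itself (correlation length change under
#'   differencing).
#' * `TCT` — trace of the covariance matrix of the 3x3 tercile-symbol
#'   transition probability matrix of z.
#' * `SES` — Shannon entropy (nats) of a 10-bin equal-width histogram of z.
#' * `CFS` — centroid of the periodogram (power-weighted mean frequency,
#'   cycles/bin).
#' * `SFD` — as `SFR`, with F(tau) the root-mean-square detrended
#'   fluctuation (DFA) instead of the range.
#' * `MD5`, `MD10` — center of the modal bin of a 5-/10-bin equal-width
#'   histogram of z (ties averaged).
#' * `FMA` — first local minimum lag of the ACF.
#' * `FMI` — first local minimum lag of the Gaussian automutual information
#'   `-0.5 log(1 - rho(tau)^2)`, lags 1..40.
#' * `TRS` — time-reversibility statistic `mean(diff(z)^3)`.
#' * `TEA` — mean interval (bins) between successive extreme events, defined
#'   as bins with z > 1; `NA` with fewer than two events.
#' * `RFT` — exponential-fit rate of the per-window periodogram peak
#'   frequencies: slope of `log f_w` on window index over 5 equal windows.
#' * `PDE` — proportion of successive differences exceeding `0.04 * sd(x)`
#'   in absolute value.
#'
#' @param binned integer/numeric count series (>= 50 bins).
#' @param bin_s bin width in seconds (metadata only; all outputs are in
#'   bins / cycles-per-bin).
#' @return One-row data frame with the 22 metrics, named as in
#'   [timeseries_feature_names()].
#' @export
extract_timeseries_features <- function(binned, bin_s = 0.1) {
  x <- as.numeric(binned)
  n <- length(x)
  if (n < 50) {
    stop_mea("InvalidParameter", "series has %d bins; >= 50 required", n)
  }
  out <- setNames(rep(NA_real_, 22), timeseries_feature_names())
  out["PAM"] <- ts_pam(x)
  out["PDE"] <- ts_pde(x)
  z <- zscore(x)
  if (!anyNA(z)) {
    pg <- ts_periodogram(z)
    r <- acf_fft(z)
    out["RF"] <- pg$freq[which.max(pg$power)]
    out["RM"] <- max(pg$power)
    out["EAF"] <- ts_first_below(r, exp(-1))
    out["AMI"] <- ts_hist_ami(z, lag = 1L, n_bins = 5L)
    out["SFR"] <- ts_fluct_prop(z, method = "rsrange")
    out["LPF"] <- ts_low_power_fraction(pg)
    out["MEF"] <- ts_mean_forecast_sd(z, window = 3L)
    out["EFD"] <- ts_embed_expfit(z, tau = out[["EAF"]])
    out["CCD"] <- ts_corr_length_ratio(z, r)
    out["TCT"] <- ts_transition_trace(z)
    out["SES"] <- ts_shannon_entropy(z, n_bins = 10L)
    out["CFS"] <- sum(pg$freq * pg$power) / sum(pg$power)
    out["SFD"] <- ts_fluct_prop(z, method = "dfa")
    out["MD5"] <- ts_hist_mode(z, 5L)
    out["MD10"] <- ts_hist_mode(z, 10L)
    out["FMA"] <- ts_first_local_min(r)
    out["FMI"] <- ts_first_local_min(ts_gaussian_ami(z, 40L))
    out["TRS"] <- mean(diff(z)^3)
    out["TEA"] <- ts_extreme_spacing(z, threshold = 1)
    out["RFT"] <- ts_peak_freq_expfit(z, n_windows = 5L)
  }
  as.data.frame(as.list(out))
}

# ---- helpers (each implements exactly the documented definition) ----------

ts_periodogram <- function(z) {
  n <- length(z)
  K <- floor(n / 2)
  P <- Mod(stats::fft(z))^2 / n
  list(freq = (1:K) / n, power = P[2:(K + 1)])
}

# ACF with 1/n normalization for lags 1..floor(n/2), computed via FFT
# (zero-padded to a highly composite length).
acf_fft <- function(z) {
  n <- length(z)
  zc <- z - mean(z)
  m <- stats::nextn(2 * n)
  f <- stats::fft(c(zc, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(f)^2, inverse = TRUE))[1:(floor(n / 2) + 1)]
  (ac / ac[1])[-1]
}

ts_first_below <- function(r, level) {
  i <- which(r < level)
  if (length(i)) i[1] else NA_real_
}

# first zero crossing of the ACF
ts_first_zero <- function(r) {
  i <- which(r < 0)
  if (length(i)) i[1] else NA_real_
}

ts_first_local_min <- function(v) {
  if (length(v) < 2) return(NA_real_)
  i <- which(diff(v) > 0)
  if (length(i)) i[1] else NA_real_
}

ts_hist_ami <- function(z, lag, n_bins) {
  breaks <- seq(min(z), max(z), length.out = n_bins + 1)
  b <- pmin(pmax(findInterval(z, breaks, rightmost.closed = TRUE), 1L), n_bins)
  n <- length(z)
  i <- b[1:(n - lag)]
  j <- b[(1 + lag):n]
  joint <- table(factor(i, levels = 1:n_bins), factor(j, levels = 1:n_bins))
  p <- joint / sum(joint)
  pi_ <- rowSums(p)
  pj <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pi_, pj)[nz]))
}

ts_shannon_entropy <- function(z, n_bins) {
  breaks <- seq(min(z), max(z), length.out = n_bins + 1)
  b <- pmin(pmax(findInterval(z, breaks, rightmost.closed = TRUE), 1L), n_bins)
  p <- tabulate(b, n_bins) / length(z)
  -sum(p[p > 0] * log(p[p > 0]))
}

ts_hist_mode <- function(z, n_bins) {
  breaks <- seq(min(z), max(z), length.out = n_bins + 1)
  b <- pmin(pmax(findInterval(z, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(b, n_bins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mean(centers[counts == max(counts)])
}

ts_pam <- function(x) {
  above <- x > mean(x)
  if (!any(above)) return(0)
  runs <- rle(above)
  max(runs$lengths[runs$values])
}

ts_pde <- function(x) {
  s <- stats::sd(x)
  mean(abs(diff(x)) > 0.04 * s)
}

ts_mean_forecast_sd <- function(z, window) {
  n <- length(z)
  if (n <= window + 1) return(NA_real_)
  cs <- cumsum(c(0, z))
  pred <- (cs[(window + 1):n] - cs[1:(n - window)]) / window
  stats::sd(z[(window + 1):n] - pred)
}

ts_low_power_fraction <- function(pg) {
  k <- max(1L, floor(length(pg$power) / 5))
  sum(pg$power[1:k]) / sum(pg$power)
}

ts_gaussian_ami <- function(z, max_lag) {
  n <- length(z)
  lags <- 1:min(max_lag, n - 2)
  vapply(lags, function(tau) {
    rho <- stats::cor(z[1:(n - tau)], z[(1 + tau):n])
    -0.5 * log(max(1 - rho^2, .Machine$double.eps))
  }, numeric(1))
}

ts_extreme_spacing <- function(z, threshold) {
  ev <- which(z > threshold)
  if (length(ev) < 2) return(NA_real_)
  mean(diff(ev))
}

ts_corr_length_ratio <- function(z, r = acf_fft(z)) {
  t0 <- ts_first_zero(r)
  t1 <- ts_first_zero(acf_fft(diff(z)))
  if (is.na(t0) || is.na(t1)) return(NA_real_)
  t1 / t0
}

ts_transition_trace <- function(z) {
  q <- stats::quantile(z, c(1 / 3, 2 / 3), names = FALSE)
  s <- findInterval(z, q) + 1L
  n <- length(s)
  joint <- table(factor(s[-n], levels = 1:3), factor(s[-1], levels = 1:3))
  M <- unclass(joint / sum(joint))
  sum(diag(stats::cov(M)))
}

ts_embed_expfit <- function(z, tau) {
  n <- length(z)
  tau <- if (is.na(tau)) 1L else as.integer(min(max(tau, 1), floor(n / 10)))
  a <- z[1:(n - tau)]
  b <- z[(1 + tau):n]
  d <- sqrt(diff(a)^2 + diff(b)^2)
  if (!length(d) || max(d) == 0) return(NA_real_)
  breaks <- seq(0, max(d), length.out = 11)
  counts <- tabulate(pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE),
                               1L), 10L), 10L)
  dens <- counts / (length(d) * diff(breaks)[1])
  centers <- (breaks[-1] + breaks[-11]) / 2
  lambda <- 1 / mean(d)
  mean(abs(dens - lambda * exp(-lambda * centers)))
}

ts_peak_freq_expfit <- function(z, n_windows) {
  n <- length(z)
  len <- floor(n / n_windows)
  if (len < 8) return(NA_real_)
  f <- vapply(seq_len(n_windows), function(w) {
    seg <- z[((w - 1) * len + 1):(w * len)]
    segz <- zscore(seg)
    if (anyNA(segz)) return(NA_real_)
    pg <- ts_periodogram(segz)
    pg$freq[which.max(pg$power)]
  }, numeric(1))
  if (anyNA(f)) return(NA_real_)
  w <- seq_len(n_windows)
  stats::cov(w, log(f)) / stats::var(w)
}

# Fluctuation analysis: cumulative sum, windows of log-spaced sizes,
# per-window linear detrend; F(tau) = mean range ("rsrange") or RMS
# fluctuation ("dfa"); returns breakpoint position of the best two-segment
# linear fit to log F vs log tau as a proportion of the scale axis.
ts_fluct_prop <- function(z, method) {
  n <- length(z)
  y <- cumsum(z)
  taus <- unique(round(exp(seq(log(5), log(floor(n / 2)), length.out = 50))))
  Fv <- vapply(taus, function(tau) fluct_stat(y, tau, method), numeric(1))
  ok <- is.finite(Fv) & Fv > 0
  taus <- taus[ok]; Fv <- Fv[ok]
  m <- length(taus)
  if (m < 6) return(NA_real_)
  L <- log(taus); Y <- log(Fv)
  sse <- function(i, j) {
    xx <- L[i:j]; yy <- Y[i:j]
    b <- stats::cov(xx, yy) / stats::var(xx)
    a <- mean(yy) - b * mean(xx)
    sum((yy - a - b * xx)^2)
  }
  ks <- 3:(m - 3)
  total <- vapply(ks, function(k) sse(1, k) + sse(k + 1, m), numeric(1))
  ks[which.min(total)] / m
}

fluct_stat <- function(y, tau, method) {
  m <- floor(length(y) / tau)
  if (m < 1) return(NA_real_)
  W <- matrix(y[1:(m * tau)], nrow = tau)
  t_ <- 1:tau
  tc <- t_ - mean(t_)
  denom <- sum(tc^2)
  slopes <- colSums(W * tc) / denom
  res <- W - outer(tc, slopes) - rep(colMeans(W), each = tau)
  if (method == "rsrange") {
    mean(apply(res, 2, function(r) max(r) - min(r)))
  } else {
    sqrt(mean(res^2))
  }
}
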