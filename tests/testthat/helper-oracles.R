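# Independent naive oracles: literal transcriptions of the documented metric
# definitions, written with explicit loops and direct sums so they share no
# code path with the package implementations.

# ---- spike time tiling coefficient, brute force ---------------------------

oracle_sttc <- function(a, b, T, dt) {
  tiled <- function(s) {
    if (!length(s)) return(0)
    covered <- 0
    prev_end <- -Inf
    for (x in sort(s)) {
      lo <- max(x - dt, 0, prev_end)
      hi <- min(x + dt, T)
      if (hi > lo) covered <- covered + hi - lo
      prev_end <- max(prev_end, hi)
    }
    covered / T
  }
  prop <- function(s, other) {
    if (!length(s) || !length(other)) return(0)
    hits <- 0
    for (x in s) {
      near <- FALSE
      for (y in other) if (abs(x - y) <= dt) { near <- TRUE; break }
      if (near) hits <- hits + 1
    }
    hits / length(s)
  }
  Ta <- tiled(a); Tb <- tiled(b)
  Pa <- prop(a, b); Pb <- prop(b, a)
  0.5 * ((Pa - Tb) / (1 - Pa * Tb) + (Pb - Ta) / (1 - Pb * Ta))
}

# ---- time-series metric oracles -------------------------------------------

o_zscore <- function(x) (x - mean(x)) / sd(x)

# direct-sum ACF, 1/n normalization
o_acf <- function(z, tau) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0
  for (t in 1:(n - tau)) num <- num + zc[t] * zc[t + tau]
  num / sum(zc^2)
}

# direct DFT periodogram at frequencies k/n, k = 1..floor(n/2)
o_periodogram <- function(z) {
  n <- length(z)
  K <- floor(n / 2)
  P <- numeric(K)
  for (k in 1:K) {
    re <- 0; im <- 0
    for (t in 1:n) {
      ang <- -2 * pi * k * (t - 1) / n
      re <- re + z[t] * cos(ang)
      im <- im + z[t] * sin(ang)
    }
    P[k] <- (re^2 + im^2) / n
  }
  list(freq = (1:K) / n, power = P)
}

# findInterval-equivalent binning by scanning the break vector
o_bin_of <- function(v, breaks) {
  nb <- length(breaks) - 1
  b <- 0
  for (i in seq_len(nb + 1)) if (v >= breaks[i]) b <- i
  min(max(b, 1), nb)
}

o_hist_counts <- function(vals, breaks) {
  counts <- rep(0L, length(breaks) - 1)
  for (v in vals) {
    b <- o_bin_of(v, breaks)
    counts[b] <- counts[b] + 1L
  }
  counts
}

o_fluct <- function(z, method) {
  n <- length(z)
  y <- cumsum(z)
  taus <- unique(round(exp(seq(log(5), log(floor(n / 2)), length.out = 50))))
  Fv <- numeric(0)
  kept <- integer(0)
  for (tau in taus) {
    m <- floor(n / tau)
    if (m < 1) next
    stats <- numeric(m)
    for (w in seq_len(m)) {
      seg <- y[((w - 1) * tau + 1):(w * tau)]
      fit <- lm(seg ~ seq_len(tau))
      res <- residuals(fit)
      stats[w] <- if (method == "rsrange") max(res) - min(res) else mean(res^2)
    }
    Fi <- if (method == "rsrange") mean(stats) else sqrt(mean(stats))
    if (is.finite(Fi) && Fi > 0) {
      Fv <- c(Fv, Fi)
      kept <- c(kept, tau)
    }
  }
  m <- length(kept)
  if (m < 6) return(NA_real_)
  L <- log(kept); Y <- log(Fv)
  best_k <- NA; best_sse <- Inf
  for (k in 3:(m - 3)) {
    f1 <- lm(Y[1:k] ~ L[1:k])
    f2 <- lm(Y[(k + 1):m] ~ L[(k + 1):m])
    sse <- sum(residuals(f1)^2) + sum(residuals(f2)^2)
    if (sse < best_sse) { best_sse <- sse; best_k <- k }
  }
  best_k / m
}

# all 22 metrics, literal definitions
oracle_ts_metrics <- function(x) {
  n <- length(x)
  out <- setNames(rep(NA_real_, 22),
                  c("RF", "RM", "EAF", "AMI", "SFR", "LPF", "MEF", "PAM",
                    "EFD", "CCD", "TCT", "SES", "CFS", "SFD", "MD5", "MD10",
                    "FMA", "FMI", "TRS", "TEA", "RFT", "PDE"))

  # raw-series metrics
  mu <- mean(x)
  run <- 0; best <- 0
  for (v in x) {
    if (v > mu) { run <- run + 1; best <- max(best, run) } else run <- 0
  }
  out["PAM"] <- best
  thr <- 0.04 * sd(x)
  exceed <- 0
  for (t in 2:n) if (abs(x[t] - x[t - 1]) > thr) exceed <- exceed + 1
  out["PDE"] <- exceed / (n - 1)

  if (sd(x) == 0) return(out)
  z <- o_zscore(x)

  pg <- o_periodogram(z)
  i_max <- which.max(pg$power)
  out["RF"] <- pg$freq[i_max]
  out["RM"] <- pg$power[i_max]
  out["LPF"] <- sum(pg$power[1:max(1, floor(length(pg$power) / 5))]) /
    sum(pg$power)
  out["CFS"] <- sum(pg$freq * pg$power) / sum(pg$power)

  max_lag <- floor(n / 2)
  r <- vapply(1:max_lag, function(tau) o_acf(z, tau), numeric(1))
  eaf <- NA
  for (tau in 1:max_lag) if (r[tau] < exp(-1)) { eaf <- tau; break }
  out["EAF"] <- eaf
  fma <- NA
  for (tau in 1:(max_lag - 1)) if (r[tau + 1] > r[tau]) { fma <- tau; break }
  out["FMA"] <- fma

  # histogram AMI at lag 1, 5 bins
  breaks5 <- seq(min(z), max(z), length.out = 6)
  joint <- matrix(0, 5, 5)
  for (t in 1:(n - 1)) {
    i <- o_bin_of(z[t], breaks5); j <- o_bin_of(z[t + 1], breaks5)
    joint[i, j] <- joint[i, j] + 1
  }
  p <- joint / sum(joint)
  mi <- 0
  for (i in 1:5) for (j in 1:5) {
    if (p[i, j] > 0) {
      mi <- mi + p[i, j] * log(p[i, j] / (sum(p[i, ]) * sum(p[, j])))
    }
  }
  out["AMI"] <- mi

  out["SFR"] <- o_fluct(z, "rsrange")
  out["SFD"] <- o_fluct(z, "dfa")

  # 3-sample mean forecast residual sd
  res <- numeric(0)
  for (t in 4:n) res <- c(res, z[t] - mean(z[(t - 3):(t - 1)]))
  out["MEF"] <- sd(res)

  # embedding distance exponential fit, tau = EAF capped
  tau_e <- if (is.na(eaf)) 1 else min(max(eaf, 1), floor(n / 10))
  a <- z[1:(n - tau_e)]; b <- z[(1 + tau_e):n]
  d <- numeric(0)
  for (t in 1:(length(a) - 1)) {
    d <- c(d, sqrt((a[t + 1] - a[t])^2 + (b[t + 1] - b[t])^2))
  }
  if (max(d) > 0) {
    brk <- seq(0, max(d), length.out = 11)
    cnt <- o_hist_counts(d, brk)
    dens <- cnt / (length(d) * (brk[2] - brk[1]))
    ctr <- (brk[-1] + brk[-11]) / 2
    lam <- 1 / mean(d)
    out["EFD"] <- mean(abs(dens - lam * exp(-lam * ctr)))
  }

  # correlation length ratio under differencing (first ACF zero crossings)
  zd <- diff(z)
  rd <- vapply(1:floor(length(zd) / 2), function(tau) o_acf(zd, tau),
               numeric(1))
  t0 <- NA; t1 <- NA
  for (tau in seq_along(r)) if (r[tau] < 0) { t0 <- tau; break }
  for (tau in seq_along(rd)) if (rd[tau] < 0) { t1 <- tau; break }
  if (!is.na(t0) && !is.na(t1)) out["CCD"] <- t1 / t0

  # tercile transition matrix trace of covariance
  q <- quantile(z, c(1 / 3, 2 / 3), names = FALSE)
  sym <- integer(n)
  for (t in 1:n) sym[t] <- 1 + (z[t] >= q[1]) + (z[t] >= q[2])
  M <- matrix(0, 3, 3)
  for (t in 1:(n - 1)) M[sym[t], sym[t + 1]] <- M[sym[t], sym[t + 1]] + 1
  M <- M / sum(M)
  out["TCT"] <- sum(diag(cov(M)))

  # entropy and histogram modes
  breaks10 <- seq(min(z), max(z), length.out = 11)
  p10 <- o_hist_counts(z, breaks10) / n
  out["SES"] <- -sum(p10[p10 > 0] * log(p10[p10 > 0]))
  for (nb in c(5, 10)) {
    brk <- seq(min(z), max(z), length.out = nb + 1)
    cnt <- o_hist_counts(z, brk)
    ctr <- (brk[-1] + brk[-(nb + 1)]) / 2
    out[if (nb == 5) "MD5" else "MD10"] <- mean(ctr[cnt == max(cnt)])
  }

  # gaussian AMI first local minimum
  ami <- numeric(0)
  for (tau in 1:min(40, n - 2)) {
    rho <- cor(z[1:(n - tau)], z[(1 + tau):n])
    ami <- c(ami, -0.5 * log(max(1 - rho^2, .Machine$double.eps)))
  }
  fmi <- NA
  for (tau in 1:(length(ami) - 1)) {
    if (ami[tau + 1] > ami[tau]) { fmi <- tau; break }
  }
  out["FMI"] <- fmi

  out["TRS"] <- mean(diff(z)^3)

  ev <- which(z > 1)
  if (length(ev) >= 2) out["TEA"] <- mean(diff(ev))

  # per-window spectral peak exponential fit
  len <- floor(n / 5)
  if (len >= 8) {
    fw <- numeric(5)
    for (w in 1:5) {
      seg <- x_seg <- z[((w - 1) * len + 1):(w * len)]
      if (sd(seg) == 0) { fw <- NULL; break }
      pgw <- o_periodogram(o_zscore(seg))
      fw[w] <- pgw$freq[which.max(pgw$power)]
    }
    if (!is.null(fw)) {
      fit <- lm(log(fw) ~ seq_len(5))
      out["RFT"] <- coef(fit)[2]
    }
  }
  out
}

# ---- random spike trains for STTC/CCG tests -------------------------------

poisson_train <- function(rate, T, seed) {
  withr::with_seed(seed, sort(runif(rpois(1, rate * T), 0, T)))
}

# random test series mixing autocorrelated, periodic and count-like cases
oracle_test_series <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(80:200, 1)
    kind <- seed %% 3
    if (kind == 0) {
      as.numeric(arima.sim(list(ar = runif(1, 0.2, 0.9)), n))
    } else if (kind == 1) {
      sin(2 * pi * seq_len(n) / sample(5:25, 1)) + rnorm(n, 0, 0.3)
    } else {
      rpois(n, runif(1, 0.5, 6))
    }
  })
}
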