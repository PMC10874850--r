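#' Bin the pooled population activity of a recording
#'
#' Sums the binned spike counts of all units (100-ms bins by default) and
#' computes a Gaussian-kernel-smoothed population firing-rate trace.
#'
#' @param rec an [mea_recording()].
#' @param bin_s bin width in seconds.
#' @param smooth_sigma_s Gaussian smoothing sd in seconds.
#' @return An object of class `mea_population`: `counts` (summed counts per
#'   bin), `rate_hz` (smoothed population rate, spikes/s), `bin_s`,
#'   `n_units`, `duration_s`.
#' @export
bin_population <- function(rec, bin_s = 0.1, smooth_sigma_s = 0.1) {
  n_bins <- floor(rec$duration_s / bin_s)
  counts <- rep(0L, n_bins)
  for (u in rec$units) {
    counts <- counts + bin_spikes(u$spike_times_s, rec$duration_s, bin_s)
  }
  rate <- gauss_smooth(counts / bin_s, smooth_sigma_s / bin_s)
  structure(list(counts = counts, rate_hz = rate, bin_s = bin_s,
                 smooth_sigma_s = smooth_sigma_s,
                 n_units = length(rec$units), duration_s = rec$duration_s),
            class = "mea_population")
}

# Gaussian kernel smoothing (sd in samples), edge-normalized.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0 || length(x) < 3) return(as.numeric(x))
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  num <- stats::filter(c(rep(0, half), x, rep(0, half)), k / sum(k),
                       sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, length(x)), rep(0, half)),
                       k / sum(k), sides = 2)
  as.numeric(num / den)[(half + 1):(half + length(x))]
}

#' Detect network bursts in the population rate trace
#'
#' Culture-wide activity surges are detected on the smoothed population rate
#' with an activity-adaptive threshold `theta = median(rate) + k * MAD(rate)`
#' recomputed per recording, so the detector tracks overall activity as the
#' culture develops. Intervals above threshold are extended outward to where
#' the rate falls back below the median (capturing the rise and decay
#' phases), merged when closer than `merge_gap_s`, and discarded when
#' shorter than `min_dur_s`.
#'
#' @param pop an `mea_population` from [bin_population()].
#' @param k MAD multiplier of the detection threshold.
#' @param merge_gap_s bursts closer than this are merged.
#' @param min_dur_s minimum burst duration.
#' @return An object of class `mea_burst_set`: data frame `bursts`
#'   (`start_s`, `peak_s`, `end_s`, `amplitude_hz`) and per-recording
#'   features `burst_rate_per_min`, `MIB` (mean inter-burst interval, s,
#'   start-to-start), `MFT` (mean peak-to-end time, s), `mean_duration_s`,
#'   `mean_rise_s`, `burst_amplitude_hz`. With zero bursts the features are
#'   `NA` (not zero).
#' @export
detect_network_bursts <- function(pop, k = 5, merge_gap_s = 0.1,
                                  min_dur_s = 0.05) {
  r <- pop$rate_hz
  bin_s <- pop$bin_s
  base <- stats::median(r)
  spread <- stats::mad(r)
  theta <- base + k * spread
  above <- r > theta & spread > 0
  bursts <- data.frame(start_s = numeric(), peak_s = numeric(),
                       end_s = numeric(), amplitude_hz = numeric())
  if (any(above)) {
    runs <- rle(above)
    ends_idx <- cumsum(runs$lengths)
    starts_idx <- ends_idx - runs$lengths + 1L
    core <- cbind(starts_idx[runs$values], ends_idx[runs$values])
    # extend outward to where the rate falls below the running median
    ext <- t(apply(core, 1, function(iv) {
      a <- iv[1]; b <- iv[2]
      while (a > 1 && r[a - 1] > base) a <- a - 1
      while (b < length(r) && r[b + 1] > base) b <- b + 1
      c(a, b)
    }))
    ext <- ext[order(ext[, 1]), , drop = FALSE]
    # merge overlapping or near-adjacent intervals
    merged <- list(ext[1, ])
    if (nrow(ext) > 1) {
      for (i in 2:nrow(ext)) {
        last <- merged[[length(merged)]]
        if ((ext[i, 1] - last[2]) * bin_s <= merge_gap_s) {
          merged[[length(merged)]] <- c(last[1], max(last[2], ext[i, 2]))
        } else {
          merged[[length(merged) + 1]] <- ext[i, ]
        }
      }
    }
    rows <- lapply(merged, function(iv) {
      dur <- (iv[2] - iv[1] + 1) * bin_s
      if (dur < min_dur_s) return(NULL)
      pk <- iv[1] - 1L + which.max(r[iv[1]:iv[2]])
      data.frame(start_s = (iv[1] - 1) * bin_s,
                 peak_s = (pk - 0.5) * bin_s,
                 end_s = iv[2] * bin_s,
                 amplitude_hz = r[pk])
    })
    bursts <- do.call(rbind, Filter(Negate(is.null), rows)) %||% bursts
  }
  nb <- nrow(bursts)
  feats <- if (nb > 0) {
    list(burst_rate_per_min = nb / (pop$duration_s / 60),
         MIB = if (nb > 1) mean(diff(bursts$start_s)) else NA_real_,
         MFT = mean(bursts$end_s - bursts$peak_s),
         mean_duration_s = mean(bursts$end_s - bursts$start_s),
         mean_rise_s = mean(bursts$peak_s - bursts$start_s),
         burst_amplitude_hz = mean(bursts$amplitude_hz))
  } else {
    list(burst_rate_per_min = NA_real_, MIB = NA_real_, MFT = NA_real_,
         mean_duration_s = NA_real_, mean_rise_s = NA_real_,
         burst_amplitude_hz = NA_real_)
  }
  structure(c(list(bursts = bursts, theta = theta, baseline = base), feats),
            class = "mea_burst_set")
}

#' Spike time tiling coefficient of two spike trains
#'
#' `STTC = 0.5 * ((P_A - T_B) / (1 - P_A * T_B) + (P_B - T_A) / (1 - P_B * T_A))`
#' where `T_X` is the fraction of the recording tiled by `+-delta_t` windows
#' around X's spikes and `P_X` the proportion of X's spikes falling within
#' `delta_t` of any spike of the other train. Rate-robust and bounded in
#' `[-1, 1]`.
#'
#' @param a,b sorted spike-time vectors (s).
#' @param duration_s recording duration (s).
#' @param delta_t_s coincidence window (s), default 10 ms.
#' @return The STTC value; `NA` if a denominator degenerates.
#' @export
sttc <- function(a, b, duration_s, delta_t_s = 0.01) {
  Ta <- tiled_fraction(a, duration_s, delta_t_s)
  Tb <- tiled_fraction(b, duration_s, delta_t_s)
  Pa <- prop_within(a, b, delta_t_s)
  Pb <- prop_within(b, a, delta_t_s)
  d1 <- 1 - Pa * Tb
  d2 <- 1 - Pb * Ta
  if (d1 == 0 || d2 == 0) return(NA_real_)
  0.5 * ((Pa - Tb) / d1 + (Pb - Ta) / d2)
}

# fraction of [0, T] covered by the union of [s - dt, s + dt] windows
tiled_fraction <- function(s, T, dt) {
  if (!length(s)) return(0)
  starts <- pmax(s - dt, 0)
  ends <- pmin(s + dt, T)
  prev <- c(-Inf, ends[-length(ends)])
  sum(pmax(0, ends - pmax(starts, prev))) / T
}

# proportion of spikes in `a` within dt of any spike in `b`
prop_within <- function(a, b, dt) {
  if (!length(a)) return(0)
  if (!length(b)) return(0)
  idx <- findInterval(a, b)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(b))
  near <- abs(a - b[lo]) <= dt | abs(a - b[hi]) <= dt
  mean(near)
}

#' Functional connectivity graph from the spike time tiling coefficient
#'
#' Computes all pairwise STTC values and keeps an (undirected) edge wherever
#' the coefficient exceeds `threshold`.
#'
#' @param rec an [mea_recording()] with >= 2 units of >= 2 spikes each.
#' @param delta_t_s coincidence window (s).
#' @param threshold edge-inclusion threshold on the STTC.
#' @return An object of class `mea_graph`: `nodes` (unit IDs), `weights`
#'   (symmetric STTC matrix), `adjacency` (logical), `directed = FALSE`,
#'   `method = "sttc"`.
#' @export
infer_connectivity_sttc <- function(rec, delta_t_s = 0.01, threshold = 0.1) {
  units <- Filter(function(u) length(u$spike_times_s) >= 2, rec$units)
  n <- length(units)
  if (n < 2) stop_mea("InvalidParameter", ">= 2 units with >= 2 spikes required")
  W <- matrix(NA_real_, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      W[i, j] <- W[j, i] <- sttc(units[[i]]$spike_times_s,
                                 units[[j]]$spike_times_s,
                                 rec$duration_s, delta_t_s)
    }
  }
  diag(W) <- NA_real_
  A <- !is.na(W) & W > threshold
  ids <- vapply(units, function(u) u$unit_id, integer(1))
  structure(list(nodes = ids, weights = W, adjacency = A, directed = FALSE,
                 method = "sttc", params = list(delta_t_s = delta_t_s,
                                                threshold = threshold)),
            class = "mea_graph")
}

#' Functional connectivity graph from jitter-tested cross-correlograms
#'
#' For each ordered unit pair the cross-correlogram (CCG) of spike-time lags
#' is compared against a band from spike-jittered surrogates: a directed
#' edge is called when the largest short-latency bin (0-10 ms) exceeds the
#' `1 - alpha` quantile of the surrogate maxima over the same bins (a
#' max-statistic band, so the per-pair false-positive rate under the jitter
#' null is `alpha`). Jittering destroys fine timing while preserving slow
#' rate co-modulation, so the test is robust to rate nonstationarity.
#'
#' @param rec an [mea_recording()].
#' @param window_ms CCG half-window (ms).
#' @param bin_ms CCG bin width (ms).
#' @param jitter_ms uniform jitter half-width (ms).
#' @param n_jitter number of surrogates.
#' @param alpha pointwise significance level.
#' @param seed integer seed for the surrogates.
#' @param latency_ms short-latency range tested for an edge.
#' @return An `mea_graph` with a directed logical `adjacency`.
#' @export
infer_connectivity_ccg <- function(rec, window_ms = 50, bin_ms = 1,
                                   jitter_ms = 10, n_jitter = 100,
                                   alpha = 0.01, seed = 1,
                                   latency_ms = c(0, 10)) {
  units <- Filter(function(u) length(u$spike_times_s) >= 2, rec$units)
  n <- length(units)
  ids <- vapply(units, function(u) u$unit_id, integer(1))
  A <- matrix(FALSE, n, n)
  if (n >= 2) {
    breaks <- seq(-window_ms, window_ms, by = bin_ms) / 1000
    test_bins <- which(breaks[-1] > latency_ms[1] / 1000 &
                         breaks[-length(breaks)] < latency_ms[2] / 1000)
    with_seed(seed, {
      for (i in 1:n) {
        for (j in 1:n) {
          if (i == j) next
          a <- units[[i]]$spike_times_s
          b <- units[[j]]$spike_times_s
          obs <- ccg_counts(a, b, breaks)
          sur <- matrix(0, n_jitter, length(breaks) - 1)
          for (s in seq_len(n_jitter)) {
            bj <- sort(b + stats::runif(length(b), -jitter_ms, jitter_ms) / 1000)
            sur[s, ] <- ccg_counts(a, bj, breaks)
          }
          sur_max <- apply(sur[, test_bins, drop = FALSE], 1, max)
          thr <- stats::quantile(sur_max, probs = 1 - alpha, names = FALSE)
          A[i, j] <- max(obs[test_bins]) > thr
        }
      }
    })
  }
  structure(list(nodes = ids, weights = NULL, adjacency = A, directed = TRUE,
                 method = "ccg",
                 params = list(window_ms = window_ms, bin_ms = bin_ms,
                               jitter_ms = jitter_ms, n_jitter = n_jitter,
                               alpha = alpha, latency_ms = latency_ms)),
            class = "mea_graph")
}

# histogram of lags (b - a) for all pairs within the outer break range
ccg_counts <- function(a, b, breaks) {
  w <- breaks[length(breaks)]
  lo <- findInterval(a + breaks[1], b) + 1L
  hi <- findInterval(a + w, b)
  lags <- unlist(lapply(seq_along(a), function(k) {
    if (hi[k] < lo[k]) return(numeric(0))
    b[lo[k]:hi[k]] - a[k]
  }))
  if (!length(lags)) return(rep(0L, length(breaks) - 1))
  graphics::hist(lags, breaks = breaks, plot = FALSE)$counts
}

#' Density and global efficiency of a functional graph
#'
#' `DEC` is the realized/possible edge fraction (ordered pairs for directed
#' graphs, unordered otherwise). `GEC` is the global efficiency: the mean
#' over ordered node pairs of the inverse shortest-path length on the
#' binarized graph (directed graphs are first symmetrized: an undirected
#' edge is kept if either direction is significant); unreachable pairs
#' contribute 0.
#'
#' @param g an `mea_graph`.
#' @return Named list with `DEC` and `GEC`.
#' @export
compute_graph_features <- function(g) {
  A <- g$adjacency
  n <- nrow(A)
  if (n < 2) return(list(DEC = 0, GEC = 0))
  n_edges <- if (g$directed) sum(A) else sum(A[upper.tri(A)])
  n_possible <- if (g$directed) n * (n - 1) else n * (n - 1) / 2
  S <- A | t(A) # symmetrized for path lengths
  eff <- 0
  for (i in 1:n) {
    d <- bfs_dist(S, i)
    reach <- which(is.finite(d) & d > 0)
    eff <- eff + sum(1 / d[reach])
  }
  list(DEC = n_edges / n_possible, GEC = eff / (n * (n - 1)))
}

# single-source BFS distances on a logical adjacency matrix
bfs_dist <- function(S, src) {
  n <- nrow(S)
  d <- rep(Inf, n)
  d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(S[v, ] & !is.finite(d))
      d[nb] <- d[v] + 1
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  d
}

#' Time-series metrics of the population activity
#'
#' Applies the 22-metric set of [extract_timeseries_features()] to the
#' binned population counts; names are prefixed `n` (network level) to
#' distinguish them from the single-cell (`s`-prefixed) variants.
#'
#' @param pop an `mea_population`.
#' @param bin_s bin width metadata.
#' @return One-row data frame with `nRF` ... `nPDE`.
#' @export
extract_network_timeseries_features <- function(pop, bin_s = pop$bin_s) {
  f <- extract_timeseries_features(pop$counts, bin_s)
  names(f) <- paste0("n", names(f))
  f
}

#' @importFrom graphics hist
NULL
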