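#' Configuration for the synthetic culture generator
#'
#' Describes a longitudinal two-group HD-MEA study: cultures per group,
#' weekly recording ages, unit counts, firing statistics, network-burst
#' dynamics, group/batch/developmental effects and waveform archetypes.
#' Defaults emulate a developing dopaminergic culture study: 15-min weekly
#' recordings, tonic ~1 Hz units riding on network bursts a few times per
#' minute with sub-second rise and ~1 s decay.
#'
#' @param n_cultures_per_group cultures per group.
#' @param groups character vector of group labels.
#' @param weeks integer vector of recording weeks (age is `7 * week` days).
#' @param n_units units per culture.
#' @param duration_s recording duration in seconds (15 min).
#' @param sampling_rate_hz template/trace sampling rate.
#' @param baseline_rate_hz mean per-unit tonic firing rate.
#' @param unit_rate_sd_log lognormal sd of per-unit rate multipliers.
#' @param burst_rate_per_min network bursts per minute (0 disables bursting).
#' @param burst_ibi_shape gamma shape of inter-burst intervals (larger =
#'   more clock-like bursting).
#' @param burst_rise_s,burst_decay_s rise and decay time constants of the
#'   double-exponential burst envelope.
#' @param burst_gain peak rate multiplier at the burst maximum (>= 1).
#' @param regularity firing regularity in `[0, 1)`: 0 gives Poisson ISIs,
#'   values near 1 give clock-like trains. ISIs are gamma-renewal with shape
#'   `1 / (1 - regularity)`, so the ISI coefficient of variation is
#'   `sqrt(1 - regularity)`.
#' @param group_effects named list: for each non-reference group, a named
#'   list of additive offsets applied to config parameters
#'   (e.g. `list(A53T = list(burst_rate_per_min = 3, regularity = 0.3))`).
#' @param n_batches number of culture batches (assigned round-robin).
#' @param batch_rate_sd_log per-batch lognormal sd multiplying firing rates.
#' @param developmental_trend named list of per-day additive slopes applied
#'   to parameters as the culture ages (anchored at the first recording week).
#' @param waveform_archetypes data frame of per-archetype waveform parameter
#'   means: `trough_uv`, `trough_to_peak_ms`, `half_width_ms`,
#'   `spatial_decay_um`, `responder_prob` (probability that a unit of this
#'   archetype reduces its rate under the acute D2-agonist perturbation).
#' @param archetype_mix archetype mixing proportions.
#' @param waveform_jitter relative sd of per-unit waveform parameter jitter.
#' @return A `mea_sim_config` list.
#' @export
sim_config <- function(n_cultures_per_group = 10,
                       groups = c("WT", "A53T"),
                       weeks = 1:5,
                       n_units = 30,
                       duration_s = 900,
                       sampling_rate_hz = 20000,
                       baseline_rate_hz = 1,
                       unit_rate_sd_log = 0.4,
                       burst_rate_per_min = 4,
                       burst_ibi_shape = 5,
                       burst_rise_s = 0.3,
                       burst_decay_s = 1,
                       burst_gain = 8,
                       regularity = 0.2,
                       group_effects = list(A53T = list(burst_rate_per_min = 3,
                                                        regularity = 0.4,
                                                        baseline_rate_hz = 0.5)),
                       n_batches = 2,
                       batch_rate_sd_log = 0.15,
                       developmental_trend = list(baseline_rate_hz = 0.02,
                                                  burst_rate_per_min = 0.05),
                       waveform_archetypes = default_archetypes(),
                       archetype_mix = c(0.5, 0.5),
                       waveform_jitter = 0.08) {
  cfg <- as.list(environment())
  stopifnot(cfg$burst_gain >= 1, cfg$regularity >= 0, cfg$regularity < 1,
            cfg$baseline_rate_hz >= 0, cfg$burst_rate_per_min >= 0,
            cfg$burst_rise_s > 0, cfg$burst_decay_s > cfg$burst_rise_s)
  class(cfg) <- "mea_sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_archetypes <- function() {
  data.frame(archetype = c(1L, 2L),
             trough_uv = c(60, 140),
             trough_to_peak_ms = c(0.35, 0.9),
             half_width_ms = c(0.15, 0.35),
             spatial_decay_um = c(25, 40),
             responder_prob = c(0.8, 0.2))
}

#' Simulate a longitudinal culture series
#'
#' Generates one [mea_recording()] per culture per week, with per-unit
#' gamma-renewal spike trains rate-modulated by a shared double-exponential
#' network-burst envelope, parametric biphasic waveform templates with
#' exponential spatial decay, group/batch/developmental parameter effects,
#' and a ground-truth record of everything generated.
#'
#' @param cfg a [sim_config()].
#' @param seed integer master seed; output is deterministic given the seed.
#' @return A list with `recordings` (list of [mea_recording()]) and `truth`
#'   (class `mea_ground_truth`): `bursts` (per culture-week burst windows
#'   with start/peak/end), `units` (per-culture archetype labels and
#'   responder flags), `params` (realized per-recording parameters) and
#'   `cultures` (metadata table).
#' @export
simulate_culture_series <- function(cfg, seed) {
  stopifnot(inherits(cfg, "mea_sim_config"))
  groups <- cfg$groups
  cultures <- data.frame()
  idx <- 0L
  for (g in groups) {
    for (i in seq_len(cfg$n_cultures_per_group)) {
      idx <- idx + 1L
      cultures <- rbind(cultures, data.frame(
        culture_id = sprintf("%s_%02d", g, i), group = g,
        batch = sprintf("batch%d", ((idx - 1L) %% cfg$n_batches) + 1L)))
    }
  }

  recordings <- list()
  bursts <- list()
  unit_truth <- list()
  params <- list()
  base_week <- min(cfg$weeks)

  for (ci in seq_len(nrow(cultures))) {
    cu <- cultures[ci, ]
    cseed <- child_seed(seed, ci)
    units_meta <- with_seed(cseed, draw_units(cfg))
    units_meta$culture_id <- cu$culture_id
    unit_truth[[ci]] <- units_meta
    batch_factor <- with_seed(child_seed(seed, 10000L + match(cu$batch, unique(cultures$batch))),
                              exp(stats::rnorm(1, 0, cfg$batch_rate_sd_log)))
    for (w in cfg$weeks) {
      p <- effective_params(cfg, cu$group, w, base_week, batch_factor)
      rseed <- child_seed(cseed, w)
      sim <- with_seed(rseed, simulate_recording_core(cfg, p, units_meta))
      rec <- mea_recording(culture_id = cu$culture_id, units = sim$units,
                           duration_s = cfg$duration_s,
                           sampling_rate_hz = cfg$sampling_rate_hz,
                           group = cu$group, treatment = "none",
                           batch = cu$batch, age_days = 7L * w)
      key <- sprintf("%s_w%d", cu$culture_id, w)
      recordings[[key]] <- rec
      if (nrow(sim$bursts)) {
        sim$bursts$culture_id <- cu$culture_id
        sim$bursts$week <- w
        bursts[[key]] <- sim$bursts
      }
      params[[key]] <- c(list(culture_id = cu$culture_id, week = w), p)
    }
  }

  truth <- structure(list(
    bursts = if (length(bursts)) do.call(rbind, bursts) else
      data.frame(start_s = numeric(), peak_s = numeric(), end_s = numeric(),
                 culture_id = character(), week = integer()),
    units = do.call(rbind, unit_truth),
    params = params,
    cultures = cultures), class = "mea_ground_truth")
  list(recordings = recordings, truth = truth)
}

# Per-unit identities fixed across weeks: archetype, waveform parameters,
# rate multiplier, responder flag.
draw_units <- function(cfg) {
  arch <- sample(cfg$waveform_archetypes$archetype, cfg$n_units,
                 replace = TRUE, prob = cfg$archetype_mix)
  ap <- cfg$waveform_archetypes[match(arch, cfg$waveform_archetypes$archetype), ]
  jit <- function(mu) mu * exp(stats::rnorm(cfg$n_units, 0, cfg$waveform_jitter))
  data.frame(unit_id = seq_len(cfg$n_units) - 1L,
             archetype = arch,
             trough_uv = jit(ap$trough_uv),
             trough_to_peak_ms = jit(ap$trough_to_peak_ms),
             half_width_ms = jit(ap$half_width_ms),
             spatial_decay_um = jit(ap$spatial_decay_um),
             rate_mult = exp(stats::rnorm(cfg$n_units, 0, cfg$unit_rate_sd_log)),
             responder = stats::runif(cfg$n_units) < ap$responder_prob,
             x_um = stats::runif(cfg$n_units, 0, 35),
             y_um = stats::runif(cfg$n_units, 0, 35))
}

# Apply group offsets, developmental trend (anchored at the first recording
# week) and the batch rate factor to the config parameters.
effective_params <- function(cfg, group, week, base_week, batch_factor) {
  p <- cfg[c("baseline_rate_hz", "burst_rate_per_min", "burst_ibi_shape",
             "burst_rise_s", "burst_decay_s", "burst_gain", "regularity")]
  ge <- cfg$group_effects[[group]]
  for (nm in names(ge)) p[[nm]] <- p[[nm]] + ge[[nm]]
  days <- 7 * (week - base_week)
  for (nm in names(cfg$developmental_trend)) {
    p[[nm]] <- p[[nm]] + cfg$developmental_trend[[nm]] * days
  }
  p$baseline_rate_hz <- max(p$baseline_rate_hz, 0) * batch_factor
  p$burst_rate_per_min <- max(p$burst_rate_per_min, 0)
  p$regularity <- min(max(p$regularity, 0), 0.95)
  p
}

# One recording: shared burst envelope, then per-unit gamma-renewal trains
# generated by time rescaling through the cumulative intensity.
simulate_recording_core <- function(cfg, p, units_meta) {
  T <- cfg$duration_s
  env <- burst_envelope(T, p)
  exp_base <- p$baseline_rate_hz * units_meta$rate_mult * T
  if (all(exp_base * mean(env$e) < 0.5)) {
    stop_mea("DegenerateConfig",
             "expected spike count is ~0 for every unit; check rates")
  }
  # Cumulative intensity on the envelope grid (per unit = rate * E).
  E <- cumsum(env$e) * env$dt
  units <- vector("list", nrow(units_meta))
  for (i in seq_len(nrow(units_meta))) {
    rate <- p$baseline_rate_hz * units_meta$rate_mult[i]
    st <- gamma_renewal_rescaled(rate * E[length(E)], p$regularity,
                                 function(s) {
                                   stats::approx(rate * E, env$t, xout = s,
                                                 rule = 2)$y
                                 })
    tp <- make_template(cfg, units_meta[i, ])
    units[[i]] <- mea_unit(unit_id = units_meta$unit_id[i],
                           spike_times_s = pmin(st, T),
                           template = tp$template,
                           electrode_positions = tp$positions)
  }
  list(units = units, bursts = env$bursts)
}

# Shared network-burst envelope e(t) >= 1 on a 5-ms grid, with ground-truth
# burst windows. Each burst contributes a peak-normalized double exponential
# scaled to (gain - 1).
burst_envelope <- function(T, p) {
  dt <- 0.005
  t <- seq(0, T, by = dt)
  e <- rep(1, length(t))
  bursts <- data.frame(start_s = numeric(), peak_s = numeric(),
                       end_s = numeric())
  if (p$burst_rate_per_min > 0 && p$burst_gain > 1) {
    mean_ibi <- 60 / p$burst_rate_per_min
    k <- p$burst_ibi_shape
    n_max <- ceiling(T / mean_ibi * 3 + 10)
    ibis <- stats::rgamma(n_max, shape = k, rate = k / mean_ibi)
    onsets <- cumsum(c(stats::runif(1, 0, mean_ibi), ibis))
    onsets <- onsets[onsets < T - 2 * p$burst_rise_s]
    r <- p$burst_rise_s; d <- p$burst_decay_s
    t_pk <- r * d / (d - r) * log(d / r)
    h_max <- exp(-t_pk / d) - exp(-t_pk / r)
    for (on in onsets) {
      rel <- t - on
      idx <- rel >= 0 & rel < t_pk + 6 * d
      h <- (exp(-rel[idx] / d) - exp(-rel[idx] / r)) / h_max
      e[idx] <- e[idx] + (p$burst_gain - 1) * h
      bursts <- rbind(bursts, data.frame(start_s = on, peak_s = on + t_pk,
                                         end_s = min(on + t_pk + 2.5 * d, T)))
    }
    # Ground-truth windows must not overlap: truncate at the next onset.
    if (nrow(bursts) > 1) {
      bursts$end_s <- pmin(bursts$end_s, c(bursts$start_s[-1], Inf))
    }
  }
  list(t = t, e = e, dt = dt, bursts = bursts)
}

# Gamma-renewal point process with total operational time Lambda_total,
# mapped to clock time via the supplied inverse cumulative intensity.
# shape k = 1 / (1 - regularity); ISI CV = sqrt(1/k) in operational time.
gamma_renewal_rescaled <- function(Lambda_total, regularity, inv_Lambda) {
  if (Lambda_total <= 0) return(numeric(0))
  k <- 1 / (1 - regularity)
  n_draw <- ceiling(Lambda_total + 4 * sqrt(Lambda_total) + 20)
  s <- cumsum(stats::rgamma(n_draw, shape = k, rate = k))
  while (s[length(s)] < Lambda_total) {
    s <- c(s, s[length(s)] +
             cumsum(stats::rgamma(n_draw, shape = k, rate = k)))
  }
  s <- s[s <= Lambda_total]
  if (!length(s)) return(numeric(0))
  sort(inv_Lambda(s))
}

# Parametric biphasic template: negative Gaussian trough then positive
# Gaussian peak, attenuated exponentially with electrode distance.
# 8 electrodes on a 17.5-um-pitch patch; 3 ms at the config sampling rate.
make_template <- function(cfg, um) {
  fs <- cfg$sampling_rate_hz
  n_samp <- round(0.003 * fs)
  tt <- (seq_len(n_samp) - 1) / fs * 1000 # ms
  t_tr <- 1.0
  t_pk <- t_tr + um$trough_to_peak_ms
  sig1 <- um$half_width_ms / 2.355 # FWHM -> sd
  sig2 <- 2 * sig1
  w <- -um$trough_uv * exp(-(tt - t_tr)^2 / (2 * sig1^2)) +
    0.35 * um$trough_uv * exp(-(tt - t_pk)^2 / (2 * sig2^2))
  pitch <- 17.5
  grid <- expand.grid(x = pitch * 0:3, y = pitch * 0:1)
  d <- sqrt((grid$x - um$x_um)^2 + (grid$y - um$y_um)^2)
  atten <- exp(-d / um$spatial_decay_um)
  list(template = outer(atten, w), positions = as.matrix(grid))
}

#' Simulate an acute pharmacological perturbation
#'
#' Emulates the firing-rate reduction of drug-responsive units after acute
#' agonist addition: each spike of a responder unit is kept independently
#' with probability `responder_fr_ratio` (binomial thinning), so responder
#' rates fall to `responder_fr_ratio` times baseline in expectation;
#' non-responders are returned unchanged.
#'
#' @param rec baseline [mea_recording()].
#' @param truth `mea_ground_truth` carrying per-unit responder flags.
#' @param responder_fr_ratio post/baseline rate ratio in `(0, 1]`.
#' @param seed integer seed for the thinning.
#' @return The post-drug [mea_recording()] (treatment set to `"QP"`).
#' @export
simulate_perturbation <- function(rec, truth, responder_fr_ratio, seed) {
  if (responder_fr_ratio <= 0 || responder_fr_ratio > 1) {
    stop_mea("InvalidParameter",
             "responder_fr_ratio must be in (0, 1], got %g", responder_fr_ratio)
  }
  ut <- truth$units[truth$units$culture_id == rec$culture_id, ]
  if (!nrow(ut)) stop_mea("InvalidParameter",
                          "no responder flags for culture %s", rec$culture_id)
  post <- rec
  post$treatment <- "QP"
  post$units <- with_seed(seed, lapply(rec$units, function(u) {
    resp <- ut$responder[match(u$unit_id, ut$unit_id)]
    if (isTRUE(resp) && responder_fr_ratio < 1) {
      keep <- stats::runif(length(u$spike_times_s)) < responder_fr_ratio
      u$spike_times_s <- u$spike_times_s[keep]
    }
    u
  }))
  post
}
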