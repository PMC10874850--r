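#' Extract action-potential waveform features from a unit template
#'
#' Features are computed on the electrode with the largest negative template
#' amplitude (the peak electrode of the electrical footprint). Times are in
#' milliseconds relative to the trough; amplitudes in microvolts.
#'
#' The eight metrics:
#' * `trough_amplitude_uV` — signed trough minimum (<= 0).
#' * `peak_amplitude_uV` — largest positive excursion after the trough.
#' * `trough_to_peak_ms` — time from trough to that positive peak.
#' * `half_width_ms` — width of the trough at half its depth (linear
#'   interpolation between samples).
#' * `asymmetry` — `(peak_post - peak_pre) / (peak_post + peak_pre)` where
#'   `peak_pre`/`peak_post` are the maxima before/after the trough.
#' * `repolarization_slope_uV_per_ms` — least-squares slope from the trough
#'   to the post-trough peak.
#' * `recovery_slope_uV_per_ms` — least-squares slope over the 0.5 ms
#'   following the post-trough peak.
#' * `peak_trough_ratio` — `peak_post / |trough|`.
#'
#' @param unit an [mea_unit()].
#' @param sampling_rate_hz sampling rate of the template samples.
#' @return A one-row data frame of the eight features.
#' @export
extract_waveform_features <- function(unit, sampling_rate_hz = 20000) {
  tp <- unit$template
  if (!length(tp) || all(tp == 0)) {
    stop_mea("NoSignal", "unit %d: flat template", unit$unit_id)
  }
  elec <- which.min(apply(tp, 1, min))
  w <- tp[elec, ]
  dt_ms <- 1000 / sampling_rate_hz
  i_tr <- which.min(w)
  trough <- w[i_tr]

  post <- if (i_tr < length(w)) w[(i_tr + 1):length(w)] else numeric(0)
  pre <- if (i_tr > 1) w[1:(i_tr - 1)] else numeric(0)
  i_pk_rel <- if (length(post)) which.max(post) else NA_integer_
  peak_post <- if (length(post)) max(post) else NA_real_
  peak_pre <- if (length(pre)) max(pre, 0) else 0
  ttp_ms <- if (!is.na(i_pk_rel)) i_pk_rel * dt_ms else NA_real_

  # half-width: first crossings of trough/2 on each side, interpolated
  half <- trough / 2
  left <- crossing_time(w, i_tr, half, -1L)
  right <- crossing_time(w, i_tr, half, +1L)
  half_width <- if (is.na(left) || is.na(right)) NA_real_ else (right - left) * dt_ms

  asym <- if (peak_post + peak_pre > 0) {
    (peak_post - peak_pre) / (peak_post + peak_pre)
  } else {
    NA_real_
  }

  repol <- if (!is.na(i_pk_rel) && i_pk_rel >= 1) {
    fit_slope(w, i_tr, i_tr + i_pk_rel, dt_ms)
  } else {
    NA_real_
  }
  i_pk <- i_tr + i_pk_rel
  rec_end <- min(length(w), i_pk + max(1L, round(0.5 / dt_ms)))
  recov <- if (!is.na(i_pk_rel) && rec_end > i_pk) {
    fit_slope(w, i_pk, rec_end, dt_ms)
  } else {
    NA_real_
  }

  data.frame(trough_amplitude_uV = trough,
             peak_amplitude_uV = peak_post,
             trough_to_peak_ms = ttp_ms,
             half_width_ms = half_width,
             asymmetry = asym,
             repolarization_slope_uV_per_ms = repol,
             recovery_slope_uV_per_ms = recov,
             peak_trough_ratio = if (trough < 0) peak_post / abs(trough) else NA_real_)
}

# fractional sample index (relative to i0) where w crosses `level` walking in
# `dir`; NA if never crossed.
crossing_time <- function(w, i0, level, dir) {
  i <- i0
  while (i + dir >= 1 && i + dir <= length(w)) {
    j <- i + dir
    if (w[j] >= level) {
      frac <- (level - w[i]) / (w[j] - w[i])
      return((i - i0) + dir * frac)
    }
    i <- j
  }
  NA_real_
}

fit_slope <- function(w, i_from, i_to, dt_ms) {
  idx <- i_from:i_to
  x <- (idx - idx[1]) * dt_ms
  stats::cov(x, w[idx]) / stats::var(x)
}

#' @importFrom stats cov
NULL
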