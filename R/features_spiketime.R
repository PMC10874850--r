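#' Extract spike-train timing features for one unit
#'
#' Four metrics describing the temporal statistics of a spike train:
#' * `MIS` — mean inter-spike interval (s).
#' * `CVI` — coefficient of variation of the ISI (sample sd / mean); the
#'   package's firing-regularity measure (0 for clock-like, ~1 for Poisson).
#' * `firing_rate_hz` — spike count / recording duration.
#' * `isi_pacf1` — partial autocorrelation of the ISI sequence at lag 1
#'   (serial ISI dependence beyond rate).
#'
#' Metrics whose preconditions are unmet (fewer than 2 spikes; fewer than 5
#' for `isi_pacf1`) are returned as `NA`, never silently zero.
#'
#' @param unit an [mea_unit()] (or numeric spike-time vector).
#' @param duration_s recording duration in seconds.
#' @return One-row data frame with `MIS`, `CVI`, `firing_rate_hz`,
#'   `isi_pacf1`.
#' @export
extract_spike_time_features <- function(unit, duration_s) {
  st <- if (inherits(unit, "mea_unit")) unit$spike_times_s else as.numeric(unit)
  n <- length(st)
  fr <- n / duration_s
  if (n < 2) {
    return(data.frame(MIS = NA_real_, CVI = NA_real_, firing_rate_hz = fr,
                      isi_pacf1 = NA_real_))
  }
  isi <- diff(st)
  mis <- mean(isi)
  cvi <- stats::sd(isi) / mis
  pac <- if (n >= 5 && stats::sd(isi) > 0) {
    as.numeric(stats::pacf(isi, lag.max = 1, plot = FALSE)$acf[1])
  } else {
    NA_real_
  }
  data.frame(MIS = mis, CVI = cvi, firing_rate_hz = fr, isi_pacf1 = pac)
}

#' @importFrom stats pacf
NULL
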