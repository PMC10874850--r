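#' Unit quality control
#'
#' Filters spike-sorted units on overall activity, refractory-period
#' violations and waveform shape. A unit passes if its firing rate exceeds
#' `fr_min` (default 0.01 Hz), the fraction of inter-spike intervals shorter
#' than `refractory_ms` is below `viol_max` (default 2%), and its template
#' passes the waveform check. Units with fewer than 2 spikes are always
#' removed (reason `too_few_spikes`).
#'
#' The waveform check is a stand-in for the spike sorter's notion of an
#' "irregular" waveform, for which no canonical definition exists: the peak
#' electrode's trough amplitude must reach at least `amp_min` microvolts in
#' depth and the trough must precede the largest positive peak that follows
#' it. Set `check_waveform = FALSE` to disable it.
#'
#' @param rec an [mea_recording()].
#' @param fr_min minimum firing rate in Hz (exclusive bound).
#' @param refractory_ms assumed refractory period in milliseconds.
#' @param viol_max maximum tolerated refractory-violation fraction
#'   (exclusive bound).
#' @param amp_min minimum trough depth in microvolts for the waveform check.
#' @param check_waveform logical; disable the waveform criterion entirely.
#' @return A list with `recording` (the filtered [mea_recording()]) and
#'   `report` (class `mea_qc_report`): a per-unit data frame with
#'   `firing_rate_hz`, `refractory_violation_fraction`, `waveform_ok`,
#'   `passed` and `reason`, plus summary counts. If every unit is removed the
#'   report carries `all_removed = TRUE` and a warning is raised.
#' @export
run_quality_control <- function(rec, fr_min = 0.01, refractory_ms = 2,
                                viol_max = 0.02, amp_min = 10,
                                check_waveform = TRUE) {
  stopifnot(refractory_ms > 0)
  rows <- lapply(rec$units, function(u) {
    n <- length(u$spike_times_s)
    fr <- n / rec$duration_s
    isi <- diff(u$spike_times_s)
    viol <- if (length(isi)) mean(isi < refractory_ms / 1000) else NA_real_
    wf_ok <- if (check_waveform) waveform_ok(u$template, amp_min) else TRUE
    reason <- if (n < 2) {
      "too_few_spikes"
    } else if (fr <= fr_min) {
      "low_firing_rate"
    } else if (viol >= viol_max) {
      "refractory_violations"
    } else if (!wf_ok) {
      "waveform_irregular"
    } else {
      "pass"
    }
    data.frame(unit_id = u$unit_id, n_spikes = n, firing_rate_hz = fr,
               refractory_violation_fraction = viol, waveform_ok = wf_ok,
               passed = reason == "pass", reason = reason)
  })
  report <- do.call(rbind, rows)
  if (is.null(report)) {
    report <- data.frame(unit_id = integer(), n_spikes = integer(),
                         firing_rate_hz = numeric(),
                         refractory_violation_fraction = numeric(),
                         waveform_ok = logical(), passed = logical(),
                         reason = character())
  }
  keep <- report$passed
  filtered <- rec
  filtered$units <- rec$units[keep]
  all_removed <- length(rec$units) > 0 && !any(keep)
  if (all_removed) {
    warning(sprintf("all %d units of %s removed by quality control",
                    length(rec$units), rec$culture_id))
  }
  structure(list(recording = filtered,
                 report = structure(list(units = report,
                                         n_input = length(rec$units),
                                         n_passed = sum(keep),
                                         all_removed = all_removed,
                                         params = list(fr_min = fr_min,
                                                       refractory_ms = refractory_ms,
                                                       viol_max = viol_max,
                                                       amp_min = amp_min,
                                                       check_waveform = check_waveform)),
                                    class = "mea_qc_report")),
            class = "mea_qc_result")
}

# Trough deep enough and trough precedes the largest subsequent positive peak.
waveform_ok <- function(template, amp_min) {
  if (!length(template) || all(template == 0)) return(FALSE)
  elec <- which.min(apply(template, 1, min))
  w <- template[elec, ]
  trough_idx <- which.min(w)
  if (-w[trough_idx] < amp_min) return(FALSE)
  post <- w[seq(trough_idx, length(w))]
  any(post > 0)
}

#' @export
print.mea_qc_report <- function(x, ...) {
  cat(sprintf("<mea_qc_report> %d/%d units passed\n", x$n_passed, x$n_input))
  tb <- table(x$units$reason)
  for (r in names(tb)) cat(sprintf("  %s: %d\n", r, tb[[r]]))
  invisible(x)
}
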