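#' Construct a spike-sorted unit
#'
#' A unit is a putative single neuron isolated by spike sorting. It carries
#' its spike times (seconds), its mean multi-electrode waveform template (the
#' electrical footprint) and the electrode coordinates the template rows refer
#' to.
#'
#' @param unit_id integer unit identifier, unique within a recording.
#' @param spike_times_s numeric vector of spike times in seconds, sorted
#'   non-decreasing.
#' @param template numeric matrix, electrodes x samples, in microvolts.
#' @param electrode_positions numeric matrix, electrodes x 2, in micrometers.
#'   Row count must equal the template row count.
#' @return An object of class `mea_unit`.
#' @export
mea_unit <- function(unit_id, spike_times_s, template, electrode_positions) {
  spike_times_s <- as.numeric(spike_times_s)
  if (is.unsorted(spike_times_s)) {
    stop_mea("CorruptInput", "unit %s: spike times are not sorted", unit_id)
  }
  template <- as.matrix(template)
  electrode_positions <- as.matrix(electrode_positions)
  if (nrow(template) != nrow(electrode_positions)) {
    stop_mea("CorruptInput",
             "unit %s: template has %d electrodes but positions have %d rows",
             unit_id, nrow(template), nrow(electrode_positions))
  }
  structure(list(unit_id = as.integer(unit_id),
                 spike_times_s = spike_times_s,
                 template = template,
                 electrode_positions = electrode_positions),
            class = "mea_unit")
}

#' Construct a sorted recording
#'
#' One culture recorded at one time point: a list of spike-sorted units plus
#' the culture metadata used downstream (group label, treatment, batch, age).
#'
#' @param culture_id character culture identifier.
#' @param units list of [mea_unit()] objects with unique IDs.
#' @param duration_s positive recording duration in seconds.
#' @param sampling_rate_hz positive sampling rate in Hz.
#' @param group character group label (e.g. genotype "WT"/"A53T").
#' @param treatment character treatment label (default "none").
#' @param batch character batch identifier.
#' @param age_days non-negative integer culture age in days in vitro. The
#'   recording week is `floor(age_days / 7)`.
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(culture_id, units, duration_s, sampling_rate_hz,
                          group = NA_character_, treatment = "none",
                          batch = NA_character_, age_days = NA_integer_) {
  stopifnot(duration_s > 0, sampling_rate_hz > 0)
  ids <- vapply(units, function(u) u$unit_id, integer(1))
  if (anyDuplicated(ids)) {
    stop_mea("CorruptInput", "duplicate unit IDs in recording %s", culture_id)
  }
  for (u in units) {
    if (length(u$spike_times_s) &&
        (u$spike_times_s[1] < 0 || max(u$spike_times_s) > duration_s)) {
      stop_mea("CorruptInput",
               "unit %d of %s has spike times outside [0, duration]",
               u$unit_id, culture_id)
    }
  }
  structure(list(culture_id = as.character(culture_id),
                 group = as.character(group),
                 treatment = as.character(treatment),
                 batch = as.character(batch),
                 age_days = as.integer(age_days),
                 duration_s = as.numeric(duration_s),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 units = units),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> culture %s | group %s | treatment %s | batch %s\n",
              x$culture_id, x$group, x$treatment, x$batch))
  cat(sprintf("  age %s days (week %s), %.1f s at %.0f Hz, %d units, %d spikes\n",
              x$age_days, age_week(x), x$duration_s, x$sampling_rate_hz,
              length(x$units),
              sum(vapply(x$units, function(u) length(u$spike_times_s), numeric(1)))))
  invisible(x)
}

#' @export
print.mea_unit <- function(x, ...) {
  cat(sprintf("<mea_unit> id %d: %d spikes, template %d electrodes x %d samples\n",
              x$unit_id, length(x$spike_times_s),
              nrow(x$template), ncol(x$template)))
  invisible(x)
}

#' Recording week from age in days
#'
#' @param x an `mea_recording` or an integer vector of ages in days.
#' @return integer week, `floor(age_days / 7)`.
#' @export
age_week <- function(x) {
  days <- if (inherits(x, "mea_recording")) x$age_days else x
  as.integer(floor(days / 7))
}

unit_ids <- function(rec) vapply(rec$units, function(u) u$unit_id, integer(1))

n_spikes <- function(rec) {
  sum(vapply(rec$units, function(u) length(u$spike_times_s), numeric(1)))
}
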