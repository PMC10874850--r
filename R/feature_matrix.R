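#' Average per-unit features to one culture-level vector
#'
#' Per-feature mean across units, ignoring not-available values; the number
#' of units contributing to each feature is recorded alongside.
#'
#' @param per_unit data frame of per-unit feature values (numeric columns).
#' @return List with `value` (named numeric vector of means) and `n_units`
#'   (named integer vector of contributing units per feature). With zero
#'   rows every feature is `NA`.
#' @export
aggregate_culture <- function(per_unit) {
  num <- per_unit[vapply(per_unit, is.numeric, logical(1))]
  if (!nrow(num)) {
    return(list(value = setNames(rep(NA_real_, ncol(num)), names(num)),
                n_units = setNames(rep(0L, ncol(num)), names(num))))
  }
  list(value = vapply(num, function(v) {
         if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
       }, numeric(1)),
       n_units = vapply(num, function(v) sum(!is.na(v)), integer(1)))
}

#' Extract the full culture-level feature vector of one recording
#'
#' Runs the complete per-recording feature pipeline: per-unit waveform,
#' spike-time and time-series features averaged across units (`s` prefix on
#' the time-series block), network-burst features, graph features on the
#' functional connectivity graph, and network-level time-series features
#' (`n` prefix).
#'
#' @param rec an [mea_recording()] (typically after [run_quality_control()]).
#' @param bin_s activity bin width (s).
#' @param graph_method `"sttc"` (default) or `"ccg"` for the connectivity
#'   graph behind `DEC`/`GEC`.
#' @param graph_seed seed for the CCG jitter surrogates (ignored for STTC).
#' @return One-row data frame: metadata columns (`culture_id`, `group`,
#'   `treatment`, `batch`, `age_days`, `week`, `n_units`) followed by the
#'   feature columns, with a `feature_class` attribute mapping each feature
#'   column to its class (`waveform`, `spike-time`, `sc-time-series`,
#'   `burst`, `graph`, `net-time-series`).
#' @export
extract_culture_features <- function(rec, bin_s = 0.1,
                                     graph_method = c("sttc", "ccg"),
                                     graph_seed = 1) {
  graph_method <- match.arg(graph_method)
  n_units <- length(rec$units)
  classes <- c()

  if (n_units > 0) {
    wf <- do.call(rbind, lapply(rec$units, function(u) {
      tryCatch(extract_waveform_features(u, rec$sampling_rate_hz),
               meaphys_error = function(e) NULL)
    }))
    stf <- do.call(rbind, lapply(rec$units, extract_spike_time_features,
                                 duration_s = rec$duration_s))
    tsf <- do.call(rbind, lapply(rec$units, function(u) {
      extract_timeseries_features(bin_spikes(u$spike_times_s,
                                             rec$duration_s, bin_s), bin_s)
    }))
    names(tsf) <- paste0("s", names(tsf))
    wf_mean <- aggregate_culture(wf %||% data.frame())$value
    if (!length(wf_mean)) {
      wf_mean <- setNames(rep(NA_real_, 8),
                          names(extract_waveform_features(rec$units[[1]])))
    }
    st_mean <- aggregate_culture(stf)$value
    ts_mean <- aggregate_culture(tsf)$value
  } else {
    wf_mean <- setNames(rep(NA_real_, 8),
                        c("trough_amplitude_uV", "peak_amplitude_uV",
                          "trough_to_peak_ms", "half_width_ms", "asymmetry",
                          "repolarization_slope_uV_per_ms",
                          "recovery_slope_uV_per_ms", "peak_trough_ratio"))
    st_mean <- setNames(rep(NA_real_, 4),
                        c("MIS", "CVI", "firing_rate_hz", "isi_pacf1"))
    ts_mean <- setNames(rep(NA_real_, 22),
                        paste0("s", timeseries_feature_names()))
  }

  pop <- if (n_units > 0) bin_population(rec, bin_s) else NULL
  if (!is.null(pop)) {
    bs <- detect_network_bursts(pop)
    burst <- unlist(bs[c("burst_rate_per_min", "MIB", "MFT",
                         "mean_duration_s", "mean_rise_s",
                         "burst_amplitude_hz")])
    nts <- unlist(extract_network_timeseries_features(pop))
  } else {
    burst <- setNames(rep(NA_real_, 6),
                      c("burst_rate_per_min", "MIB", "MFT", "mean_duration_s",
                        "mean_rise_s", "burst_amplitude_hz"))
    nts <- setNames(rep(NA_real_, 22),
                    paste0("n", timeseries_feature_names()))
  }

  graph <- c(DEC = NA_real_, GEC = NA_real_)
  if (n_units >= 2) {
    g <- tryCatch({
      if (graph_method == "sttc") {
        infer_connectivity_sttc(rec)
      } else {
        infer_connectivity_ccg(rec, seed = graph_seed)
      }
    }, meaphys_error = function(e) NULL)
    if (!is.null(g)) graph <- unlist(compute_graph_features(g))
  }

  vals <- c(wf_mean, st_mean, ts_mean, burst, graph, nts)
  classes <- c(rep("waveform", length(wf_mean)),
               rep("spike-time", length(st_mean)),
               rep("sc-time-series", length(ts_mean)),
               rep("burst", length(burst)),
               rep("graph", length(graph)),
               rep("net-time-series", length(nts)))
  out <- cbind(data.frame(culture_id = rec$culture_id, group = rec$group,
                          treatment = rec$treatment, batch = rec$batch,
                          age_days = rec$age_days, week = age_week(rec),
                          n_units = n_units),
               as.data.frame(as.list(vals)))
  attr(out, "feature_class") <- setNames(classes, names(vals))
  out
}

#' Extract culture-level features for a list of recordings
#'
#' @param recordings list of [mea_recording()] objects.
#' @param qc apply [run_quality_control()] first (default TRUE).
#' @param ... passed to [extract_culture_features()] and, where named,
#'   to [run_quality_control()].
#' @return Long-assemblable feature table: one row per recording.
#' @export
extract_study_features <- function(recordings, qc = TRUE, ...) {
  dots <- list(...)
  qc_args <- dots[names(dots) %in% names(formals(run_quality_control))]
  fx_args <- dots[names(dots) %in% names(formals(extract_culture_features))]
  rows <- lapply(recordings, function(rec) {
    if (qc) rec <- do.call(run_quality_control, c(list(rec), qc_args))$recording
    do.call(extract_culture_features, c(list(rec), fx_args))
  })
  fc <- attr(rows[[1]], "feature_class")
  out <- do.call(rbind, rows)
  attr(out, "feature_class") <- fc
  rownames(out) <- NULL
  out
}

#' Assemble the cultures x (weeks x features) matrix
#'
#' Pivots a per-recording feature table into the rectangular matrix the ML
#' layer consumes: one row per culture, columns ordered week-major then by
#' feature name. Feature classes and weeks can be subset. Missing
#' culture-week cells are imputed with the per-column median of same-group
#' cultures and flagged in the `imputed` mask.
#'
#' @param features table from [extract_study_features()] (its
#'   `feature_class` attribute drives class selection).
#' @param classes character vector of feature classes to keep (default all).
#' @param weeks integer vector of weeks to keep (default all observed).
#' @return An object of class `mea_feature_matrix`: `values` (numeric
#'   matrix), `rows` (culture metadata data frame), `columns` (week/feature/
#'   class data frame), `imputed` (logical mask).
#' @export
assemble_feature_matrix <- function(features, classes = NULL, weeks = NULL) {
  fc <- attr(features, "feature_class")
  if (is.null(fc)) stop_mea("InvalidSelection", "features lack class metadata")
  if (is.null(classes)) classes <- unique(fc)
  keep_feats <- names(fc)[fc %in% classes]
  if (!length(keep_feats)) stop_mea("InvalidSelection", "empty feature selection")
  if (is.null(weeks)) weeks <- sort(unique(features$week))
  if (!length(weeks) || !any(features$week %in% weeks)) {
    stop_mea("InvalidSelection", "no recordings in the selected weeks")
  }
  keep_feats <- sort(keep_feats)
  weeks <- sort(weeks)

  cultures <- unique(features[, c("culture_id", "group", "treatment", "batch")])
  cultures <- cultures[order(cultures$culture_id), ]
  rownames(cultures) <- NULL

  cols <- expand.grid(feature = keep_feats, week = weeks,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cols <- cols[order(cols$week, cols$feature), c("week", "feature")]
  cols$class <- unname(fc[cols$feature])
  rownames(cols) <- NULL

  M <- matrix(NA_real_, nrow(cultures), nrow(cols),
              dimnames = list(cultures$culture_id,
                              paste0("w", cols$week, "_", cols$feature)))
  for (r in seq_len(nrow(features))) {
    w <- features$week[r]
    if (!w %in% weeks) next
    ci <- match(features$culture_id[r], cultures$culture_id)
    ji <- which(cols$week == w)
    M[ci, ji] <- as.numeric(features[r, cols$feature[ji]])
  }

  imputed <- is.na(M)
  for (j in seq_len(ncol(M))) {
    nas <- is.na(M[, j])
    if (!any(nas)) next
    for (i in which(nas)) {
      same <- cultures$group == cultures$group[i]
      med <- stats::median(M[same, j], na.rm = TRUE)
      if (is.na(med)) med <- stats::median(M[, j], na.rm = TRUE)
      M[i, j] <- med
    }
  }
  bad <- colSums(!is.na(M)) == 0
  if (any(bad)) {
    M <- M[, !bad, drop = FALSE]
    cols <- cols[!bad, ]
    imputed <- imputed[, !bad, drop = FALSE]
  }
  structure(list(values = M, rows = cultures, columns = cols,
                 imputed = imputed),
            class = "mea_feature_matrix")
}

#' @export
print.mea_feature_matrix <- function(x, ...) {
  cat(sprintf("<mea_feature_matrix> %d cultures x %d columns (%d weeks, %d features)\n",
              nrow(x$values), ncol(x$values), length(unique(x$columns$week)),
              length(unique(x$columns$feature))))
  invisible(x)
}

#' Batchwise z-scoring with train-derived parameters
#'
#' Transforms every column to z-scores per batch, using means and sample
#' standard deviations computed on the training rows only; test rows are
#' transformed with the training parameters, never their own. Zero-variance
#' columns map to 0. Batches with fewer than 2 training rows fall back to
#' global training parameters (with a warning).
#'
#' @param m an `mea_feature_matrix`.
#' @param train_rows integer or logical index of training rows.
#' @return List with `values` (normalized matrix over all rows) and
#'   `params` (per-batch list of `mean`/`sd` vectors, plus the global
#'   fallback).
#' @export
batch_zscore <- function(m, train_rows = seq_len(nrow(m$values))) {
  M <- m$values
  batches <- m$rows$batch
  train <- logical(nrow(M))
  train[train_rows] <- TRUE
  g_mean <- colMeans(M[train, , drop = FALSE])
  g_sd <- apply(M[train, , drop = FALSE], 2, stats::sd)
  params <- list(global = list(mean = g_mean, sd = g_sd))
  out <- M
  for (b in unique(batches)) {
    rows_b <- batches == b
    tr_b <- rows_b & train
    if (sum(tr_b) >= 2) {
      mu <- colMeans(M[tr_b, , drop = FALSE])
      sd_ <- apply(M[tr_b, , drop = FALSE], 2, stats::sd)
    } else {
      warning(sprintf("batch %s has < 2 training rows; using global parameters", b))
      mu <- g_mean
      sd_ <- g_sd
    }
    params[[b]] <- list(mean = mu, sd = sd_)
    sd_safe <- ifelse(is.na(sd_) | sd_ == 0, Inf, sd_)
    out[rows_b, ] <- sweep(sweep(M[rows_b, , drop = FALSE], 2, mu), 2,
                           sd_safe, "/")
  }
  out[!is.finite(out)] <- 0
  list(values = out, params = params)
}
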