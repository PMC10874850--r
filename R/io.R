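#' Load a spike-sorted recording from disk
#'
#' Two on-disk layouts are supported and auto-detected:
#'
#' * **phy/Kilosort layout**: a directory with `spike_times.npy` (sample
#'   indices), `spike_clusters.npy` (or `spike_templates.npy`),
#'   `templates.npy` (unit x sample x electrode, or unit x electrode x
#'   sample), `channel_positions.npy` and optionally `params.py` carrying
#'   `sample_rate`.
#' * **portable exchange bundle**: a directory with `manifest.json`,
#'   `spikes.csv` (`unit_id,time_s`) and `templates.csv` (long format
#'   `unit_id,electrode,sample,amplitude_uv` plus `electrodes.csv` with
#'   `electrode,x_um,y_um`), as written by [write_recording_bundle()].
#'
#' @param path directory containing one of the supported layouts.
#' @param metadata named list or one-row data frame supplying at least
#'   `culture_id`; `group`, `treatment`, `batch`, `age_days`, `duration_s`
#'   and `sampling_rate_hz` are used when present. Entries override values
#'   stored in a bundle manifest.
#' @return A validated [mea_recording()].
#' @export
load_recording <- function(path, metadata = list()) {
  if (!dir.exists(path)) stop_mea("MissingInput", "no such directory: %s", path)
  metadata <- as.list(metadata)
  if (file.exists(file.path(path, "manifest.json"))) {
    load_bundle(path, metadata)
  } else if (file.exists(file.path(path, "spike_times.npy"))) {
    load_phy(path, metadata)
  } else {
    stop_mea("MissingInput",
             "%s contains neither manifest.json nor spike_times.npy", path)
  }
}

require_meta <- function(metadata, field) {
  if (is.null(metadata[[field]]) || is.na(metadata[[field]])) {
    stop_mea("MetadataError", "required metadata field '%s' missing", field)
  }
  metadata[[field]]
}

load_phy <- function(path, metadata) {
  need <- c("spike_times.npy", "templates.npy", "channel_positions.npy")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop_mea("MissingInput", "missing files in %s: %s", path,
             paste(missing, collapse = ", "))
  }
  cluster_file <- if (file.exists(file.path(path, "spike_clusters.npy"))) {
    "spike_clusters.npy"
  } else if (file.exists(file.path(path, "spike_templates.npy"))) {
    "spike_templates.npy"
  } else {
    stop_mea("MissingInput", "missing files in %s: spike_clusters.npy", path)
  }

  samples <- as.numeric(read_npy(file.path(path, "spike_times.npy")))
  clusters <- as.integer(read_npy(file.path(path, cluster_file)))
  if (length(samples) != length(clusters)) {
    stop_mea("CorruptInput",
             "spike_times (%d) and %s (%d) differ in length",
             length(samples), cluster_file, length(clusters))
  }
  templates <- read_npy(file.path(path, "templates.npy"))
  positions <- read_npy(file.path(path, "channel_positions.npy"))

  fs <- metadata$sampling_rate_hz %||% read_params_py(path)
  if (is.null(fs)) {
    stop_mea("MetadataError",
             "sampling_rate_hz not in metadata and no params.py found")
  }
  times_s <- samples / fs
  duration <- metadata$duration_s %||% (max(times_s) + 1 / fs)

  # templates.npy is unit x sample x electrode in phy convention; accept the
  # transposed layout by matching the electrode axis to channel_positions.
  n_elec <- nrow(as.matrix(positions))
  get_template <- function(i) {
    tp <- templates[i, , ]
    if (ncol(tp) == n_elec && nrow(tp) != n_elec) tp <- t(tp)
    tp
  }
  units <- lapply(sort(unique(clusters)), function(cl) {
    mea_unit(unit_id = cl,
             spike_times_s = sort(times_s[clusters == cl]),
             template = get_template(cl + 1L),
             electrode_positions = as.matrix(positions))
  })
  mea_recording(culture_id = require_meta(metadata, "culture_id"),
                units = units, duration_s = duration, sampling_rate_hz = fs,
                group = metadata$group %||% NA_character_,
                treatment = metadata$treatment %||% "none",
                batch = metadata$batch %||% NA_character_,
                age_days = metadata$age_days %||% NA_integer_)
}

read_params_py <- function(path) {
  pf <- file.path(path, "params.py")
  if (!file.exists(pf)) return(NULL)
  lines <- readLines(pf, warn = FALSE)
  hit <- grep("^\\s*sample_rate\\s*=", lines, value = TRUE)
  if (!length(hit)) return(NULL)
  as.numeric(sub(".*=\\s*([0-9.eE+]+).*", "\\1", hit[1]))
}

load_bundle <- function(path, metadata) {
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  for (f in c("spikes.csv", "templates.csv", "electrodes.csv")) {
    if (!file.exists(file.path(path, f))) {
      stop_mea("MissingInput", "bundle %s lacks %s", path, f)
    }
  }
  meta <- utils::modifyList(as.list(man$metadata %||% man), metadata)
  spikes <- utils::read.csv(file.path(path, "spikes.csv"))
  tmpl <- utils::read.csv(file.path(path, "templates.csv"))
  elec <- utils::read.csv(file.path(path, "electrodes.csv"))
  if (!all(c("unit_id", "time_s") %in% names(spikes))) {
    stop_mea("CorruptInput", "spikes.csv must have unit_id,time_s columns")
  }
  positions <- as.matrix(elec[order(elec$electrode), c("x_um", "y_um")])
  ids <- sort(unique(c(spikes$unit_id, tmpl$unit_id)))
  units <- lapply(ids, function(id) {
    tu <- tmpl[tmpl$unit_id == id, ]
    n_samp <- max(tu$sample) + 1L
    tp <- matrix(0, nrow = nrow(positions), ncol = n_samp)
    tp[cbind(tu$electrode + 1L, tu$sample + 1L)] <- tu$amplitude_uv
    mea_unit(unit_id = id,
             spike_times_s = sort(spikes$time_s[spikes$unit_id == id]),
             template = tp, electrode_positions = positions)
  })
  mea_recording(culture_id = require_meta(meta, "culture_id"),
                units = units,
                duration_s = require_meta(meta, "duration_s"),
                sampling_rate_hz = require_meta(meta, "sampling_rate_hz"),
                group = meta$group %||% NA_character_,
                treatment = meta$treatment %||% "none",
                batch = meta$batch %||% NA_character_,
                age_days = meta$age_days %||% NA_integer_)
}

#' Write a recording as a portable exchange bundle
#'
#' Writes the JSON-manifest + CSV layout that [load_recording()] reads back;
#' spike times round-trip exactly (they are printed at full double
#' precision).
#'
#' @param rec an [mea_recording()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_recording_bundle <- function(rec, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  man <- list(format = "meaphys-bundle", version = 1L,
              metadata = list(culture_id = rec$culture_id, group = rec$group,
                              treatment = rec$treatment, batch = rec$batch,
                              age_days = rec$age_days,
                              duration_s = rec$duration_s,
                              sampling_rate_hz = rec$sampling_rate_hz))
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  spikes <- do.call(rbind, lapply(rec$units, function(u) {
    data.frame(unit_id = u$unit_id, time_s = u$spike_times_s)
  }))
  if (is.null(spikes)) spikes <- data.frame(unit_id = integer(), time_s = numeric())
  write_csv_full(spikes, file.path(path, "spikes.csv"))
  tmpl <- do.call(rbind, lapply(rec$units, function(u) {
    idx <- expand.grid(electrode = seq_len(nrow(u$template)) - 1L,
                       sample = seq_len(ncol(u$template)) - 1L)
    data.frame(unit_id = u$unit_id, electrode = idx$electrode,
               sample = idx$sample,
               amplitude_uv = u$template[cbind(idx$electrode + 1L,
                                               idx$sample + 1L)])
  }))
  write_csv_full(tmpl, file.path(path, "templates.csv"))
  pos <- rec$units[[1]]$electrode_positions
  write_csv_full(data.frame(electrode = seq_len(nrow(pos)) - 1L,
                            x_um = pos[, 1], y_um = pos[, 2]),
                 file.path(path, "electrodes.csv"))
  invisible(path)
}

# CSV writer at full double precision (so round-trips are exact).
write_csv_full <- function(df, path) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- sprintf("%.17g", df[[col]])
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a culture metadata table
#'
#' @param path CSV or JSON file with columns/fields `culture_id`, `group`,
#'   `treatment`, `batch`, `age_days`.
#' @return A data frame with one row per culture-recording.
#' @export
read_metadata <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  need <- c("culture_id", "group", "age_days")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_mea("MetadataError", "metadata lacks columns: %s",
             paste(missing, collapse = ", "))
  }
  df
}
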