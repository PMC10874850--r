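# Tiny NPY v1.0 writer used only to build phy-style fixtures in tests.
write_npy_test <- function(x, path, dtype = c("f8", "i4")) {
  dtype <- switch(match.arg(dtype), f8 = "<f8", i4 = "<i4")
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  shape <- paste0("(", paste(dims, collapse = ", "),
                  if (length(dims) == 1) "," else "", ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    dtype, shape)
  pad <- 64 - ((10 + nchar(header) + 1) %% 64)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, utf8ToInt("NUMPY"), 0x01, 0x00)), con)
  writeBin(nchar(header), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  # C order: flatten row-major
  vals <- if (is.null(dim(x))) x else as.vector(aperm(x))
  if (dtype == "<f8") {
    writeBin(as.numeric(vals), con, size = 8, endian = "little")
  } else {
    writeBin(as.integer(vals), con, size = 4, endian = "little")
  }
  invisible(path)
}

# A minimal deterministic 3-unit phy fixture at 20 kHz.
make_phy_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spikes <- c(200, 400, 1000, 3000, 5000, 2000, 4000) # sample indices
  clusters <- c(0L, 0L, 1L, 1L, 1L, 2L, 2L)
  write_npy_test(spikes, file.path(dir, "spike_times.npy"))
  write_npy_test(clusters, file.path(dir, "spike_clusters.npy"), "i4")
  tmpl <- array(0, dim = c(3, 30, 4)) # unit x sample x electrode
  for (u in 1:3) tmpl[u, 10, u] <- -40 - 10 * u
  for (u in 1:3) tmpl[u, 16, u] <- 15
  write_npy_test(tmpl, file.path(dir, "templates.npy"))
  pos <- matrix(c(0, 0, 17.5, 0, 0, 17.5, 17.5, 17.5), ncol = 2, byrow = TRUE)
  write_npy_test(pos, file.path(dir, "channel_positions.npy"))
  writeLines("sample_rate = 20000.0", file.path(dir, "params.py"))
  dir
}

ids_of <- function(rec) vapply(rec$units, `[[`, integer(1), "unit_id")

# Quick unit/recording builders for tests.
test_template <- function(trough = -50, n_elec = 2, n_samp = 40,
                          trough_at = 15, peak_at = 25, peak = 20) {
  tp <- matrix(0, n_elec, n_samp)
  tp[1, trough_at] <- trough
  tp[1, peak_at] <- peak
  tp
}

test_unit <- function(id, st, trough = -50, ...) {
  tp <- test_template(trough = trough, ...)
  mea_unit(id, st, tp, cbind(seq_len(nrow(tp)) * 17.5, 0))
}

test_recording <- function(units, duration = 10, ...) {
  mea_recording("test", units, duration_s = duration,
                sampling_rate_hz = 20000, group = "WT", batch = "b1",
                age_days = 7, ...)
}
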