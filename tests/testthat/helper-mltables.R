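# Designed per-recording feature tables for exercising the ML layer without
# spike-level simulation: features are Gaussian noise, optionally with a
# group effect on selected columns, an age trend, and batch offsets.
make_synth_features <- function(n_per_group = 10, weeks = 1:5, n_feat = 6,
                                effect = 2, informative = 1, age_slope = 0,
                                batch_shift = 0.5, noise = 1, seed = 1,
                                groups = c("WT", "A53T")) {
  withr::with_seed(seed, {
    rows <- list()
    feat_names <- sprintf("f%02d", seq_len(n_feat))
    idx <- 0
    for (g in groups) {
      for (i in seq_len(n_per_group)) {
        idx <- idx + 1
        cid <- sprintf("%s_%02d", g, i)
        batch <- sprintf("batch%d", 1 + (idx %% 2))
        for (w in weeks) {
          v <- rnorm(n_feat, 0, noise)
          v <- v + age_slope * (7 * w)
          if (g == groups[2]) v[seq_len(informative)] <- v[seq_len(informative)] + effect
          v <- v + (batch == "batch2") * batch_shift
          rows[[length(rows) + 1]] <- cbind(
            data.frame(culture_id = cid, group = g, treatment = "none",
                       batch = batch, age_days = 7L * w, week = w,
                       n_units = 10L),
            as.data.frame(as.list(setNames(v, feat_names))))
        }
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "feature_class") <- setNames(rep("spike-time", n_feat),
                                           feat_names)
    out
  })
}
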