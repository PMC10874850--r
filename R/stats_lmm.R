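#' Build a long trajectory table from a per-recording feature table
#'
#' @param features table from [extract_study_features()].
#' @param feature_names columns to melt (default: all feature columns).
#' @return Long data frame with `culture_id`, `group`, `week`, `feature`,
#'   `value` — one row per culture x time x feature.
#' @export
trajectory_table <- function(features, feature_names = NULL) {
  fc <- attr(features, "feature_class")
  if (is.null(feature_names)) feature_names <- names(fc)
  do.call(rbind, lapply(feature_names, function(f) {
    data.frame(culture_id = features$culture_id, group = features$group,
               week = features$week, feature = f,
               value = as.numeric(features[[f]]))
  }))
}

#' Linear mixed-effects test of a developmental feature trajectory
#'
#' Fits `value ~ 1 + group * time + (1 | culture)` by REML with
#' sum-to-zero (effects) coding of the group factor and time in weeks
#' centered at the first observed week. Fixed-effect t-tests use the
#' Satterthwaite approximation for the denominator degrees of freedom. A
#' singular random-effect variance keeps the fit but is flagged.
#'
#' @param traj long table from [trajectory_table()] (or equivalent columns).
#' @param feature feature name to test.
#' @return One-row data frame with, per fixed effect (`intercept`, `group`,
#'   `time`, `group_time`), the estimate, standard error, Satterthwaite df
#'   and raw p-value, plus `singular`.
#' @export
fit_lmm_trajectory <- function(traj, feature) {
  d <- traj[traj$feature == feature & !is.na(traj$value), ]
  if (!nrow(d)) stop_mea("InvalidLabels", "no data for feature %s", feature)
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2) stop_mea("InvalidLabels", "need >= 2 groups")
  stats::contrasts(d$group) <- stats::contr.sum(nlevels(d$group))
  d$time <- d$week - min(d$week)
  fit <- suppressMessages(lmerTest::lmer(
    value ~ 1 + group * time + (1 | culture_id), data = d, REML = TRUE))
  co <- summary(fit)$coefficients
  terms <- c(intercept = "(Intercept)", group = "group1", time = "time",
             group_time = "group1:time")
  out <- data.frame(feature = feature, singular = lme4::isSingular(fit))
  for (nm in names(terms)) {
    row <- co[terms[nm], ]
    out[[paste0(nm, "_estimate")]] <- row[["Estimate"]]
    out[[paste0(nm, "_se")]] <- row[["Std. Error"]]
    out[[paste0(nm, "_df")]] <- row[["df"]]
    out[[paste0(nm, "_p")]] <- row[["Pr(>|t|)"]]
  }
  out
}

#' Bonferroni adjustment
#'
#' @param p raw p-values in `[0, 1]`.
#' @param n_features number of comparisons.
#' @return `pmin(1, p * n_features)`.
#' @export
adjust_bonferroni <- function(p, n_features) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, p * n_features)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**",
                                     ifelse(p < 0.05, "*", ""))))
}

#' Mixed-model scan over all features
#'
#' Runs [fit_lmm_trajectory()] per feature, Bonferroni-adjusts each fixed
#' effect's p-values across features and annotates significance stars
#' (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, on the adjusted values).
#'
#' @param traj long trajectory table.
#' @param features features to test (default: all present).
#' @return Data frame, one row per feature.
#' @export
lmm_feature_scan <- function(traj, features = unique(traj$feature)) {
  rows <- lapply(features, function(f) {
    tryCatch(fit_lmm_trajectory(traj, f), error = function(e) NULL)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  n <- nrow(out)
  for (eff in c("group", "time", "group_time")) {
    out[[paste0(eff, "_p_adj")]] <- adjust_bonferroni(out[[paste0(eff, "_p")]], n)
    out[[paste0(eff, "_stars")]] <- significance_stars(out[[paste0(eff, "_p_adj")]])
  }
  out
}

#' @importFrom stats contrasts contr.sum
NULL
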