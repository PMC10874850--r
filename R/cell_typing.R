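#' Per-unit feature table for cell typing
#'
#' Rows are individual units across recordings; columns are the waveform
#' metrics, optionally combined with the per-unit activity features
#' (spike-time metrics plus the single-cell time-series set). Units whose
#' feature rows are entirely not-available are dropped.
#'
#' @param recordings list of [mea_recording()] objects (typically one
#'   baseline recording per culture).
#' @param mode `"waveform"` or `"combined"`.
#' @param bin_s bin width for the time-series features.
#' @return Data frame keyed by `culture_id`, `unit_id` with feature columns.
#' @export
unit_feature_table <- function(recordings, mode = c("waveform", "combined"),
                               bin_s = 0.1) {
  mode <- match.arg(mode)
  rows <- lapply(recordings, function(rec) {
    do.call(rbind, lapply(rec$units, function(u) {
      wf <- tryCatch(extract_waveform_features(u, rec$sampling_rate_hz),
                     meaphys_error = function(e) NULL)
      if (is.null(wf)) return(NULL)
      row <- cbind(data.frame(culture_id = rec$culture_id,
                              unit_id = u$unit_id), wf)
      if (mode == "combined") {
        st <- extract_spike_time_features(u, rec$duration_s)
        ts <- extract_timeseries_features(
          bin_spikes(u$spike_times_s, rec$duration_s, bin_s), bin_s)
        names(ts) <- paste0("s", names(ts))
        row <- cbind(row, st, ts)
      }
      row
    }))
  })
  out <- do.call(rbind, rows)
  feat <- setdiff(names(out), c("culture_id", "unit_id"))
  keep <- rowSums(!is.na(out[, feat, drop = FALSE])) > 0
  out <- out[keep, ]
  rownames(out) <- NULL
  out
}

#' Louvain clustering of units
#'
#' Z-scores the feature columns, builds a k-nearest-neighbor graph on the
#' standardized features (Euclidean distance, edges weighted 1) and runs
#' seeded Louvain community detection. Cluster IDs are relabeled by
#' descending cluster size, making the labeling invariant to row order.
#'
#' @param t table from [unit_feature_table()].
#' @param k_neighbors neighbors per unit in the graph.
#' @param resolution Louvain resolution parameter. The default 0.5 favors
#'   coarse partitions: at 1.0, modularity subdivides even a tight,
#'   well-separated cloud of similar units, which is rarely the wanted
#'   granularity for cell typing; raise it to split finer.
#' @param seed integer seed.
#' @return An `mea_cluster_assignment`: `units` (keys + `cluster`),
#'   `modularity`, `sizes`, `features` (columns used).
#' @export
cluster_units <- function(t, k_neighbors = 15, resolution = 0.5, seed = 1) {
  feat <- setdiff(names(t), c("culture_id", "unit_id"))
  n <- nrow(t)
  if (n < 10) stop_mea("InvalidParameter", ">= 10 units required, got %d", n)
  if (n <= k_neighbors) {
    stop_mea("InvalidParameter", "k_neighbors = %d >= %d units",
             k_neighbors, n)
  }
  X <- as.matrix(t[, feat, drop = FALSE])
  # columns that are constant up to numerical noise carry no structure and
  # would have that noise amplified to unit variance by z-scoring
  sds <- apply(X, 2, stats::sd)
  informative <- !is.na(sds) & sds > 1e-8 * pmax(1, abs(colMeans(X)))
  X <- scale(X[, informative, drop = FALSE])
  X[!is.finite(X)] <- 0
  if (ncol(X) == 0 || max(X) - min(X) < 1e-8) {
    # no separable structure at all: one cluster
    return(structure(list(units = cbind(t[, c("culture_id", "unit_id")],
                                        cluster = rep(1L, n)),
                          modularity = NA_real_, sizes = n, features = feat,
                          params = list(k_neighbors = k_neighbors,
                                        resolution = resolution, seed = seed)),
                     class = "mea_cluster_assignment"))
  }
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k_neighbors)]
    cbind(i, nb)
  }))
  # undirected union of the directed kNN relations
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  comm <- with_seed(seed,
                    igraph::cluster_louvain(g, resolution = resolution))
  memb <- as.integer(igraph::membership(comm))
  # relabel by descending size; ties broken by the smallest unit key in the
  # cluster (canonical order), so labels are invariant to row permutation
  canon <- order(t$culture_id, t$unit_id)
  canon_rank <- integer(n)
  canon_rank[canon] <- seq_len(n)
  sizes_tab <- tapply(rep(1L, n), memb, sum)
  first_key <- tapply(canon_rank, memb, min)
  ord <- order(-sizes_tab, first_key)
  relabel <- integer(length(ord))
  relabel[as.integer(names(sizes_tab))[ord]] <- seq_along(ord)
  cl <- relabel[memb]
  structure(list(units = cbind(t[, c("culture_id", "unit_id")],
                               cluster = cl),
                 modularity = igraph::modularity(comm),
                 sizes = as.integer(table(cl)),
                 features = feat,
                 params = list(k_neighbors = k_neighbors,
                               resolution = resolution, seed = seed)),
            class = "mea_cluster_assignment")
}

#' Train a cluster classifier on unit features
#'
#' Random-forest classifier of cluster membership, evaluated by stratified
#' 5-fold cross-validation; returns the CV confusion matrix and the OOB
#' permutation importance of every feature. Clusters below `min_size` are
#' merged into their nearest cluster (centroid distance) with a warning.
#'
#' @param t table from [unit_feature_table()].
#' @param clusters an `mea_cluster_assignment` or integer vector per row.
#' @param min_size minimum units per cluster.
#' @param n_trees trees per forest.
#' @param seed master seed.
#' @return List with `model` (refit on all units), `confusion` (5-fold CV
#'   confusion matrix), `cv_accuracy`, `importance`, `cluster` (labels
#'   after any merging), `schema`.
#' @export
train_cluster_classifier <- function(t, clusters, min_size = 5,
                                     n_trees = 500, seed = 1) {
  cl <- if (inherits(clusters, "mea_cluster_assignment")) {
    clusters$units$cluster
  } else {
    as.integer(clusters)
  }
  feat <- setdiff(names(t), c("culture_id", "unit_id"))
  X <- as.matrix(t[, feat, drop = FALSE])
  X[is.na(X)] <- 0
  # merge undersized clusters into the nearest centroid
  repeat {
    sizes <- table(cl)
    small <- names(sizes)[sizes < min_size]
    if (!length(small)) break
    warning(sprintf("cluster %s below %d units; merging into nearest cluster",
                    small[1], min_size))
    cent <- do.call(rbind, lapply(split(seq_along(cl), cl),
                                  function(i) colMeans(X[i, , drop = FALSE])))
    s <- small[1]
    others <- setdiff(rownames(cent), s)
    dd <- apply(cent[others, , drop = FALSE], 1,
                function(v) sum((v - cent[s, ])^2))
    cl[cl == as.integer(s)] <- as.integer(others[which.min(dd)])
  }
  y <- factor(cl)
  folds <- make_folds(y, 5, child_seed(seed, 1L))
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in unique(folds)) {
    tr <- folds != f
    rf <- fit_rf(scale_train(X, tr)$train, y[tr], n_trees,
                 child_seed(seed, 10L + f))
    pred[!tr] <- predict(rf, scale_train(X, tr)$test[!tr, , drop = FALSE])
  }
  rf_all <- fit_rf(scale(X), y, n_trees, child_seed(seed, 0L),
                   importance = TRUE)
  imp <- randomForest::importance(rf_all, type = 1, scale = FALSE)[, 1]
  list(model = list(rf = rf_all, schema = feat,
                    center = colMeans(X), scale = apply(X, 2, stats::sd)),
       confusion = table(truth = y, predicted = pred),
       cv_accuracy = mean(pred == y),
       importance = data.frame(feature = names(imp),
                               importance = unname(imp)),
       cluster = as.integer(as.character(y)),
       schema = feat)
}

scale_train <- function(X, tr) {
  mu <- colMeans(X[tr, , drop = FALSE])
  sd_ <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  list(train = Z[tr, , drop = FALSE], test = Z)
}

#' Predict per-culture cluster compositions
#'
#' @param model `model` element from [train_cluster_classifier()].
#' @param new_units table from [unit_feature_table()].
#' @return Data frame: one row per culture x cluster with `n` and
#'   `fraction`; fractions sum to 1 per culture.
#' @export
predict_composition <- function(model, new_units) {
  if (!nrow(new_units)) stop_mea("EmptyInput", "no units to classify")
  missing_cols <- setdiff(model$schema, names(new_units))
  if (length(missing_cols)) {
    stop_mea("SchemaError", "missing feature columns: %s",
             paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(new_units[, model$schema, drop = FALSE])
  X[is.na(X)] <- 0
  sd_ <- model$scale
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  Z <- sweep(sweep(X, 2, model$center), 2, sd_, "/")
  pred <- predict(model$rf, Z)
  by_culture <- split(pred, new_units$culture_id)
  out <- do.call(rbind, Map(function(p, id) {
    tab <- table(p)
    data.frame(culture_id = id, cluster = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / length(p))
  }, by_culture, names(by_culture)))
  rownames(out) <- NULL
  out
}

#' Map acute perturbation responses onto unit clusters
#'
#' Compares per-unit firing rates before and after an acute drug addition;
#' a unit is called a responder when its post/baseline rate ratio falls
#' below `1 - decrease_threshold` (default: a >10% rate reduction). When a
#' cluster assignment is supplied, the per-cluster responder fraction is
#' reported.
#'
#' @param baseline,post matched [mea_recording()]s (unit IDs shared).
#' @param clusters optional `mea_cluster_assignment` covering the baseline
#'   units.
#' @param decrease_threshold responder criterion on the rate decrease.
#' @return An `mea_perturbation_response`: `units` (per-unit rates, ratio,
#'   responder flag, cluster), `responder_fraction`, `per_cluster`,
#'   `n_unmatched`.
#' @export
map_perturbation_response <- function(baseline, post, clusters = NULL,
                                      decrease_threshold = 0.1) {
  ids_b <- unit_ids(baseline)
  ids_p <- unit_ids(post)
  common <- intersect(ids_b, ids_p)
  n_unmatched <- length(union(ids_b, ids_p)) - length(common)
  rows <- do.call(rbind, lapply(common, function(id) {
    ub <- baseline$units[[match(id, ids_b)]]
    up <- post$units[[match(id, ids_p)]]
    fr_b <- length(ub$spike_times_s) / baseline$duration_s
    fr_p <- length(up$spike_times_s) / post$duration_s
    data.frame(unit_id = id, baseline_fr_hz = fr_b, post_fr_hz = fr_p,
               fr_ratio = if (fr_b > 0) fr_p / fr_b else NA_real_)
  }))
  rows$responder <- !is.na(rows$fr_ratio) &
    rows$fr_ratio < 1 - decrease_threshold
  rows$culture_id <- baseline$culture_id
  per_cluster <- NULL
  if (!is.null(clusters)) {
    cu <- clusters$units[clusters$units$culture_id == baseline$culture_id, ]
    rows$cluster <- cu$cluster[match(rows$unit_id, cu$unit_id)]
    per_cluster <- stats::aggregate(responder ~ cluster,
                                    rows[!is.na(rows$cluster), ], mean)
    names(per_cluster)[2] <- "responder_fraction"
  }
  structure(list(units = rows,
                 responder_fraction = mean(rows$responder),
                 per_cluster = per_cluster,
                 n_unmatched = n_unmatched,
                 decrease_threshold = decrease_threshold),
            class = "mea_perturbation_response")
}
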