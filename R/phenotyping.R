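#' Leave-one-culture-out phenotype classification
#'
#' Trains a random-forest classifier on the culture feature matrix with one
#' cross-validation fold per culture: the held-out culture is predicted by a
#' model trained (and batchwise z-scored) on the remaining cultures only, so
#' no normalization or model parameter ever sees the held-out row. Class
#' imbalance is handled by stratified bootstrap sampling down to the
#' smallest class. A final model is refit on all rows.
#'
#' @param m an `mea_feature_matrix` from [assemble_feature_matrix()].
#' @param labels factor/character group label per row (defaults to the
#'   matrix's `group` column).
#' @param n_trees trees per forest.
#' @param seed master seed; the whole procedure is deterministic given it.
#' @param ... passed to [randomForest::randomForest()].
#' @return List with `accuracy`, `predictions` (per-fold data frame),
#'   `model` (a `mea_phenotype_model` refit on all rows).
#' @export
classify_loo <- function(m, labels = m$rows$group, n_trees = 500, seed = 1,
                         ...) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop_mea("InvalidLabels", ">= 2 classes required")
  if (any(table(y) < 2)) stop_mea("InvalidLabels", ">= 2 cultures per class required")
  n <- nrow(m$values)
  pred <- character(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    nz <- batch_zscore(m, train)
    rf <- fit_rf(nz$values[train, , drop = FALSE], y[train], n_trees,
                 child_seed(seed, i), ...)
    pred[i] <- as.character(predict(rf, nz$values[i, , drop = FALSE]))
  }
  nz_all <- batch_zscore(m)
  rf_all <- fit_rf(nz_all$values, y, n_trees, child_seed(seed, 0L),
                   importance = TRUE, ...)
  model <- structure(list(rf = rf_all, schema = colnames(m$values),
                          columns = m$columns, norm = nz_all$params,
                          task = "classification", classes = levels(y),
                          n_trees = n_trees, seed = seed),
                     class = "mea_phenotype_model")
  list(accuracy = mean(pred == as.character(y)),
       predictions = data.frame(culture_id = m$rows$culture_id,
                                truth = as.character(y), predicted = pred),
       model = model)
}

fit_rf <- function(X, y, n_trees, seed, ...) {
  # a matrix with no variation cannot grow a tree (and randomForest's C code
  # loops forever on one): fall back to the majority class / mean
  sds <- apply(X, 2, stats::sd)
  if (ncol(X) == 0 || all(is.na(sds) | sds == 0)) {
    return(constant_fit(y))
  }
  with_seed(seed, {
    if (is.factor(y)) {
      nmin <- min(table(y))
      randomForest::randomForest(X, y, ntree = n_trees, strata = y,
                                 sampsize = rep(nmin, nlevels(y)), ...)
    } else {
      # weekly recording cadence means few distinct ages; the forest is
      # still the right tool, so muffle randomForest's nudge toward
      # classification
      withCallingHandlers(
        randomForest::randomForest(X, y, ntree = n_trees, ...),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
  })
}

constant_fit <- function(y) {
  if (is.factor(y)) {
    freq <- table(y) / length(y)
    structure(list(classes = levels(y), freq = freq,
                   majority = names(freq)[which.max(freq)]),
              class = "meaphys_constant_fit")
  } else {
    structure(list(value = mean(y)), class = "meaphys_constant_fit")
  }
}

#' @export
predict.meaphys_constant_fit <- function(object, newdata, type = "response",
                                         ...) {
  n <- if (is.null(dim(newdata))) 1L else nrow(newdata)
  if (is.null(object$classes)) return(rep(object$value, n))
  if (type == "prob") {
    return(matrix(rep(as.numeric(object$freq), each = n), nrow = n,
                  dimnames = list(NULL, object$classes)))
  }
  factor(rep(object$majority, n), levels = object$classes)
}

#' @export
print.mea_phenotype_model <- function(x, ...) {
  cat(sprintf("<mea_phenotype_model> %s, %d features, %d trees\n",
              x$task, length(x$schema), x$n_trees))
  invisible(x)
}

#' Out-of-bag permutation predictor importance
#'
#' Importance of each feature column as the mean decrease in out-of-bag
#' accuracy (classification) or increase in OOB MSE (regression) when the
#' column is permuted — the standard permutation importance of a
#' random-forest ensemble. With `by_time = TRUE` the week-major columns are
#' reported grouped per recording week.
#'
#' @param model a `mea_phenotype_model` fitted with importance enabled.
#' @param by_time report one row per feature x week instead of per column.
#' @return Data frame with `feature`, `week` (if applicable), `importance`.
#' @export
permutation_importance <- function(model, by_time = FALSE) {
  imp <- if (inherits(model$rf, "meaphys_constant_fit")) {
    setNames(rep(0, length(model$schema)), model$schema)
  } else {
    randomForest::importance(model$rf, type = 1, scale = FALSE)[, 1]
  }
  tab <- data.frame(column = model$schema,
                    feature = model$columns$feature,
                    week = model$columns$week,
                    importance = unname(imp[model$schema]))
  if (!by_time) {
    agg <- stats::aggregate(importance ~ feature, tab, mean)
    return(agg[order(-agg$importance), ])
  }
  tab[order(tab$week, -tab$importance), c("feature", "week", "importance")]
}

#' Tune random-forest hyperparameters by seeded randomized search
#'
#' Draws `budget` random settings (tree count, minimum node size, features
#' per split) and scores each by inner 5-fold cross-validated accuracy on
#' the batch-normalized matrix; returns the argmax. Deterministic given the
#' seed.
#'
#' @param m an `mea_feature_matrix`.
#' @param labels group label per row.
#' @param budget number of settings evaluated (>= 1).
#' @param seed master seed.
#' @return List with `best` (the chosen settings and its score) and
#'   `trace` (all evaluated settings).
#' @export
tune_hyperparameters <- function(m, labels = m$rows$group, budget = 100,
                                 seed = 1) {
  if (budget < 1) stop_mea("InvalidParameter", "budget must be >= 1")
  y <- factor(labels)
  p <- ncol(m$values)
  grid <- with_seed(child_seed(seed, 1L), data.frame(
    n_trees = sample(c(100L, 200L, 300L, 500L, 800L), budget, replace = TRUE),
    nodesize = sample(1:10, budget, replace = TRUE),
    mtry = pmax(1L, round(p * stats::runif(budget, 0.05, 0.8)))))
  folds <- make_folds(y, 5, child_seed(seed, 2L))
  score <- vapply(seq_len(budget), function(b) {
    correct <- 0L
    for (f in unique(folds)) {
      tr <- which(folds != f)
      te <- which(folds == f)
      nz <- batch_zscore(m, tr)
      rf <- fit_rf(nz$values[tr, , drop = FALSE], y[tr], grid$n_trees[b],
                   child_seed(seed, 100L + b * 7L + f),
                   nodesize = grid$nodesize[b], mtry = grid$mtry[b])
      correct <- correct + sum(predict(rf, nz$values[te, , drop = FALSE]) == y[te])
    }
    correct / length(y)
  }, numeric(1))
  grid$score <- score
  best <- grid[which.max(score), ]
  list(best = best, trace = grid)
}

# stratified fold assignment
make_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(factor(y))) {
      idx <- which(y == cl)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

#' Pivot the per-recording feature table to a recording-level matrix
#'
#' One row per culture-recording (for age regression), rather than the
#' concatenated per-culture layout of [assemble_feature_matrix()].
#'
#' @param features table from [extract_study_features()].
#' @param classes feature classes to keep (default all).
#' @return An `mea_feature_matrix` whose `rows` carry `age_days`/`week`.
#' @export
recording_feature_matrix <- function(features, classes = NULL) {
  fc <- attr(features, "feature_class")
  if (is.null(classes)) classes <- unique(fc)
  keep <- sort(names(fc)[fc %in% classes])
  M <- as.matrix(features[, keep, drop = FALSE])
  rownames(M) <- paste0(features$culture_id, "_w", features$week)
  # median-impute within group so the matrix is complete
  for (j in seq_len(ncol(M))) {
    nas <- is.na(M[, j])
    if (any(nas)) {
      for (i in which(nas)) {
        same <- features$group == features$group[i]
        med <- stats::median(M[same, j], na.rm = TRUE)
        M[i, j] <- if (is.na(med)) stats::median(M[, j], na.rm = TRUE) else med
      }
    }
  }
  keep_col <- colSums(!is.na(M)) > 0
  M <- M[, keep_col, drop = FALSE]
  structure(list(values = M,
                 rows = features[, c("culture_id", "group", "treatment",
                                     "batch", "age_days", "week")],
                 columns = data.frame(week = NA_integer_,
                                      feature = colnames(M),
                                      class = unname(fc[colnames(M)])),
                 imputed = NULL),
            class = "mea_feature_matrix")
}

#' Leave-one-culture-out age regression
#'
#' Random-forest regression of recording age on the feature vector of each
#' recording. All recordings of a culture are held out together (the fold
#' unit is the culture), preventing culture-identity leakage. Reports the
#' mean absolute error overall and per true week, plus the
#' predict-the-training-mean baseline MAE.
#'
#' @param rm a recording-level `mea_feature_matrix` from
#'   [recording_feature_matrix()].
#' @param n_trees trees per forest.
#' @param seed master seed.
#' @return List with `mae_days`, `baseline_mae_days`, `per_week` (data
#'   frame week/mae), `predictions`.
#' @export
predict_age <- function(rm, n_trees = 500, seed = 1) {
  ages <- rm$rows$age_days
  if (length(unique(ages)) < 3) stop_mea("InvalidLabels", ">= 3 distinct ages required")
  cultures <- unique(rm$rows$culture_id)
  pred <- numeric(nrow(rm$values))
  base_pred <- numeric(nrow(rm$values))
  for (ci in seq_along(cultures)) {
    te <- which(rm$rows$culture_id == cultures[ci])
    tr <- setdiff(seq_len(nrow(rm$values)), te)
    nz <- batch_zscore(rm, tr)
    rf <- fit_rf(nz$values[tr, , drop = FALSE], ages[tr], n_trees,
                 child_seed(seed, ci))
    pred[te] <- predict(rf, nz$values[te, , drop = FALSE])
    base_pred[te] <- mean(ages[tr])
  }
  err <- abs(pred - ages)
  per_week <- stats::aggregate(err, list(week = rm$rows$week), mean)
  names(per_week)[2] <- "mae_days"
  list(mae_days = mean(err),
       baseline_mae_days = mean(abs(base_pred - ages)),
       per_week = per_week,
       predictions = data.frame(culture_id = rm$rows$culture_id,
                                week = rm$rows$week, age_days = ages,
                                predicted_days = pred))
}

#' Apply a pretrained phenotype model to new cultures
#'
#' Aligns the new matrix to the model schema by column name, normalizes the
#' new batches with their own batch statistics — computed on untreated /
#' control rows when the batch has any (treatment in `control_treatments`),
#' otherwise on all rows of the batch (flagged) — and predicts class labels
#' with per-row class scores.
#'
#' @param model a `mea_phenotype_model`.
#' @param new_m an `mea_feature_matrix` of the new cultures.
#' @param control_treatments treatments regarded as control for batch
#'   normalization.
#' @return Data frame of predictions with class score columns; attribute
#'   `batch_flags` names batches normalized without control rows.
#' @export
apply_pretrained <- function(model, new_m,
                             control_treatments = c("none", "untreated", "ntLNA")) {
  missing_cols <- setdiff(model$schema, colnames(new_m$values))
  if (length(missing_cols)) {
    stop_mea("SchemaError", "new matrix lacks columns: %s",
             paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  M <- new_m$values[, model$schema, drop = FALSE]
  batches <- new_m$rows$batch
  ctrl <- new_m$rows$treatment %in% control_treatments
  Z <- M
  flagged <- character(0)
  for (b in unique(batches)) {
    rows_b <- batches == b
    ref <- rows_b & ctrl
    if (sum(ref) < 2) {
      ref <- rows_b
      flagged <- c(flagged, b)
    }
    mu <- colMeans(M[ref, , drop = FALSE])
    sd_ <- apply(M[ref, , drop = FALSE], 2, stats::sd)
    sd_[is.na(sd_) | sd_ == 0] <- Inf
    Z[rows_b, ] <- sweep(sweep(M[rows_b, , drop = FALSE], 2, mu), 2, sd_, "/")
  }
  Z[!is.finite(Z)] <- 0
  scores <- predict(model$rf, Z, type = "prob")
  out <- data.frame(culture_id = new_m$rows$culture_id,
                    predicted = as.character(predict(model$rf, Z)))
  out <- cbind(out, as.data.frame(scores))
  attr(out, "batch_flags") <- flagged
  out
}

#' 2-D embedding, k-means clustering and cluster purity
#'
#' Embeds the batch-normalized feature matrix with UMAP (seeded), runs
#' k-means (default k = 2) on the embedding, and quantifies how well the
#' clusters separate the group labels via cluster purity:
#' `purity = (1/N) * sum_clusters max_class |cluster intersect class|`.
#'
#' @param m an `mea_feature_matrix`.
#' @param labels group label per row.
#' @param k number of k-means clusters.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed master seed.
#' @return An `mea_embedding`: `coords` (n x 2), `cluster` (k-means
#'   labels), `purity`, and the parameters used.
#' @export
embed_and_purity <- function(m, labels = m$rows$group, k = 2,
                             n_neighbors = 15, min_dist = 0.1, seed = 1) {
  n <- nrow(m$values)
  if (k > n) stop_mea("InvalidParameter", "k = %d exceeds %d rows", k, n)
  Z <- batch_zscore(m)$values
  nn <- min(n_neighbors, n - 1)
  coords <- with_seed(child_seed(seed, 1L),
                      uwot::umap(Z, n_neighbors = nn, min_dist = min_dist,
                                 n_threads = 1, n_sgd_threads = 1))
  km <- with_seed(child_seed(seed, 2L),
                  stats::kmeans(coords, centers = k, nstart = 20))
  structure(list(coords = coords, cluster = km$cluster,
                 purity = cluster_purity(km$cluster, labels),
                 params = list(k = k, n_neighbors = nn, min_dist = min_dist,
                               seed = seed)),
            class = "mea_embedding")
}

#' Cluster purity against reference labels
#'
#' @param cluster integer cluster assignment.
#' @param labels reference class labels.
#' @return Purity in `[0, 1]`; always at least the largest class frequency
#'   when clusters are informative, and exactly the largest class frequency
#'   for a single cluster.
#' @export
cluster_purity <- function(cluster, labels) {
  tab <- table(cluster, labels)
  sum(apply(tab, 1, max)) / length(cluster)
}

#' @importFrom stats kmeans
NULL
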