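#' @title Composite state indices and colony statistics
#' @description Per-replicate normalization, the Colony Growth Index (CGI)
#'   and Chromatin Reorganization Index (CRI) built by PCA followed by LDA
#'   over stage classes of the day range, protein-expression regression against the
#'   index and time, and hierarchical clustering of day-10 colonies.
#' @name state_indices
NULL

#' Min-max normalize columns within each biological replicate
#'
#' Each listed column is rescaled to [0, 1] within each replicate, so
#' replicate-specific intensity offsets drop out. Columns that are constant
#' within a replicate (including single-row replicates) map to 0.5 with a
#' warning.
#'
#' @param table data.frame with a `replicate` column.
#' @param columns character vector of columns to normalize.
#' @return the table with normalized columns.
#' @export
normalize_within_replicate <- function(table, columns) {
  stopifnot("replicate" %in% names(table), all(columns %in% names(table)))
  if (any(is.na(table$replicate)) || any(table$replicate == ""))
    stop("every row needs a replicate label", call. = FALSE)
  warned <- FALSE
  for (rep_id in unique(table$replicate)) {
    sel <- table$replicate == rep_id
    for (cl in columns) {
      v <- table[[cl]][sel]
      rng <- range(v)
      if (diff(rng) <= 0) {
        table[[cl]][sel] <- 0.5
        warned <- TRUE
      } else {
        table[[cl]][sel] <- (v - rng[1]) / diff(rng)
      }
    }
  }
  if (warned)
    warning("constant-within-replicate column(s) mapped to 0.5")
  table
}

.metadata_cols <- c("colony_id", "day", "replicate", "treatment", "branch",
                    "branch_expressed", "progression_s", "proliferating",
                    "nucleus_id", "n_nuclei", "cgi", "cri", "pseudotime")

feature_columns <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  setdiff(names(table)[num], .metadata_cols)
}

# Early/late stage classes: a median split of the sorted unique days. With
# per-day classes the near-noiseless day-0 class dominates the first
# discriminant and the index stops tracking progression; a two-stage split
# keeps the (then unique) discriminant on the progression axis.
stage_classes <- function(day) {
  ud <- sort(unique(day))
  k <- min(2L, length(ud))
  bins <- rep(seq_len(k), each = ceiling(length(ud) / k))[seq_along(ud)]
  factor(bins[match(day, ud)])
}

# Core PCA -> LDA recipe shared by CGI and CRI. Returns scores plus a
# serializable model that can be reapplied to new rows.
fit_pca_lda_index <- function(table, features, n_pc = 3L,
                              class_col = "day",
                              lda_classes = c("stage", "day")) {
  lda_classes <- match.arg(lda_classes)
  X <- as.matrix(table[, features, drop = FALSE])
  cls_raw <- table[[class_col]]
  cls <- if (lda_classes == "stage") stage_classes(cls_raw)
         else factor(cls_raw)
  if (length(unique(cls_raw)) < 2)
    stop("need at least 2 distinct ", class_col, " labels", call. = FALSE)
  if (nrow(X) <= n_pc)
    stop("need more rows than principal components", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0))
    stop("zero-variance feature(s): ",
         paste(features[scl == 0], collapse = ", "), call. = FALSE)
  Z <- scale(X, center = ctr, scale = scl)
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pca$rotation))
  pcs <- pca$x[, seq_len(n_pc), drop = FALSE]
  # degenerate within-class scatter gives lda a singular covariance
  for (g in unique(cls)) {
    sub <- pcs[cls == g, , drop = FALSE]
    if (nrow(sub) > 1 && all(apply(sub, 2, stats::sd) < 1e-12))
      stop("numerical degeneracy: identical rows within class '", g, "'",
           call. = FALSE)
  }
  ld <- MASS::lda(pcs, grouping = cls)
  w <- ld$scaling[, 1]
  scores <- as.numeric(pcs %*% w)
  # orientation: mean score at the latest day exceeds the mean at the
  # earliest day, so the index increases along confined growth
  days_num <- as.numeric(as.character(cls_raw))
  sgn <- if (mean(scores[days_num == max(days_num)]) >=
             mean(scores[days_num == min(days_num)])) 1 else -1
  scores <- sgn * scores
  model <- list(features = features, center = ctr, scale = scl,
                pca_loadings = pca$rotation[, seq_len(n_pc), drop = FALSE],
                lda_weights = w, orientation_sign = sgn,
                training_days = sort(unique(days_num)),
                training_scores = scores)
  class(model) <- "index_model"
  list(scores = scores, model = model)
}

#' Apply a fitted index model to new rows
#'
#' @param model an `index_model` from [compute_cgi()] or [compute_cri()].
#' @param table data.frame containing the model's feature columns.
#' @return numeric index scores.
#' @export
apply_index_model <- function(model, table) {
  missing_cols <- setdiff(model$features, names(table))
  if (length(missing_cols) > 0)
    stop("missing feature columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(table[, model$features, drop = FALSE])
  Z <- scale(X, center = model$center, scale = model$scale)
  pcs <- Z %*% model$pca_loadings
  as.numeric(model$orientation_sign * (pcs %*% model$lda_weights))
}

#' Colony Growth Index (CGI)
#'
#' Features are z-scored, reduced to the first three principal components,
#' and collapsed to a single discriminant by LDA. Class labels default to
#' an early/late stage split of the day range (per-day classes available
#' via `lda_classes = "day"`). The sign is fixed so the mean CGI at the
#' latest training day exceeds the mean at day 0: CGI increases as small
#' elongated colonies become large spheroids.
#'
#' @param table colony feature table with `day` (and feature columns).
#' @param features feature columns (default: all numeric non-metadata).
#' @param n_pc number of principal components fed to LDA.
#' @param ... forwarded to the fitting core (notably `lda_classes`,
#'   `"stage"` terciles of the day range by default, or `"day"`).
#' @return list: `scores` (per colony), `model` (an `index_model`).
#' @export
compute_cgi <- function(table, features = feature_columns(table),
                        n_pc = 3L, ...) {
  fit_pca_lda_index(table, features, n_pc, ...)
}

#' Chromatin Reorganization Index (CRI)
#'
#' The CGI recipe applied to nuclear morphology and chromatin features
#' (nuclear volume/shape, heterochromatin volume and fraction, co-occurrence
#' textures). Per-colony CRI is the mean over the colony's nuclei.
#'
#' @param nucleus_table per-nucleus feature table with `day` and
#'   `colony_id`.
#' @param features nuclear feature columns.
#' @param n_pc number of principal components fed to LDA.
#' @param ... forwarded to the fitting core (notably `lda_classes`).
#' @return list: `scores` (per nucleus), `colony_scores` (named per-colony
#'   means), `model`.
#' @export
compute_cri <- function(nucleus_table,
                        features = feature_columns(nucleus_table),
                        n_pc = 3L, ...) {
  fit <- fit_pca_lda_index(nucleus_table, features, n_pc, ...)
  colony <- tapply(fit$scores, nucleus_table$colony_id, mean)
  list(scores = fit$scores, colony_scores = colony, model = fit$model)
}

#' Regression of protein expression on CGI and time
#'
#' Least-squares fit of `protein ~ CGI + day` on a random train split;
#' the coefficient of determination and Pearson correlation are reported on
#' the held-out split.
#'
#' @param table data.frame with `cgi`, `day` and the protein column.
#' @param protein name of the protein column.
#' @param train_fraction fraction of rows used for fitting.
#' @param seed split seed (recorded in the model).
#' @return list of class `protein_regression`: `coefficients`,
#'   `r_squared_test`, `pearson_r_test`, `train_fraction`, `seed`, `fit`.
#' @export
fit_protein_model <- function(table, protein, train_fraction = 0.7,
                              seed = 1L) {
  stopifnot(all(c("cgi", "day", protein) %in% names(table)),
            nrow(table) >= 20)
  y <- table[[protein]]
  if (stats::var(y) == 0) stop("zero-variance protein", call. = FALSE)
  set.seed(seed)
  n <- nrow(table)
  idx <- sample.int(n, size = floor(train_fraction * n))
  train <- table[idx, ]
  test <- table[-idx, ]
  fml <- stats::as.formula(paste0("`", protein, "` ~ cgi + day"))
  fit <- stats::lm(fml, data = train)
  pred <- stats::predict(fit, newdata = test)
  resid <- test[[protein]] - pred
  ss_res <- sum(resid^2)
  ss_tot <- sum((test[[protein]] - mean(test[[protein]]))^2)
  r2 <- 1 - ss_res / ss_tot
  r <- stats::cor(pred, test[[protein]])
  structure(list(coefficients = stats::coef(fit), r_squared_test = r2,
                 pearson_r_test = r, train_fraction = train_fraction,
                 seed = seed, n_train = nrow(train), n_test = nrow(test),
                 fit = fit),
            class = "protein_regression")
}

#' Hierarchical clustering of day-10 colonies
#'
#' Highly correlated features (pairwise |Pearson r| above the threshold) are
#' reduced by keeping the first column of each correlated pair in
#' deterministic column order; remaining features are z-scored and clustered
#' with Ward linkage on Euclidean distances; the tree is cut at `k`.
#'
#' @param table day-10 colony feature table.
#' @param k number of clusters.
#' @param features candidate feature columns.
#' @param cor_threshold correlation-filter threshold.
#' @return list: `labels` (integer per row), `dropped_features`,
#'   `kept_features`, `hclust` (the tree).
#' @export
hierarchical_cluster_day10 <- function(table, k = 3L,
                                       features = feature_columns(table),
                                       cor_threshold = 0.9) {
  if (k > nrow(table)) stop("k exceeds the number of rows", call. = FALSE)
  X <- as.matrix(table[, features, drop = FALSE])
  keep <- rep(TRUE, ncol(X))
  if (ncol(X) > 1) {
    cm <- abs(stats::cor(X))
    for (j in 2:ncol(X)) {
      if (any(cm[j, seq_len(j - 1)][keep[seq_len(j - 1)]] > cor_threshold))
        keep[j] <- FALSE
    }
  }
  Xk <- scale(X[, keep, drop = FALSE])
  hc <- stats::hclust(stats::dist(Xk), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  list(labels = labels, dropped_features = features[!keep],
       kept_features = features[keep], hclust = hc)
}
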