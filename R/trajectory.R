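#' @title Diffusion-map pseudotime and branch detection
#' @description Spectral embedding of colony morphology: features are
#'   z-scored, reduced to the first 10 principal components (each scaled to
#'   unit variance), and a Gaussian kernel of width 0.8 on Euclidean
#'   distances is density-normalized (alpha = 1) and eigendecomposed.
#'   Pseudotime is the diffusion distance from a root colony, normalized to
#'   [0, 1]; branches are detected by k-means in diffusion space and named
#'   by composition (day-0 fraction) and colony size. Held-out colonies are
#'   projected by Nystrom extension.
#' @name trajectory_inference
NULL

# morphology feature set shared by CGI and the diffusion map
.MORPHOLOGY_FEATURES <- c("volume", "surface_area", "sphericity",
                          "moment1", "moment2", "moment3", "moment4",
                          "moment5", "feret", "min_feret", "major_radius",
                          "elongation", "flatness", "dist_mean", "dist_min",
                          "dist_max", "dist_sd", "projected_area",
                          "circularity", "aspect_ratio")

#' Morphology feature columns present in a table
#' @param table a colony feature table.
#' @return character vector of column names.
#' @export
morphology_features <- function(table)
  intersect(.MORPHOLOGY_FEATURES, names(table))

# deterministic eigenvector sign: largest-|value| entry made positive
fix_sign <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s == 0) s <- 1
  v * s
}

#' Build a diffusion map of colony morphology
#'
#' @param table colony feature table.
#' @param features feature columns (default: the morphology set).
#' @param n_pc number of principal components (default 10).
#' @param kernel_sigma Gaussian kernel width on the unit-variance PC
#'   coordinates (default 0.8; `"auto"` uses the median pairwise distance).
#' @param n_components number of nontrivial diffusion components kept.
#' @param row_ids identifiers of the fitted rows (default `colony_id`
#'   column or row numbers).
#' @return object of class `diffusion_embedding`: eigenvalues (descending,
#'   nontrivial), `psi` (diffusion eigenvectors), `coords`
#'   (eigenvalue-scaled coordinates), and everything needed for Nystrom
#'   projection of new rows.
#' @export
build_diffusion_map <- function(table, features = morphology_features(table),
                                n_pc = 10L, kernel_sigma = 0.8,
                                n_components = 10L, row_ids = NULL) {
  stopifnot(nrow(table) >= 20)
  if (is.null(row_ids))
    row_ids <- if ("colony_id" %in% names(table)) table$colony_id
               else as.character(seq_len(nrow(table)))
  X <- as.matrix(table[, features, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  pca <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pca$rotation))
  # PCs keep their natural variance ordering (rescaling them would inflate
  # pure-noise components to unit scale and drown the manifold structure)
  Y <- pca$x[, seq_len(n_pc), drop = FALSE]
  pc_scl <- rep(1, n_pc)
  if (anyDuplicated(Y)) warning("duplicate rows in kernel space")
  D2 <- as.matrix(stats::dist(Y))^2
  if (identical(kernel_sigma, "auto"))
    kernel_sigma <- stats::median(sqrt(D2[upper.tri(D2)]))
  K <- exp(-D2 / (2 * kernel_sigma^2))
  # density normalization (alpha = 1), then the symmetric normalized operator
  q <- rowSums(K)
  K1 <- K / outer(q, q)
  dgr <- rowSums(K1)
  A <- K1 / outer(sqrt(dgr), sqrt(dgr))
  eg <- eigen(A, symmetric = TRUE)
  lam <- eg$values
  V <- eg$vectors
  # right eigenvectors of the Markov operator; trivial component dropped
  psi <- V / sqrt(dgr)
  m <- min(n_components, ncol(psi) - 1L)
  keep <- 2:(m + 1L)
  psi_k <- apply(psi[, keep, drop = FALSE], 2, fix_sign)
  lam_k <- lam[keep]
  coords <- sweep(psi_k, 2, lam_k, `*`)
  structure(list(features = features, center = ctr, scale = scl,
                 pca_loadings = pca$rotation[, seq_len(n_pc), drop = FALSE],
                 pc_scale = pc_scl, kernel_sigma = kernel_sigma,
                 eigenvalues = lam_k, psi = psi_k, coords = coords,
                 ref_pc = Y, ref_q = q, ref_degree = dgr,
                 reference_rows = row_ids, lambda0 = lam[1]),
            class = "diffusion_embedding")
}

#' Diffusion pseudotime from a root colony
#'
#' Pseudotime is the diffusion distance from the root, computed in the
#' diffusion eigenbasis with components weighted by `lambda / (1 - lambda)`,
#' then min-max normalized to [0, 1]. The root is either a reference row id
#' or `"auto"`: the colony nearest the day-0 centroid in diffusion
#' coordinates.
#'
#' @param embedding a `diffusion_embedding`.
#' @param root row id or `"auto"`.
#' @param days per-row day labels (required for `"auto"`).
#' @return list of class `pseudotime_result`: `pseudotime` (in [0, 1]),
#'   `root_id`, `root_index`, `range` (raw distance range, reused when
#'   projecting new colonies).
#' @export
compute_pseudotime <- function(embedding, root = "auto", days = NULL) {
  lam <- embedding$eigenvalues
  if (any(lam >= 1))
    stop("numerical degeneracy: nontrivial eigenvalue >= 1", call. = FALSE)
  W <- sweep(embedding$psi, 2, lam / (1 - lam), `*`)
  if (identical(root, "auto")) {
    if (is.null(days)) stop("root = 'auto' needs day labels", call. = FALSE)
    d0 <- days == min(days)
    ctr <- colMeans(embedding$coords[d0, , drop = FALSE])
    root_index <- which.min(colSums((t(embedding$coords) - ctr)^2))
  } else {
    root_index <- match(root, embedding$reference_rows)
    if (is.na(root_index)) stop("root not among reference rows", call. = FALSE)
  }
  dd <- sqrt(colSums((t(W) - W[root_index, ])^2))
  rng <- range(dd)
  pt <- (dd - rng[1]) / diff(rng)
  structure(list(pseudotime = pt, root_id =
                   embedding$reference_rows[root_index],
                 root_index = root_index, range = rng),
            class = "pseudotime_result")
}

#' Detect trajectory branches by clustering diffusion components
#'
#' k-means (50 restarts, fixed seed) on the first `n_components` nontrivial
#' diffusion components. With k = 3 and metadata available, clusters are
#' named deterministically: the cluster with the highest day-0 fraction
#' (ties: the larger cluster) is pre-decision; of the remaining two, the one
#' with larger mean colony volume is success (large spherical colonies), the
#' other transient (small spherical colonies).
#'
#' @param embedding a `diffusion_embedding`.
#' @param metadata data.frame aligned with the fitted rows, with `day` and
#'   `volume` columns (used for naming).
#' @param k number of branches.
#' @param n_components diffusion components used for clustering.
#' @param seed k-means seed.
#' @return list of class `branch_result`: `branch` (character per row),
#'   `centroids` (k x components, named rows when k = 3), `named`.
#' @export
detect_branches <- function(embedding, metadata = NULL, k = 3L,
                            n_components = 3L, seed = 1L) {
  stopifnot(k >= 2)
  m <- min(n_components, ncol(embedding$coords))
  X <- embedding$coords[, seq_len(m), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 50L, iter.max = 100L)
  cl <- km$cluster
  named <- FALSE
  if (k == 3 && !is.null(metadata) &&
      all(c("day", "volume") %in% names(metadata))) {
    day0 <- metadata$day == min(metadata$day)
    frac0 <- vapply(1:3, function(g) mean(day0[cl == g]), numeric(1))
    size <- tabulate(cl, 3)
    pre <- order(-frac0, -size)[1]
    rest <- setdiff(1:3, pre)
    vols <- vapply(rest, function(g) mean(metadata$volume[cl == g]),
                   numeric(1))
    succ <- rest[which.max(vols)]
    trans <- setdiff(rest, succ)
    name_map <- character(3)
    name_map[pre] <- "pre_decision"
    name_map[succ] <- "success"
    name_map[trans] <- "transient"
    branch <- name_map[cl]
    centroids <- km$centers
    rownames(centroids) <- name_map
    named <- TRUE
  } else {
    branch <- paste0("cluster_", cl)
    centroids <- km$centers
    rownames(centroids) <- paste0("cluster_", seq_len(k))
  }
  structure(list(branch = branch, centroids = centroids, named = named,
                 n_components = m, cluster = cl),
            class = "branch_result")
}

#' Branch composition per group
#'
#' @param labels branch labels per colony.
#' @param metadata data.frame with the grouping column.
#' @param group_by grouping column name (e.g. `"day"` or `"treatment"`).
#' @return data.frame: one row per group, one fraction column per branch;
#'   fractions sum to 1 per group. Empty groups are omitted with a warning.
#' @export
branch_fractions <- function(labels, metadata, group_by = "day") {
  stopifnot(length(labels) == nrow(metadata),
            group_by %in% names(metadata))
  g <- metadata[[group_by]]
  groups <- sort(unique(g))
  branches <- sort(unique(labels))
  out <- lapply(groups, function(gr) {
    sel <- g == gr
    if (!any(sel)) {
      warning("empty group omitted: ", gr)
      return(NULL)
    }
    fr <- vapply(branches, function(b) mean(labels[sel] == b), numeric(1))
    df <- data.frame(group = gr)
    for (b in branches) df[[b]] <- fr[[b]]
    df
  })
  res <- do.call(rbind, out)
  names(res)[1] <- group_by
  res
}

#' Project held-out colonies into a fitted diffusion map
#'
#' Nystrom extension: the kernel between new and reference rows is
#' normalized exactly as during fitting and back-projected through the
#' eigenvectors, so re-projecting a reference row reproduces its fitted
#' coordinates. Branch labels come from the nearest named branch centroid;
#' pseudotime uses the fitted root and scaling and is clipped to [0, 1]
#' (with a flag when clipping occurred).
#'
#' @param embedding a `diffusion_embedding`.
#' @param new_table feature table sharing the fitted feature schema.
#' @param branch_fit optional `branch_result` for branch assignment.
#' @param pseudotime_fit optional `pseudotime_result` for pseudotime.
#' @return list: `coords`, `branch` (or NULL), `pseudotime` (or NULL),
#'   `clipped` (logical per row).
#' @export
project_new_colonies <- function(embedding, new_table, branch_fit = NULL,
                                 pseudotime_fit = NULL) {
  missing_cols <- setdiff(embedding$features, names(new_table))
  if (length(missing_cols) > 0)
    stop("schema mismatch; missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- as.matrix(new_table[, embedding$features, drop = FALSE])
  Z <- scale(X, center = embedding$center, scale = embedding$scale)
  Y <- (Z %*% embedding$pca_loadings)
  Y <- sweep(Y, 2, embedding$pc_scale, `/`)
  # kernel vs reference rows, same alpha = 1 normalization
  D2 <- outer(rowSums(Y^2), rowSums(embedding$ref_pc^2), `+`) -
    2 * Y %*% t(embedding$ref_pc)
  D2[D2 < 0] <- 0
  K <- exp(-D2 / (2 * embedding$kernel_sigma^2))
  qn <- rowSums(K)
  K1 <- K / outer(qn, embedding$ref_q)
  dn <- rowSums(K1)
  P <- K1 / dn
  psi_new <- (P %*% embedding$psi) %*%
    diag(1 / embedding$eigenvalues, length(embedding$eigenvalues))
  coords <- sweep(psi_new, 2, embedding$eigenvalues, `*`)
  branch <- NULL
  if (!is.null(branch_fit)) {
    m <- branch_fit$n_components
    cen <- branch_fit$centroids
    dmat <- outer(rowSums(coords[, seq_len(m), drop = FALSE]^2),
                  rowSums(cen^2), `+`) -
      2 * coords[, seq_len(m), drop = FALSE] %*% t(cen)
    branch <- rownames(cen)[apply(dmat, 1, which.min)]
  }
  pt <- NULL
  clipped <- rep(FALSE, nrow(coords))
  if (!is.null(pseudotime_fit)) {
    lam <- embedding$eigenvalues
    W_new <- sweep(psi_new, 2, lam / (1 - lam), `*`)
    W_ref <- sweep(embedding$psi, 2, lam / (1 - lam), `*`)
    dd <- sqrt(colSums((t(W_new) - W_ref[pseudotime_fit$root_index, ])^2))
    rng <- pseudotime_fit$range
    pt <- (dd - rng[1]) / diff(rng)
    clipped <- pt < 0 | pt > 1
    pt <- clamp(pt, 0, 1)
  }
  list(coords = coords, branch = branch, pseudotime = pt, clipped = clipped)
}
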