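#' @title Colony- and nucleus-level morphometry
#' @description Shape descriptors (volume, surface area, sphericity,
#'   bounding-ellipsoid elongation/flatness, Feret diameters, projected-image
#'   features), chromatin descriptors (heterochromatin volume above the
#'   mean + 1.5 SD threshold, Haralick co-occurrence textures) and
#'   per-channel protein summaries, all in physical units.
#' @name morphometry
NULL

#' Sphericity from volume and surface area
#'
#' `(36 * pi * V^2)^(1/3) / SA`: equals exactly 1 for an ideal sphere and is
#' below 1 for any other shape.
#'
#' @param volume object volume (um^3).
#' @param surface_area object surface area (um^2).
#' @param printed_formula if TRUE, evaluate the alternative
#'   `((4*pi*V^2)/(9*SA^3))^(1/3)` variant (which is not 1 for a sphere);
#'   kept for comparability, off by default.
#' @return dimensionless sphericity.
#' @export
sphericity <- function(volume, surface_area, printed_formula = FALSE) {
  if (printed_formula)
    return(((4 * pi * volume^2) / (9 * surface_area^3))^(1 / 3))
  (36 * pi * volume^2)^(1 / 3) / surface_area
}

# voxel-center physical coordinates of TRUE voxels
mask_coords <- function(mask, spacing) {
  ind <- which(mask, arr.ind = TRUE)
  sweep(ind - 0.5, 2, spacing, `*`)
}

# Surface area by the coarea formula: integral of |grad| of the Gaussian-
# smoothed indicator. Exactly scale-equivariant and accurate to ~2% on
# digital balls.
surface_area_mask <- function(mask, spacing, sigma_vox = 1.5) {
  d <- dim(mask)
  sm <- array(.blur3d(as.numeric(mask), as.integer(d),
                      rep(sigma_vox, 3)), d)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (sm[3:d[1], , ] - sm[1:(d[1] - 2), , ]) /
    (2 * spacing[1])
  gy[, 2:(d[2] - 1), ] <- (sm[, 3:d[2], ] - sm[, 1:(d[2] - 2), ]) /
    (2 * spacing[2])
  if (d[3] > 2)
    gz[, , 2:(d[3] - 1)] <- (sm[, , 3:d[3]] - sm[, , 1:(d[3] - 2)]) /
      (2 * spacing[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(spacing)
}

# Quasi-uniform directions on the half sphere (Fibonacci lattice).
fib_directions <- function(k = 600L) {
  i <- seq_len(k) - 0.5
  phi <- acos(1 - i / k)           # polar angle on the upper half sphere
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Feret (maximum caliper) and minimum Feret diameters
#'
#' Directional widths of the foreground voxel corners (support-function
#' evaluation over a dense direction lattice): the Feret diameter is the
#' maximum width, the minimum Feret the smallest. For a rectangle the Feret
#' diameter is the length of the diagonal.
#'
#' @param mask a `colony_mask` or logical 3D array.
#' @param spacing voxel spacing (taken from the mask object if present).
#' @param n_directions number of probe directions.
#' @return named numeric: `feret`, `min_feret` (um).
#' @export
feret_diameters <- function(mask, spacing = NULL, n_directions = 600L) {
  if (inherits(mask, "colony_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  stopifnot(any(mask), !is.null(spacing))
  d <- dim(mask)
  bd <- array(.boundary6(as.integer(mask), as.integer(d)), d) > 0
  pts <- mask_coords(bd, spacing)
  U <- fib_directions(n_directions)
  proj <- pts %*% t(U)
  # corner correction: voxels extend +-spacing/2 along each axis
  halfw <- abs(U) %*% (spacing / 2)
  widths <- apply(proj, 2, max) - apply(proj, 2, min) + 2 * c(halfw)
  c(feret = max(widths), min_feret = min(widths))
}

#' Bounding-ellipsoid axes, elongation and flatness
#'
#' Semi-axes from the eigenvalues of the voxel-coordinate covariance tensor,
#' scaled so a uniform solid ellipsoid recovers its true semi-axes
#' (`a = sqrt(5 * lambda)`). Elongation is the ratio of the semimajor to the
#' major axis (b/a), flatness the ratio of the minor to the major axis
#' (c/a); both equal 1 for a sphere.
#'
#' @param mask a `colony_mask` or logical 3D array.
#' @param spacing voxel spacing if a bare array is given.
#' @return named numeric: `a`, `b`, `c`, `elongation`, `flatness`,
#'   `major_radius` (um).
#' @export
bounding_ellipsoid_axes <- function(mask, spacing = NULL) {
  if (inherits(mask, "colony_mask")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  pts <- mask_coords(mask, spacing)
  if (nrow(pts) < 4) stop("mask has fewer than 4 voxels", call. = FALSE)
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  ev <- sort(eigen(cv, symmetric = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  ax <- sqrt(5 * ev)
  if (ax[3] <= .Machine$double.eps * ax[1]) {
    warning("mask is coplanar; flatness reported as 0")
    flat <- 0
  } else {
    flat <- ax[3] / ax[1]
  }
  c(a = ax[1], b = ax[2], c = ax[3],
    elongation = ax[2] / ax[1], flatness = flat, major_radius = ax[1])
}

#' Colony-level shape features
#'
#' Volume, surface area and sphericity; the first five moments of the
#' distance-from-centroid distribution (mean, SD, and standardized moments
#' 3-5); Feret diameters; bounding-ellipsoid elongation/flatness/major
#' radius; distance-to-surface statistics over boundary voxels; and
#' projected (z-projection) area, circularity and aspect ratio.
#'
#' @param mask a `colony_mask`.
#' @param printed_sphericity forwarded to [sphericity()].
#' @return one-row data.frame of features (units: um, um^2, um^3 or
#'   dimensionless).
#' @export
colony_shape_features <- function(mask, printed_sphericity = FALSE) {
  stopifnot(inherits(mask, "colony_mask"))
  m <- mask$mask
  sp <- mask$spacing
  n_vox <- sum(m)
  if (n_vox < 2) stop("degenerate shape: mask has fewer than 2 voxels",
                      call. = FALSE)
  vox_vol <- prod(sp)
  volume <- n_vox * vox_vol
  sa <- surface_area_mask(m, sp)
  sph <- sphericity(volume, sa, printed_sphericity)

  pts <- mask_coords(m, sp)
  ctr <- colMeans(pts)
  dall <- sqrt(colSums((t(pts) - ctr)^2))
  m1 <- mean(dall)
  m2 <- pop_sd(dall)
  std <- if (m2 > 0) (dall - m1) / m2 else dall * 0
  moments <- c(m1, m2, mean(std^3), mean(std^4), mean(std^5))

  d <- dim(m)
  bd <- array(.boundary6(as.integer(m), as.integer(d)), d) > 0
  bpts <- mask_coords(bd, sp)
  dsurf <- sqrt(colSums((t(bpts) - ctr)^2))

  fer <- feret_diameters(m, sp)
  ell <- bounding_ellipsoid_axes(m, sp)

  # projected (z) features
  proj <- apply(m, c(1, 2), any)
  parea <- sum(proj) * sp[1] * sp[2]
  pd <- dim(proj)
  smp <- array(.blur3d(as.numeric(proj), as.integer(c(pd, 1L)),
                       c(1.5, 1.5, 0)), c(pd, 1))[, , 1]
  gx <- matrix(0, pd[1], pd[2]); gy <- gx
  gx[2:(pd[1] - 1), ] <- (smp[3:pd[1], ] - smp[1:(pd[1] - 2), ]) /
    (2 * sp[1])
  gy[, 2:(pd[2] - 1)] <- (smp[, 3:pd[2]] - smp[, 1:(pd[2] - 2)]) /
    (2 * sp[2])
  perim <- sum(sqrt(gx^2 + gy^2)) * sp[1] * sp[2]
  circ <- if (perim > 0) 4 * pi * parea / perim^2 else NA_real_
  pind <- which(proj, arr.ind = TRUE)
  ppts <- sweep(pind - 0.5, 2, sp[1:2], `*`)
  pcv <- stats::cov(ppts) * (nrow(ppts) - 1) / nrow(ppts)
  pev <- sort(eigen(pcv, symmetric = TRUE)$values, decreasing = TRUE)
  aspect <- if (pev[2] > 0) sqrt(pev[1] / pev[2]) else Inf

  data.frame(volume = volume, surface_area = sa, sphericity = sph,
             moment1 = moments[1], moment2 = moments[2],
             moment3 = moments[3], moment4 = moments[4],
             moment5 = moments[5],
             feret = fer[["feret"]], min_feret = fer[["min_feret"]],
             major_radius = ell[["major_radius"]],
             elongation = ell[["elongation"]], flatness = ell[["flatness"]],
             dist_mean = mean(dsurf), dist_min = min(dsurf),
             dist_max = max(dsurf), dist_sd = pop_sd(dsurf),
             projected_area = parea, circularity = circ,
             aspect_ratio = aspect)
}

#' Heterochromatin volume per nucleus
#'
#' Heterochromatin is the set of nuclear voxels whose DNA-stain intensity is
#' strictly above `mean + k * SD` of that nucleus (k = 1.5 by default). A
#' constant-intensity nucleus therefore has zero heterochromatin.
#'
#' @param image a `colony_image`.
#' @param labels a `nuclei_labels`.
#' @param dna_channel DNA channel name.
#' @param k threshold offset in SD units.
#' @return data.frame: `nucleus_id`, `hc_volume` (um^3), `hc_fraction`,
#'   `nucleus_volume` (um^3), `threshold`.
#' @export
heterochromatin_volume <- function(image, labels, dna_channel = "dna",
                                   k = 1.5) {
  v <- get_channel(image, dna_channel)
  vox_vol <- prod(labels$spacing)
  ids <- seq_len(labels$n)
  out <- lapply(ids, function(i) {
    vals <- v[labels$labels == i]
    thr <- mean(vals) + k * stats::sd(vals)
    if (is.na(thr)) thr <- mean(vals)
    hc <- sum(vals > thr) * vox_vol
    nv <- length(vals) * vox_vol
    data.frame(nucleus_id = i, hc_volume = hc, hc_fraction = hc / nv,
               nucleus_volume = nv, threshold = thr)
  })
  do.call(rbind, out)
}

#' Haralick co-occurrence texture features per nucleus
#'
#' Intensities are min-max binned to `n_levels` grey levels within each
#' nucleus; a symmetric, normalized co-occurrence matrix is accumulated over
#' the four in-plane unit offsets with both pair ends inside the nucleus.
#' Reported: inverse difference moment (IDM, local homogeneity), entropy
#' (bits), correlation and contrast. A constant nucleus takes the degenerate
#' values IDM = 1, entropy = 0, contrast = 0, correlation = 0.
#'
#' @param image a `colony_image`.
#' @param labels a `nuclei_labels`.
#' @param dna_channel channel to compute texture on.
#' @param n_levels number of grey levels.
#' @return data.frame: `nucleus_id`, `texture_idm`, `texture_entropy`,
#'   `texture_correlation`, `texture_contrast`.
#' @export
glcm_texture <- function(image, labels, dna_channel = "dna",
                         n_levels = 64L) {
  v <- get_channel(image, dna_channel)
  d <- dim(v)
  offsets <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(1L, 1L, 0L),
                   c(1L, -1L, 0L))
  out <- lapply(seq_len(labels$n), function(i) {
    sel <- labels$labels == i
    vals <- v[sel]
    rng <- range(vals)
    if (diff(rng) <= 0) {
      return(data.frame(nucleus_id = i, texture_idm = 1, texture_entropy = 0,
                        texture_correlation = 0, texture_contrast = 0))
    }
    lev <- array(0L, d)
    lev[sel] <- pmin(n_levels,
                     1L + as.integer(floor((vals - rng[1]) / diff(rng) *
                                             n_levels)))
    M <- .glcm_accum(as.integer(lev), as.integer(d), as.integer(n_levels),
                     offsets)
    feats <- glcm_features(M / sum(M))
    data.frame(nucleus_id = i, texture_idm = feats[["idm"]],
               texture_entropy = feats[["entropy"]],
               texture_correlation = feats[["correlation"]],
               texture_contrast = feats[["contrast"]])
  })
  do.call(rbind, out)
}

#' Scalar texture features of a normalized co-occurrence matrix
#'
#' @param P square co-occurrence probability matrix (sums to 1).
#' @return named numeric: `idm`, `entropy` (bits), `correlation`,
#'   `contrast`.
#' @export
glcm_features <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  idm <- sum(P / (1 + (i - j)^2))
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  contrast <- sum((i - j)^2 * P)
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sig2 <- sum((seq_len(G) - mu)^2 * px)
  correlation <- if (sig2 > 0) sum((i - mu) * (j - mu) * P) / sig2 else 0
  c(idm = idm, entropy = entropy, correlation = correlation,
    contrast = contrast)
}

#' Per-colony and per-nucleus protein summaries
#'
#' Colony mean per channel (over labeled nuclear voxels for nuclear
#' channels, over the colony mask otherwise) and, for nuclear channels, the
#' coefficient of variation of per-nucleus means (population SD / mean;
#' reported as NA for fewer than 2 nuclei).
#'
#' @param image a `colony_image`.
#' @param mask a `colony_mask`.
#' @param labels a `nuclei_labels`.
#' @param channels channels to summarize (default all protein channels).
#' @param nuclear_channels channels whose colony mean is computed over
#'   nuclei rather than the whole mask.
#' @return list: `colony_means` (named), `cv` (named), `nucleus_means`
#'   (matrix nuclei x channels).
#' @export
protein_summaries <- function(image, mask, labels,
                              channels = setdiff(image$channel_names,
                                                 c("dna", "edu")),
                              nuclear_channels = c("oct4", "lamin",
                                                   "h3k9ac")) {
  stopifnot(any(mask$mask))
  nuc_any <- labels$n > 0
  nm <- if (nuc_any)
    sapply(channels, function(ch) nucleus_means(image, labels, ch))
  else NULL
  if (nuc_any && labels$n == 1) nm <- matrix(nm, nrow = 1,
                                             dimnames = list(NULL, channels))
  cmeans <- vapply(channels, function(ch) {
    v <- get_channel(image, ch)
    if (ch %in% nuclear_channels && nuc_any) mean(v[labels$labels > 0])
    else mean(v[mask$mask])
  }, numeric(1))
  cv <- vapply(channels, function(ch) {
    if (!nuc_any || labels$n < 2) return(NA_real_)
    mu <- mean(nm[, ch])
    if (mu == 0) return(NA_real_)
    pop_sd(nm[, ch]) / mu
  }, numeric(1))
  list(colony_means = cmeans, cv = cv, nucleus_means = nm)
}

#' Voronoi proxy-cell volumes
#'
#' Partitions the colony mask by the nearest-nucleus-centroid rule (physical
#' distance; ties to the lowest nucleus id) as a proxy for unsegmentable
#' cell bodies. Proxy volumes sum exactly to the colony volume.
#'
#' @param labels a `nuclei_labels` with at least one nucleus.
#' @param mask a `colony_mask`.
#' @return numeric vector of proxy volumes (um^3), one per nucleus.
#' @export
voronoi_cell_proxies <- function(labels, mask) {
  stopifnot(labels$n >= 1)
  sp <- labels$spacing
  pts <- mask_coords(mask$mask, sp)
  cents <- t(vapply(seq_len(labels$n), function(i)
    colMeans(mask_coords(labels$labels == i, sp)), numeric(3)))
  best <- rep(1L, nrow(pts))
  bestd <- colSums((t(pts) - cents[1, ])^2)
  if (labels$n > 1) {
    for (i in 2:labels$n) {
      di <- colSums((t(pts) - cents[i, ])^2)
      upd <- di < bestd
      best[upd] <- i
      bestd[upd] <- di[upd]
    }
  }
  as.numeric(tabulate(best, nbins = labels$n)) * prod(sp)
}
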