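#' @title Brightfield alkaline-phosphatase quantification
#' @description Spheroids are segmented from brightfield RGB images by local
#'   contrast enhancement, variance and Gaussian filtering and Otsu
#'   thresholding; the chromogen signal is unmixed by colour deconvolution
#'   against the stain vector (r, g, b) = (0.65, 0.40, 0.64); a spheroid
#'   with mean activity strictly above 0.5 is called AP-positive.
#' @name phenotype_assays
NULL

#' Stain model for colour deconvolution
#'
#' The single chromogen vector is unit-normalized and completed to an
#' invertible 3x3 optical-density basis with its orthonormal complement
#' (Ruifrok-Johansson convention).
#'
#' @param stain_vector RGB optical-density vector of the chromogen.
#' @return object of class `stain_model`: `stain_vector` (unit norm),
#'   `basis` (3x3, rows = stain then complement), `basis_inv`.
#' @export
stain_model <- function(stain_vector = c(0.65, 0.40, 0.64)) {
  s <- stain_vector / sqrt(sum(stain_vector^2))
  # Gram-Schmidt complement from fixed helper axes
  cand <- diag(3)
  h1 <- cand[, which.min(abs(s))]
  u <- h1 - sum(h1 * s) * s
  u <- u / sqrt(sum(u^2))
  v <- c(s[2] * u[3] - s[3] * u[2],
         s[3] * u[1] - s[1] * u[3],
         s[1] * u[2] - s[2] * u[1])
  basis <- rbind(stain = s, comp1 = u, comp2 = v)
  structure(list(stain_vector = s, basis = basis,
                 basis_inv = solve(basis)),
            class = "stain_model")
}

# Optical density of intensities in [0, 1] against a reference white,
# with a 1/255 offset guarding saturated zeros (8-bit convention).
rgb_to_od <- function(px, background) {
  off <- 1 / 255
  od <- matrix(0, nrow(px), 3)
  for (ch in 1:3) od[, ch] <- -log10((px[, ch] + off) / (background[ch] + off))
  od
}

#' Forward synthesis of RGB pixels from stain optical density
#'
#' Exact inverse of the optical-density computation in [ap_activity()]:
#' useful for round-trip validation of the deconvolution.
#'
#' @param od_stain stain-channel optical density per pixel.
#' @param stain a `stain_model`.
#' @param background per-channel reference white in [0, 1].
#' @return n x 3 matrix of RGB intensities.
#' @export
ap_forward_od <- function(od_stain, stain = stain_model(),
                          background = c(1, 1, 1)) {
  off <- 1 / 255
  od <- outer(od_stain, stain$stain_vector)
  px <- matrix(0, length(od_stain), 3)
  for (ch in 1:3)
    px[, ch] <- (background[ch] + off) * 10^(-od[, ch]) - off
  px
}

#' Segment spheroids in a brightfield image
#'
#' Grayscale conversion, tile-based adaptive contrast enhancement (CLAHE),
#' a local variance filter, Gaussian smoothing, Otsu thresholding, hole
#' filling and small-object removal.
#'
#' @param rgb_image H x W x 3 array in [0, 1].
#' @param variance_window variance-filter window (pixels, odd).
#' @param gaussian_sigma smoothing sigma (pixels).
#' @param min_area_px minimum object area kept.
#' @param use_clahe enable the contrast-enhancement step.
#' @return list: `label` (integer matrix, 0 = background), `masks` (list of
#'   logical matrices, one per spheroid), `n`.
#' @export
segment_brightfield_spheroids <- function(rgb_image, variance_window = 7L,
                                          gaussian_sigma = 2,
                                          min_area_px = 200L,
                                          use_clahe = TRUE) {
  stopifnot(length(dim(rgb_image)) == 3, dim(rgb_image)[3] == 3)
  grey <- (rgb_image[, , 1] + rgb_image[, , 2] + rgb_image[, , 3]) / 3
  img <- EBImage::Image(grey)
  if (use_clahe && diff(range(grey)) > 0)
    img <- EBImage::clahe(img, nx = 8, ny = 8)
  w <- variance_window
  box <- matrix(1 / (w * w), w, w)
  m1 <- EBImage::filter2(img, box)
  m2 <- EBImage::filter2(img^2, box)
  v <- m2 - m1^2
  v[v < 0] <- 0
  empty <- list(label = matrix(0L, nrow(grey), ncol(grey)),
                masks = list(), n = 0L)
  if (max(v) <= 1e-10) return(empty)   # featureless image
  # local SD scale: edge strength linear in contrast, so faintly stained
  # spheroids survive the global Otsu cut alongside dark ones
  v <- sqrt(v)
  v <- EBImage::gblur(v, sigma = gaussian_sigma)
  vmax <- max(v)
  vn <- v / vmax
  thr <- EBImage::otsu(EBImage::Image(vn))
  bin <- vn > thr
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  if (length(keep) == 0) return(empty)
  out_lab <- matrix(0L, nrow(grey), ncol(grey))
  masks <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    mk <- lab == keep[i]
    mk <- as.matrix(EBImage::fillHull(mk))
    out_lab[mk] <- i
    masks[[i]] <- mk
  }
  list(label = out_lab, masks = masks, n = length(keep))
}

#' Alkaline-phosphatase activity of a spheroid
#'
#' Per-pixel optical density against the reference white is unmixed through
#' the inverse stain basis; the stain-channel concentration is divided by
#' the saturation optical density and clipped to [0, 1]; the mean over the
#' mask is returned. Negative projections (colors opposing the stain) clip
#' to 0.
#'
#' @param rgb_image H x W x 3 array in [0, 1].
#' @param mask logical matrix selecting the spheroid pixels.
#' @param stain a `stain_model`.
#' @param background per-channel reference white; `NULL` estimates it as
#'   the per-channel 99th percentile of the image.
#' @param od_sat saturation optical density mapping activity to 1.
#' @return mean activity, dimensionless in [0, 1].
#' @export
ap_activity <- function(rgb_image, mask, stain = stain_model(),
                        background = NULL, od_sat = 1.0) {
  stopifnot(any(mask))
  if (is.null(background))
    background <- apply(rgb_image, 3, stats::quantile, probs = 0.99)
  px <- cbind(rgb_image[, , 1][mask], rgb_image[, , 2][mask],
              rgb_image[, , 3][mask])
  od <- rgb_to_od(px, background)
  conc <- od %*% stain$basis_inv
  act <- clamp(conc[, 1] / od_sat, 0, 1)
  mean(act)
}

#' Classify spheroids as AP-positive
#'
#' Strict comparison of mean activity against the threshold (default 0.5),
#' plus the dataset-level positive fraction.
#'
#' @param mean_activity numeric vector of per-spheroid mean activities.
#' @param threshold positivity threshold.
#' @return list: `positive` (logical), `fraction`.
#' @export
classify_ap_positive <- function(mean_activity, threshold = 0.5) {
  stopifnot(all(mean_activity >= 0), all(mean_activity <= 1))
  pos <- mean_activity > threshold
  list(positive = pos, fraction = mean(pos))
}

#' Quantify all spheroids in a brightfield image
#'
#' Convenience wrapper: segmentation, per-spheroid activity and positivity.
#'
#' @param rgb_image H x W x 3 array in [0, 1].
#' @param stain a `stain_model`.
#' @param threshold positivity threshold.
#' @param ... forwarded to [segment_brightfield_spheroids()].
#' @return data.frame: `spheroid_id`, `area_px`, `mean_activity`,
#'   `positive`.
#' @export
ap_assay_image <- function(rgb_image, stain = stain_model(),
                           threshold = 0.5, ...) {
  seg <- segment_brightfield_spheroids(rgb_image, ...)
  if (seg$n == 0)
    return(data.frame(spheroid_id = integer(0), area_px = integer(0),
                      mean_activity = numeric(0), positive = logical(0)))
  act <- vapply(seg$masks, function(m) ap_activity(rgb_image, m, stain),
                numeric(1))
  cls <- classify_ap_positive(act, threshold)
  data.frame(spheroid_id = seq_len(seg$n),
             area_px = vapply(seg$masks, sum, numeric(1)),
             mean_activity = act, positive = cls$positive)
}
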