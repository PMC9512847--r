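#' @title 3D colony and nuclei segmentation
#' @description Colony envelopes are segmented from the cytoskeletal channel
#'   by 3D Gaussian smoothing and Otsu thresholding; nuclei are separated by
#'   an anisotropy-aware Euclidean distance transform and a seeded 3D
#'   watershed. All operations work in physical units (um) via the image
#'   voxel spacing.
#' @name segmentation
NULL

get_channel <- function(image, channel) {
  stopifnot(inherits(image, "colony_image"))
  if (!channel %in% image$channel_names)
    stop("channel '", channel, "' not found; available: ",
         paste(image$channel_names, collapse = ", "), call. = FALSE)
  image$voxels[, , , channel, drop = TRUE]
}

# 3D Gaussian blur with a physical sigma converted per-axis by spacing.
blur_physical <- function(arr, spacing, sigma_um) {
  if (sigma_um <= 0) return(arr)
  d <- dim(arr)
  out <- .blur3d(as.numeric(arr), as.integer(d), sigma_um / spacing)
  array(out, d)
}

# Fill 3D holes: background components not touching the image border.
fill_holes_3d <- function(fg) {
  d <- dim(fg)
  bg_lab <- array(.label3d(as.integer(!fg), as.integer(d)), d)
  border_labs <- unique(c(bg_lab[c(1, d[1]), , ], bg_lab[, c(1, d[2]), ],
                          bg_lab[, , c(1, d[3])]))
  border_labs <- border_labs[border_labs > 0]
  fg | (bg_lab > 0 & !(bg_lab %in% border_labs))
}

#' Segment the colony envelope from a 3D stack
#'
#' Gaussian blur with a physical sigma (converted per axis by the voxel
#' spacing), global Otsu threshold, 3D hole filling, and retention of the
#' largest 26-connected component.
#'
#' @param image a `colony_image`.
#' @param channel channel used for segmentation (default the F-actin
#'   cytoskeletal channel).
#' @param sigma_um Gaussian smoothing sigma in um.
#' @return a `colony_mask`: list with logical 3D `mask`, `spacing`, and the
#'   `threshold` used.
#' @export
segment_colony <- function(image, channel = "actin", sigma_um = 1.0) {
  stopifnot(sigma_um >= 0)
  v <- get_channel(image, channel)
  if (max(v) - min(v) <= 0)
    stop("segmentation failure: channel '", channel, "' is constant",
         call. = FALSE)
  sm <- blur_physical(v, image$spacing, sigma_um)
  thr <- otsu_threshold(as.numeric(sm))
  fg <- sm > thr
  if (!any(fg))
    stop("segmentation failure: no foreground above Otsu threshold",
         call. = FALSE)
  d <- dim(fg)
  lab <- array(.label3d(as.integer(fg), as.integer(d)), d)
  n_lab <- attr(.label3d(as.integer(fg), as.integer(d)), "n_labels")
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  mask <- fill_holes_3d(lab == keep)
  structure(list(mask = mask, spacing = image$spacing, threshold = thr,
                 channel = channel),
            class = "colony_mask")
}

#' Segment individual nuclei inside a colony mask
#'
#' The DNA channel is smoothed and Otsu-thresholded within the colony mask;
#' an anisotropy-aware Euclidean distance transform is computed on the
#' nuclear foreground; seeds are its h-maxima (greyscale-reconstruction
#' based, prominence `h_um`); touching nuclei are separated by a seeded 3D
#' watershed flooding the foreground in order of decreasing distance. Objects
#' below `min_volume_um3` are removed and labels relabeled 1..N.
#'
#' @param image a `colony_image`.
#' @param mask a `colony_mask` from [segment_colony()].
#' @param dna_channel DNA channel name.
#' @param sigma_um smoothing sigma (um) before thresholding.
#' @param h_um h-maxima prominence (um) for seed extraction. Flattened
#'   nuclei cap the distance transform at their half-thickness, so the
#'   saddle between laterally touching nuclei can be shallow; the default
#'   0.5 um resolves such contacts.
#' @param min_volume_um3 minimum object volume kept (um^3).
#' @param merge_seed_dist_um seed components closer than this (centroid
#'   distance) are merged into one marker, suppressing spurious splits from
#'   ragged boundaries; set below the nucleus diameter.
#' @param seed_mode `"hmaxima"` (default) or `"otsu_edt"`: seeds from the
#'   Otsu-thresholded distance transform instead.
#' @param threshold optional explicit intensity threshold (skips Otsu).
#' @return a `nuclei_labels`: integer 3D `labels` (0 background), `spacing`,
#'   `n` nuclei, `warning` flag (TRUE when no nuclear foreground was found).
#' @export
segment_nuclei <- function(image, mask, dna_channel = "dna", sigma_um = 0.3,
                           h_um = 0.5, min_volume_um3 = 50,
                           merge_seed_dist_um = 4.0,
                           seed_mode = c("hmaxima", "otsu_edt"),
                           threshold = NULL) {
  seed_mode <- match.arg(seed_mode)
  stopifnot(inherits(mask, "colony_mask"), any(mask$mask))
  v <- get_channel(image, dna_channel)
  sp <- image$spacing
  d <- dim(v)
  sm <- blur_physical(v, sp, sigma_um)
  inside <- sm[mask$mask]
  if (is.null(threshold)) {
    if (max(inside) - min(inside) <= 0) {
      threshold <- Inf
    } else {
      threshold <- otsu_threshold(as.numeric(inside))
    }
  }
  fg <- sm > threshold & mask$mask
  empty <- structure(list(labels = array(0L, d), spacing = sp, n = 0L,
                          warning = TRUE, threshold = threshold),
                     class = "nuclei_labels")
  if (!any(fg)) {
    warning("no nuclear foreground detected in colony; returning empty labels")
    return(empty)
  }
  edt <- array(.edt3d(as.integer(fg), as.integer(d), sp), d)
  if (seed_mode == "hmaxima") {
    rec <- array(.reconstruct3d(as.numeric(edt - h_um), as.numeric(edt),
                                as.integer(d)), d)
    eps <- 1e-3
    rec2 <- array(.reconstruct3d(as.numeric(rec - eps), as.numeric(rec),
                                 as.integer(d)), d)
    seed_mask <- (rec - rec2) > eps / 2 & fg
  } else {
    thr_e <- otsu_threshold(as.numeric(edt[fg]))
    seed_mask <- edt > thr_e & fg
  }
  if (!any(seed_mask)) seed_mask <- edt == max(edt) & fg
  seeds <- array(.label3d(as.integer(seed_mask), as.integer(d)), d)
  ns <- max(seeds)
  if (ns > 1 && merge_seed_dist_um > 0) {
    # single-linkage merge of seed components closer than the merge radius
    cents <- t(vapply(seq_len(ns), function(i)
      colMeans(mask_coords(seeds == i, sp)), numeric(3)))
    grp <- seq_len(ns)
    dm <- as.matrix(stats::dist(cents))
    for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
      if (dm[i, j] < merge_seed_dist_um) {
        gi <- grp[i]; gj <- grp[j]
        grp[grp == gj] <- gi
      }
    }
    grp <- as.integer(factor(grp))
    nz <- seeds > 0
    seeds[nz] <- grp[seeds[nz]]
  }
  lab <- array(.watershed3d(as.numeric(edt), as.integer(seeds),
                            as.integer(fg), as.integer(d)), d)
  # small-object removal + contiguous relabeling in scan order
  vox_vol <- prod(sp)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * vox_vol >= min_volume_um3)
  if (length(keep) == 0) {
    warning("all nuclear objects below min_volume_um3; returning empty labels")
    return(empty)
  }
  remap <- integer(max(lab))
  first_vox <- vapply(keep, function(k) which(lab == k)[1], numeric(1))
  keep <- keep[order(first_vox)]
  remap[keep] <- seq_along(keep)
  new_lab <- array(0L, d)
  nz <- lab > 0
  new_lab[nz] <- remap[lab[nz]]
  structure(list(labels = new_lab, spacing = sp, n = length(keep),
                 warning = FALSE, threshold = threshold),
            class = "nuclei_labels")
}

#' Per-nucleus mean intensity of a channel
#'
#' @param image a `colony_image`.
#' @param labels a `nuclei_labels`.
#' @param channel channel name.
#' @return numeric vector of length `labels$n`.
#' @export
nucleus_means <- function(image, labels, channel) {
  v <- get_channel(image, channel)
  if (labels$n == 0) return(numeric(0))
  as.numeric(tapply(v[labels$labels > 0], labels$labels[labels$labels > 0],
                    mean))
}

#' Classify per-nucleus EdU status and colony proliferation
#'
#' A nucleus is EdU-positive when its mean EdU intensity exceeds the
#' threshold; a colony is proliferating when at least one of its nuclei is
#' EdU-positive. When no threshold is supplied, an Otsu threshold is fitted
#' on the per-nucleus means (for a batch, pass a threshold computed across
#' all colonies); if that is undefined (single nucleus or constant means)
#' the fixed fallback threshold is used and flagged.
#'
#' @param image a `colony_image`.
#' @param labels a `nuclei_labels`.
#' @param edu_channel EdU channel name.
#' @param threshold optional intensity threshold (e.g. batch-level Otsu).
#' @param fallback_threshold absolute threshold used when Otsu is undefined.
#' @return list: `nucleus_positive` (logical per nucleus), `proliferating`
#'   (colony-level), `threshold`, `used_fallback`.
#' @export
#' Batch-level EdU positivity threshold
#'
#' Otsu threshold fitted across per-nucleus EdU means pooled over all
#' colonies of a batch; falls back to a fixed absolute threshold when the
#' pooled means cannot be split (fewer than 2 values, or constant).
#'
#' @param all_means numeric vector of per-nucleus EdU means pooled across
#'   the batch.
#' @param fallback_threshold absolute fallback.
#' @return list: `threshold`, `used_fallback`.
#' @export
edu_batch_threshold <- function(all_means, fallback_threshold = 1500) {
  if (length(all_means) >= 2 && max(all_means) - min(all_means) > 0) {
    list(threshold = otsu_threshold(all_means), used_fallback = FALSE)
  } else {
    list(threshold = fallback_threshold, used_fallback = TRUE)
  }
}

classify_edu <- function(image, labels, edu_channel = "edu", threshold = NULL,
                         fallback_threshold = 1500) {
  stopifnot(labels$n >= 1)
  means <- nucleus_means(image, labels, edu_channel)
  used_fallback <- FALSE
  if (is.null(threshold)) {
    if (length(means) >= 2 && max(means) - min(means) > 0) {
      threshold <- otsu_threshold(means, n_bins = 64L)
    } else {
      threshold <- fallback_threshold
      used_fallback <- TRUE
    }
  }
  pos <- means > threshold
  list(nucleus_positive = pos, proliferating = any(pos),
       threshold = threshold, used_fallback = used_fallback)
}
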