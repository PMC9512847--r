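#' Configuration for the synthetic colony time-course generator
#'
#' The generator emulates laterally confined fibroblast growth on rectangular
#' fibronectin micropatterns (29 um x 116 um, ~3300 um^2): a single elongated
#' cell at day 0 grows into a multicellular spheroid, with three planted
#' outcome branches (pre-decision / transient / success), monotone protein
#' trends tied to a latent progression coordinate, shrinking heterochromatin
#' blobs, and EdU labeling of proliferating colonies. Every colony carries a
#' ground-truth record so downstream segmentation, morphometry, index and
#' trajectory code can be validated against planted truth.
#'
#' @param pattern_width,pattern_length micropattern footprint in um
#'   (defaults 29 and 116).
#' @param voxel_spacing numeric length-3, voxel size in um along (x, y, z);
#'   default `c(0.3, 0.3, 1.0)` matches confocal acquisition at 0.3 um XY
#'   resolution and 1 um z-step. Coarser spacings give smaller canvases for
#'   fast simulation.
#' @param days integer vector of sampled days.
#' @param n_colonies_per_day colonies generated per day.
#' @param branch_probs named probabilities over
#'   `c("pre_decision", "transient", "success")`; must sum to 1.
#' @param doubling_time_days cell-doubling time driving colony growth
#'   (`n_nuclei = round(2^(day / doubling_time_days))` on the success branch).
#' @param protein_effect_sizes named per-channel slope of the planted colony
#'   mean versus progression (intensity units per unit progression).
#' @param protein_baselines named per-channel baseline intensity at
#'   progression 0.
#' @param branch_offsets named list (branch -> named channel offsets) of
#'   additive branch-specific shifts of the planted means.
#' @param noise_sd Gaussian read-noise SD added to every channel (intensity
#'   units); 0 gives exactly affine planted means.
#' @param geom_noise_cv lognormal coefficient of variation of the colony
#'   envelope size (biological size variability).
#' @param hc_blob_count_range integer range (lo, hi) of heterochromatin blobs
#'   per nucleus.
#' @param n_replicates number of biological replicates colonies are assigned
#'   to (round-robin).
#' @param canvas_um physical canvas (x, y, z) in um; voxelized by
#'   `voxel_spacing` (57.6 x 134.4 x 40 um = 192 x 448 x 40 voxels at the
#'   default spacing).
#' @param rng_seed root seed; per-colony streams are derived by counter-based
#'   splitting so any subset is reproducible.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(pattern_width = 29,
                             pattern_length = 116,
                             voxel_spacing = c(0.3, 0.3, 1.0),
                             days = c(0L, 2L, 4L, 6L, 8L, 10L),
                             n_colonies_per_day = 10L,
                             branch_probs = c(pre_decision = 0.10,
                                              transient = 0.22,
                                              success = 0.68),
                             doubling_time_days = 2.0,
                             protein_effect_sizes = c(oct4 = 4000,
                                                      vimentin = -3500,
                                                      ecadherin = 500,
                                                      lamin = -2500,
                                                      h3k9ac = 3000,
                                                      pmlc = -800),
                             protein_baselines = c(oct4 = 1000,
                                                   vimentin = 5000,
                                                   ecadherin = 2500,
                                                   lamin = 4000,
                                                   h3k9ac = 1500,
                                                   pmlc = 3000),
                             branch_offsets = list(
                               pre_decision = c(),
                               transient = c(oct4 = -300, ecadherin = 400,
                                             pmlc = 400),
                               success = c(oct4 = 500, vimentin = -500,
                                           ecadherin = -800, pmlc = -800)),
                             noise_sd = 120,
                             geom_noise_cv = 0.05,
                             hc_blob_count_range = c(2L, 6L),
                             n_replicates = 3L,
                             canvas_um = c(57.6, 134.4, 40),
                             rng_seed = 1L) {
  cfg <- list(pattern_width = pattern_width, pattern_length = pattern_length,
              voxel_spacing = voxel_spacing, days = as.integer(days),
              n_colonies_per_day = as.integer(n_colonies_per_day),
              branch_probs = branch_probs,
              doubling_time_days = doubling_time_days,
              protein_effect_sizes = protein_effect_sizes,
              protein_baselines = protein_baselines,
              branch_offsets = branch_offsets,
              noise_sd = noise_sd, geom_noise_cv = geom_noise_cv,
              hc_blob_count_range = as.integer(hc_blob_count_range),
              n_replicates = as.integer(n_replicates),
              canvas_um = canvas_um, rng_seed = as.integer(rng_seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (abs(sum(cfg$branch_probs) - 1) > 1e-9)
    stop("branch_probs must sum to 1", call. = FALSE)
  if (!setequal(names(cfg$branch_probs),
                c("pre_decision", "transient", "success")))
    stop("branch_probs must be named pre_decision, transient, success",
         call. = FALSE)
  if (any(cfg$voxel_spacing <= 0)) stop("voxel_spacing must be positive",
                                        call. = FALSE)
  if (cfg$pattern_width <= 0 || cfg$pattern_length <= 0 ||
      cfg$n_colonies_per_day <= 0 || cfg$doubling_time_days <= 0)
    stop("lengths and counts must be strictly positive", call. = FALSE)
  if (cfg$pattern_length > cfg$canvas_um[2] || cfg$pattern_width > cfg$canvas_um[1])
    stop("micropattern footprint exceeds the image canvas", call. = FALSE)
  invisible(cfg)
}

.BRANCHES <- c("pre_decision", "transient", "success")
.CHANNELS <- c("dna", "actin", "oct4", "vimentin", "ecadherin", "lamin",
               "h3k9ac", "pmlc", "edu")
# nuclear channels are rendered inside nuclei; the rest fill the cytoplasm
.NUCLEAR_CHANNELS <- c("dna", "oct4", "lamin", "h3k9ac", "edu")

# Latent progression coordinate: success advances linearly to 1 at day 10;
# transient arrests growth at the day-4 state but keeps a slow residual
# chromatin/marker drift; pre-decision pauses earliest. Nondecreasing in day.
progression_s <- function(day, branch) {
  switch(branch,
         success = day / 10,
         transient = min(day, 4) / 10 + 0.015 * max(day - 4, 0),
         pre_decision = min(day, 2) / 10 + 0.008 * max(day - 2, 0),
         stop("unknown branch: ", branch))
}

# Branch expressed by a colony's morphological state: below the bifurcation
# region every colony is pre-decision (small, elongated, pattern-shaped);
# in the small-spherical mid range it is transient; past it, success. A
# success-fate colony passes through the transient state on its way, which
# reproduces the mixed day-4 branch composition seen in confined growth.
expressed_branch <- function(s) {
  if (s < 0.35) "pre_decision" else if (s < 0.55) "transient" else "success"
}

n_nuclei_for <- function(day, branch, doubling_time_days) {
  grown <- function(d) max(1L, as.integer(round(2^(d / doubling_time_days))))
  switch(branch,
         success = grown(day),
         transient = grown(min(day, 4)),
         pre_decision = min(grown(day), 2L))
}

# Nucleus semi-axes (um): elongated fibroblast nucleus rounding up and
# shrinking slightly as progression advances.
nucleus_axes <- function(s) {
  a <- 2.5 + (3.2 - 2.5) * s    # x
  b <- 9.0 + (3.2 - 9.0) * s    # y (pattern long axis)
  c <- 2.0 + (2.8 - 2.0) * s    # z
  c(a, b, c)
}

# Planted heterochromatin fraction of the nuclear volume; decreases with
# progression (chromatin decondensation).
hc_fraction_true <- function(s) 0.18 - 0.12 * s

planted_mean <- function(cfg, channel, s, branch) {
  base <- cfg$protein_baselines[[channel]]
  slope <- cfg$protein_effect_sizes[[channel]]
  off <- cfg$branch_offsets[[branch]]
  off_c <- if (!is.null(off) && channel %in% names(off)) off[[channel]] else 0
  base + slope * s + off_c
}

# Colony envelope for day > 0. The trajectory passes through the three
# observed colony archetypes (small elongated / small spherical / large
# spherical) via two fairly sharp morphological transitions: around
# s = 0.35 the colony lets go of the elongated micropattern footprint and
# contracts to a round, still-flat colony; past s = 0.55 it grows
# vertically into a domed spheroid whose volume tracks the nucleus count
# (packing factor 3: nuclei occupy about a third of the colony volume).
# Within each archetype a gentle drift keeps the ordering in s resolvable.
envelope_axes <- function(s, n_nuclei, cfg) {
  nv <- nucleus_axes(s)
  v_pack <- 3.0 * n_nuclei * 4 / 3 * pi * prod(nv)
  r_round <- (3 * v_pack / (4 * pi))^(1 / 3)
  dome <- clamp((s - 0.55) / 0.12, 0, 1)   # vertical (3D) growth
  az_flat <- 2.6 + 1.0 * clamp(s / 0.30, 0, 1)
  az <- max(nv[3] * 1.3, (1 - dome) * az_flat + dome * r_round)
  az <- min(az, cfg$canvas_um[3] / 2 * 0.95)
  r_xy <- sqrt(3 * v_pack / (4 * pi * az)) # round footprint holding v_pack
  w <- 0.15 * clamp(s / 0.30, 0, 1) +      # within-archetype drift
    0.85 * clamp((s - 0.30) / 0.12, 0, 1)  # footprint release
  ax0 <- cfg$pattern_width / 2 * 0.92
  ay0 <- cfg$pattern_length / 2 * 0.92
  ax <- (1 - w) * ax0 + w * max(r_xy, nv[1] * 1.15)
  ay <- (1 - w) * ay0 + w * max(r_xy, nv[2] * 1.15)
  c(ax, ay, az)
}

# Radius of an ellipsoid (semi-axes ax, rotated by theta about z) along the
# unit direction u.
ellipsoid_radius <- function(axes, theta, u) {
  v1 <- u[1] * cos(theta) + u[2] * sin(theta)
  v2 <- -u[1] * sin(theta) + u[2] * cos(theta)
  1 / sqrt((v1 / axes[1])^2 + (v2 / axes[2])^2 + (u[3] / axes[3])^2)
}

place_nuclei <- function(n, env_axes, nuc_axes, min_dist_factor = 0.95) {
  # rejection sampling inside the (shrunken) envelope. The pairwise
  # constraint is direction-dependent: centers must be at least
  # min_dist_factor * (r_i(u) + r_j(u)) apart, where r(u) is each
  # ellipsoid's radius along the separation direction, so elongated nuclei
  # pack near-tangentially with slight overlap (the watershed split stays
  # exercised). The constraint is relaxed gradually if space runs out.
  lim <- pmax(env_axes - nuc_axes * 0.9, env_axes * 0.25)
  # in elongated colonies the nuclei align with the colony long axis (as in
  # confined elongated cells); in round colonies orientation is isotropic
  env_elong <- max(env_axes[1:2]) / min(env_axes[1:2])
  aligned <- env_elong > 1.5 && nuc_axes[2] / nuc_axes[1] > 1.5
  relax <- 1.0
  repeat {
    # greedy sequential placement; a full restart when stuck explores the
    # configuration space far better than relaxing the constraint in place
    centers <- matrix(NA_real_, n, 3)
    thetas <- numeric(n)
    placed <- 0L
    tries <- 0L
    while (placed < n && tries < 400L * n) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
      cand <- u * lim
      th <- if (aligned) stats::rnorm(1, 0, 0.3) else stats::runif(1, 0, pi)
      ok <- TRUE
      if (placed > 0) {
        for (i in seq_len(placed)) {
          sep <- cand - centers[i, ]
          dd <- sqrt(sum(sep^2))
          if (dd == 0) { ok <- FALSE; break }
          ud <- sep / dd
          need <- min_dist_factor * relax *
            (ellipsoid_radius(nuc_axes, th, ud) +
               ellipsoid_radius(nuc_axes, thetas[i], ud))
          if (dd < need) { ok <- FALSE; break }
        }
      }
      if (ok) {
        placed <- placed + 1L
        centers[placed, ] <- cand
        thetas[placed] <- th
      }
      tries <- tries + 1L
    }
    if (placed == n) break
    relax <- relax * 0.95  # only after a full failed restart
  }
  list(centers = centers, thetas = thetas)
}

#' Generate one synthetic colony image with ground truth
#'
#' Day 0 returns a single elongated cell filling the rectangular micropattern
#' footprint with parallel bright actin fibers and one elongated nucleus;
#' later days return a cluster of ellipsoidal nuclei inside a colony envelope
#' whose elongation decreases and volume increases with progression on the
#' success branch, plateaus after day 4 on the transient branch, and stays
#' elongated and small on the pre-decision branch. Protein channel means are
#' baseline + slope * progression + branch offset (+ Gaussian read noise);
#' nuclei contain bright heterochromatin blobs whose total volume decreases
#' with progression.
#'
#' @param config a [generator_config()].
#' @param day integer day, must be in `config$days`.
#' @param branch one of `"pre_decision"`, `"transient"`, `"success"`.
#' @param seed integer seed for this colony's RNG stream.
#' @param colony_id identifier stored in the metadata.
#' @param replicate replicate label.
#' @return list with elements `image` (a `colony_image`: 4-D array
#'   `[x, y, z, channel]`, spacing, channel names, metadata) and `truth`
#'   (one-row data.frame ground-truth record).
#' @export
generate_colony <- function(config, day, branch, seed = config$rng_seed,
                            colony_id = sprintf("d%02d_c001", day),
                            replicate = 1L) {
  validate_generator_config(config)
  if (!day %in% config$days)
    stop("day ", day, " is not in config$days", call. = FALSE)
  branch <- match.arg(branch, .BRANCHES)
  set.seed(seed)

  s <- progression_s(day, branch)
  n_nuc <- n_nuclei_for(day, branch, config$doubling_time_days)
  sp <- config$voxel_spacing
  nuc_ax <- nucleus_axes(s)

  if (day == 0) {
    n_nuc <- 1L
    half <- c(config$pattern_width / 2, config$pattern_length / 2, 1.2)
    env <- list(type = "box", half = half)
    centers <- matrix(0, 1, 3)
    # a single spread cell is thin, with a strongly flattened nucleus
    nuc_list <- list(list(center = c(0, 0, 0), axes = c(3.0, 14.0, 1.0),
                          theta = 0))
  } else {
    gnoise <- if (config$geom_noise_cv > 0)
      exp(stats::rnorm(1, 0, config$geom_noise_cv)) else 1
    env_ax <- envelope_axes(s, n_nuc, config) * gnoise
    env <- list(type = "ellipsoid", half = env_ax)
    pl <- place_nuclei(n_nuc, env_ax, nuc_ax)
    nuc_list <- lapply(seq_len(n_nuc), function(i)
      list(center = pl$centers[i, ], axes = nuc_ax, theta = pl$thetas[i]))
  }

  # crop box (um) around the envelope with margin
  margin <- 4
  half_ext <- if (env$type == "box") env$half else env$half
  ext <- pmin(half_ext + margin, config$canvas_um / 2)
  dims <- pmax(4L, as.integer(ceiling(2 * ext / sp)))
  # physical coordinates of voxel centers, origin at the envelope center
  xs <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp[1]
  ys <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp[2]
  zs <- (seq_len(dims[3]) - (dims[3] + 1) / 2) * sp[3]
  cx <- array(rep(xs, times = dims[2] * dims[3]), dims)
  cy <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
  cz <- array(rep(zs, each = dims[1] * dims[2]), dims)

  env_mask <- if (env$type == "box") {
    abs(cx) <= env$half[1] & abs(cy) <= env$half[2] & abs(cz) <= env$half[3]
  } else {
    (cx / env$half[1])^2 + (cy / env$half[2])^2 + (cz / env$half[3])^2 <= 1
  }

  nuc_id <- array(0L, dims)
  dna_core <- array(FALSE, dims)
  core_scale <- 0.90  # chromatin stops short of the nuclear envelope
  for (i in seq_along(nuc_list)) {
    nu <- nuc_list[[i]]
    dx <- cx - nu$center[1]; dy <- cy - nu$center[2]; dz <- cz - nu$center[3]
    rx <- dx * cos(nu$theta) + dy * sin(nu$theta)
    ry <- -dx * sin(nu$theta) + dy * cos(nu$theta)
    r2 <- (rx / nu$axes[1])^2 + (ry / nu$axes[2])^2 + (dz / nu$axes[3])^2
    inside <- r2 <= 1
    nuc_id[inside & nuc_id == 0L] <- i
    dna_core <- dna_core | (r2 <= core_scale^2 & nuc_id == i)
  }
  nuc_mask <- nuc_id > 0L
  cyto_mask <- env_mask & !nuc_mask

  # heterochromatin blobs: per-nucleus planted total volume, split over blobs
  v_nuc_true <- 4 / 3 * pi * prod(nuc_ax)
  if (day == 0) v_nuc_true <- 4 / 3 * pi * prod(nuc_list[[1]]$axes)
  hc_total <- hc_fraction_true(s) * v_nuc_true
  hc_mask <- array(FALSE, dims)
  for (i in seq_along(nuc_list)) {
    nu <- nuc_list[[i]]
    nb <- sample(seq(config$hc_blob_count_range[1],
                     config$hc_blob_count_range[2]), 1)
    rb <- (3 * (hc_total / nb) / (4 * pi))^(1 / 3)
    for (b in seq_len(nb)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
      bc <- nu$center + u * nu$axes * 0.55
      inside <- ((cx - bc[1])^2 + (cy - bc[2])^2 + (cz - bc[3])^2) <= rb^2
      hc_mask <- hc_mask | (inside & nuc_id == i)
    }
  }

  # planted colony-level protein means (exact affine function of s)
  prot <- vapply(names(config$protein_baselines), function(ch)
    planted_mean(config, ch, s, branch), numeric(1))

  # per-nucleus Oct4 heterogeneity: branch-specific planted CV, exactly
  # mean-1 factors so the colony mean stays the planted value
  cv_branch <- c(pre_decision = 0.15, transient = 0.25, success = 0.08)[branch]
  if (n_nuc >= 2) {
    z <- stats::rnorm(n_nuc)
    z <- (z - mean(z)) / pop_sd(z)
    oct4_factors <- pmax(0.1, 1 + cv_branch * z)
    oct4_factors <- oct4_factors / mean(oct4_factors)
  } else {
    oct4_factors <- 1
  }

  # proliferation: everything proliferates through day 4; after the
  # bifurcation only the success branch keeps cycling
  proliferating <- day <= 4 || branch == "success"
  edu_pos <- rep(FALSE, n_nuc)
  if (proliferating) {
    edu_pos <- stats::runif(n_nuc) < 0.6
    if (!any(edu_pos)) edu_pos[sample.int(n_nuc, 1)] <- TRUE
  }

  dna_base <- 3000
  vox <- array(0, c(dims, length(.CHANNELS)),
               dimnames = list(NULL, NULL, NULL, .CHANNELS))
  vox[, , , "dna"] <- dna_base * dna_core + dna_base * 1.5 * hc_mask
  # cytoplasmic actin; cortical actin above/below the nuclei renders the
  # nuclear columns at comparable brightness, so the envelope reads as one
  # solid body (as it does in real confocal stacks)
  actin <- 2500 * cyto_mask + 2500 * nuc_mask
  if (day == 0) {
    # parallel stress fibers along the pattern long axis
    fiber <- (round(cx / 3) %% 2 == 0)
    actin <- (1500 + 2500 * fiber) * cyto_mask + 2750 * nuc_mask
  }
  vox[, , , "actin"] <- actin
  for (ch in names(prot)) {
    if (ch %in% .NUCLEAR_CHANNELS) {
      if (ch == "oct4" && n_nuc >= 2) {
        lay <- array(0, dims)
        for (i in seq_len(n_nuc))
          lay[nuc_id == i] <- prot[[ch]] * oct4_factors[i]
        vox[, , , ch] <- lay
      } else {
        vox[, , , ch] <- prot[[ch]] * nuc_mask
      }
    } else {
      vox[, , , ch] <- prot[[ch]] * cyto_mask
    }
  }
  edu_lay <- 300 * nuc_mask
  for (i in which(edu_pos)) edu_lay[nuc_id == i] <- 5000
  vox[, , , "edu"] <- edu_lay

  if (config$noise_sd > 0) {
    vox <- vox + array(stats::rnorm(length(vox), 0, config$noise_sd), dim(vox))
    vox[vox < 0] <- 0
  }

  img <- structure(list(voxels = vox, spacing = sp, channel_names = .CHANNELS,
                        metadata = list(colony_id = colony_id, day = day,
                                        replicate = replicate,
                                        treatment = "control"),
                        truth_masks = list(envelope = env_mask,
                                           nuclei = nuc_id)),
                   class = "colony_image")

  geom_json <- jsonlite::toJSON(lapply(nuc_list, function(nu)
    list(center = round(nu$center, 4), axes = round(nu$axes, 4),
         theta = round(nu$theta, 4))), auto_unbox = TRUE, digits = NA)
  env_volume <- if (env$type == "box") 8 * prod(env$half) else
    4 / 3 * pi * prod(env$half)
  truth <- data.frame(colony_id = colony_id, day = day, replicate = replicate,
                      branch = branch,
                      branch_expressed = expressed_branch(s),
                      progression_s = s, n_nuclei = n_nuc,
                      proliferating = proliferating,
                      hc_volume_true = hc_total,
                      envelope_volume_true = env_volume,
                      stringsAsFactors = FALSE)
  for (ch in names(prot)) truth[[paste0("planted_", ch)]] <- prot[[ch]]
  truth$nucleus_geometries <- as.character(geom_json)
  list(image = img, truth = truth)
}

#' Generate a full synthetic time course
#'
#' Colonies per day are generated with branches drawn i.i.d. from
#' `config$branch_probs` and replicates assigned round-robin. Per-colony RNG
#' streams are derived from the root seed by counter-based splitting, so the
#' dataset (and any subset of it) is reproducible.
#'
#' @param config a [generator_config()].
#' @return list with `images` (list of `colony_image`) and `truth`
#'   (data.frame, one ground-truth row per colony).
#' @export
generate_timecourse <- function(config) {
  validate_generator_config(config)
  set.seed(derive_seed(config$rng_seed, 0L))
  n_total <- length(config$days) * config$n_colonies_per_day
  branches <- sample(.BRANCHES, n_total, replace = TRUE,
                     prob = config$branch_probs[.BRANCHES])
  images <- vector("list", n_total)
  truths <- vector("list", n_total)
  idx <- 0L
  for (day in config$days) {
    for (j in seq_len(config$n_colonies_per_day)) {
      idx <- idx + 1L
      cid <- sprintf("d%02d_c%03d", day, j)
      out <- generate_colony(config, day, branches[idx],
                             seed = derive_seed(config$rng_seed, idx),
                             colony_id = cid,
                             replicate = ((j - 1L) %% config$n_replicates) + 1L)
      images[[idx]] <- out$image
      truths[[idx]] <- out$truth
    }
  }
  list(images = images, truth = do.call(rbind, truths))
}

#' Simulate a colony feature table directly from planted geometry
#'
#' Feature-level phantom: computes the morphometric feature vector in closed
#' form from each colony's planted envelope (ellipsoid volume, elongation,
#' flatness, sphericity via the Thomsen surface-area approximation, Feret
#' diameters, projected-ellipse area/circularity/aspect ratio) plus planted
#' protein means, with small lognormal measurement noise. Orders of magnitude
#' faster than rendering and segmenting voxel images; used to exercise the
#' index, regression and trajectory modules at realistic sample sizes.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (defaults to the config root seed).
#' @param measurement_cv lognormal CV of the simulated feature measurement.
#' @return data.frame: metadata (colony_id, day, replicate, branch,
#'   progression_s, proliferating), features, and `mean_<channel>` columns.
#' @export
simulate_feature_table <- function(config, seed = config$rng_seed,
                                   measurement_cv = 0.04) {
  validate_generator_config(config)
  set.seed(seed)
  n_total <- length(config$days) * config$n_colonies_per_day
  branches <- sample(.BRANCHES, n_total, replace = TRUE,
                     prob = config$branch_probs[.BRANCHES])
  rows <- vector("list", n_total)
  idx <- 0L
  for (day in config$days) {
    for (j in seq_len(config$n_colonies_per_day)) {
      idx <- idx + 1L
      br <- branches[idx]
      s <- progression_s(day, br)
      n_nuc <- n_nuclei_for(day, br, config$doubling_time_days)
      if (day == 0) {
        half <- c(config$pattern_width / 2, config$pattern_length / 2, 1.2)
        ax <- sort(half, decreasing = TRUE)
        volume <- 8 * prod(half)
        sa <- 8 * (half[1] * half[2] + half[1] * half[3] + half[2] * half[3])
        feret <- 2 * sqrt(sum(half^2))
        min_feret <- 2 * min(half)
        proj_area <- 4 * half[1] * half[2]
        proj_perim <- 4 * (half[1] + half[2])
        aspect <- max(half[1:2]) / min(half[1:2])
      } else {
        gn <- exp(stats::rnorm(1, 0, config$geom_noise_cv))
        e_ax <- envelope_axes(s, n_nuc, config) * gn
        ax <- sort(e_ax, decreasing = TRUE)
        volume <- 4 / 3 * pi * prod(e_ax)
        p <- 1.6075  # Thomsen approximation for ellipsoid surface area
        sa <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                           ax[2]^p * ax[3]^p) / 3)^(1 / p)
        feret <- 2 * ax[1]
        min_feret <- 2 * ax[3]
        proj_area <- pi * e_ax[1] * e_ax[2]
        a2 <- max(e_ax[1:2]); b2 <- min(e_ax[1:2])
        h <- ((a2 - b2) / (a2 + b2))^2
        proj_perim <- pi * (a2 + b2) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
        aspect <- a2 / b2
      }
      m <- function(x) x * exp(stats::rnorm(1, 0, measurement_cv))
      prot <- vapply(names(config$protein_baselines), function(ch) {
        mu <- planted_mean(config, ch, s, br)
        mu + stats::rnorm(1, 0, config$noise_sd)
      }, numeric(1))
      row <- data.frame(
        colony_id = sprintf("d%02d_c%03d", day, j), day = day,
        replicate = ((j - 1L) %% config$n_replicates) + 1L, branch = br,
        branch_expressed = expressed_branch(s),
        progression_s = s, proliferating = day <= 4 || br == "success",
        n_nuclei = n_nuc,
        volume = m(volume),
        sphericity = clamp(m((36 * pi * volume^2)^(1 / 3) / sa), 0, 1),
        elongation = clamp(m(ax[2] / ax[1]), 0, 1),
        flatness = clamp(m(ax[3] / ax[1]), 0, 1),
        feret = m(feret), min_feret = m(min_feret), major_radius = m(ax[1]),
        projected_area = m(proj_area),
        circularity = clamp(m(4 * pi * proj_area / proj_perim^2), 0, 1),
        aspect_ratio = max(1, m(aspect)),
        stringsAsFactors = FALSE)
      for (ch in names(prot)) row[[paste0("mean_", ch)]] <- prot[[ch]]
      rows[[idx]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic brightfield alkaline-phosphatase images
#'
#' Renders spheroid discs over a bright background by Beer-Lambert mixing of
#' the configured chromogen stain vector: positives at high optical density,
#' negatives with a faint neutral-grey attenuation only, plus Gaussian pixel
#' noise. Returns the per-spheroid truth labels.
#'
#' @param config a [generator_config()] (used for the seed only).
#' @param positive_fraction fraction of spheroids rendered AP-positive.
#' @param n_spheroids number of spheroids in the image.
#' @param seed RNG seed.
#' @param stain_vector RGB stain vector (unit-normalized internally).
#' @param size image (height, width) in pixels.
#' @param noise_sd pixel noise SD on the [0, 1] intensity scale.
#' @return list: `image` (H x W x 3 array in [0, 1]), `labels` (data.frame
#'   with center, radius, positive flag, planted optical density).
#' @export
generate_brightfield_ap <- function(config, positive_fraction = 0.6,
                                    n_spheroids = 12L,
                                    seed = config$rng_seed,
                                    stain_vector = c(0.65, 0.40, 0.64),
                                    size = c(360L, 480L), noise_sd = 0.01) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1)
  set.seed(seed)
  sv <- stain_vector / sqrt(sum(stain_vector^2))
  bg <- c(0.93, 0.93, 0.95)
  img <- array(rep(bg, each = prod(size)), c(size, 3))
  h <- size[1]; w <- size[2]
  # non-overlapping centers on a jittered grid
  ngrid <- ceiling(sqrt(n_spheroids))
  cells <- expand.grid(gy = seq_len(ngrid), gx = seq_len(ngrid))
  cells <- cells[sample.int(nrow(cells), n_spheroids), , drop = FALSE]
  rad <- pmin(h, w) / (ngrid * 2) * 0.55
  pos <- stats::runif(n_spheroids) < positive_fraction
  labs <- data.frame(spheroid_id = seq_len(n_spheroids),
                     cy = (cells$gy - 0.5) * h / ngrid,
                     cx = (cells$gx - 0.5) * w / ngrid,
                     radius = rad * stats::runif(n_spheroids, 0.8, 1.2),
                     positive = pos)
  labs$od_stain <- ifelse(pos, stats::runif(n_spheroids, 0.75, 0.95),
                          stats::runif(n_spheroids, 0.02, 0.06))
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  grey <- c(1, 1, 1) / sqrt(3)
  for (i in seq_len(n_spheroids)) {
    inside <- (yy - labs$cy[i])^2 + (xx - labs$cx[i])^2 <= labs$radius[i]^2
    od <- outer(c(inside), labs$od_stain[i] * sv) +
      outer(c(inside), 0.22 * grey)          # cell-mass grey attenuation
    trans <- 10^(-od)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * array(trans[, ch], c(h, w))
  }
  if (noise_sd > 0) {
    img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim(img))
    img <- clamp(img, 0, 1)
  }
  list(image = img, labels = labs, background = bg)
}

#' Write a synthetic dataset to disk
#'
#' One multi-channel 16-bit TIFF per colony (pages ordered channel-major:
#' all z-planes of channel 1, then channel 2, ...), the ground truth as CSV
#' (per-nucleus geometry as a nested JSON column), and a manifest JSON
#' recording files, image shapes, the channel order, the root seed and a
#' config fingerprint.
#'
#' @param dataset output of [generate_timecourse()].
#' @param directory output directory (created if needed).
#' @param config the [generator_config()] used (hashed into the manifest).
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(dataset, directory, config = NULL) {
  if (length(dataset$images) == 0) stop("dataset is empty", call. = FALSE)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory,
                                   call. = FALSE)
  files <- character(0)
  shapes <- list()
  for (img in dataset$images) {
    v <- round(clamp(img$voxels, 0, 65535))
    d <- dim(v)
    pages <- vector("list", d[3] * d[4])
    p <- 0L
    for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
      p <- p + 1L
      pages[[p]] <- t(v[, , z, ch]) / 65535   # writeTIFF wants row-major [0,1]
    }
    f <- file.path(directory, paste0(img$metadata$colony_id, ".tif"))
    tiff::writeTIFF(pages, f, bits.per.sample = 16L, compression = "none")
    files <- c(files, basename(f))
    shapes[[img$metadata$colony_id]] <- list(dim = d,
                                             spacing = img$spacing,
                                             channels = img$channel_names)
  }
  truth_csv <- file.path(directory, "ground_truth.csv")
  utils::write.csv(dataset$truth, truth_csv, row.names = FALSE)
  manifest <- list(files = files, truth = basename(truth_csv),
                   n_colonies = length(dataset$images),
                   channel_order = .CHANNELS,
                   page_order = "channel-major (z fastest)",
                   shapes = shapes,
                   seed = if (!is.null(config)) config$rng_seed else NA,
                   config_hash = if (!is.null(config)) config_hash(config)
                   else NA)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param directory dataset directory containing the manifest.
#' @return list with `images` and `truth` mirroring [generate_timecourse()].
#' @export
read_dataset <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  truth <- utils::read.csv(file.path(directory, manifest$truth),
                           stringsAsFactors = FALSE)
  images <- lapply(manifest$files, function(f) {
    cid <- sub("\\.tif$", "", f)
    sh <- manifest$shapes[[cid]]
    d <- as.integer(unlist(sh$dim))
    pages <- tiff::readTIFF(file.path(directory, f), all = TRUE)
    v <- array(0, d)
    p <- 0L
    for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
      p <- p + 1L
      v[, , z, ch] <- t(pages[[p]]) * 65535
    }
    v <- round(v)
    dimnames(v) <- list(NULL, NULL, NULL, unlist(sh$channels))
    meta_row <- truth[truth$colony_id == cid, , drop = FALSE]
    structure(list(voxels = v, spacing = as.numeric(unlist(sh$spacing)),
                   channel_names = unlist(sh$channels),
                   metadata = list(colony_id = cid,
                                   day = meta_row$day[1],
                                   replicate = meta_row$replicate[1],
                                   treatment = "control")),
              class = "colony_image")
  })
  list(images = images, truth = truth, manifest = manifest)
}
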