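#' @title End-to-end pipeline
#' @description Orchestrates simulate -> segment -> features -> indices ->
#'   trajectory -> AP assay -> report with a single config, deterministic
#'   seeds, and CSV/JSON outputs; plus validation of every stage against the
#'   generator's planted ground truth.
#' @name pipeline_cli
NULL

#' Extract the full feature set of one colony image
#'
#' Runs colony segmentation, nuclei segmentation, colony shape features,
#' nuclear morphometry (shape, heterochromatin, texture), protein summaries
#' and Voronoi proxy volumes.
#'
#' @param image a `colony_image`.
#' @param seg_channel channel for colony segmentation.
#' @param dna_channel DNA channel.
#' @param sigma_um colony smoothing sigma (um).
#' @param nuclei_args list of extra arguments to [segment_nuclei()].
#' @return list: `colony` (one-row data.frame), `nuclei` (per-nucleus
#'   data.frame), `qc` (list: thresholds, counts, IoU vs truth when the
#'   image carries truth masks), `edu_means` (per-nucleus EdU means),
#'   `labels`, `mask`.
#' @export
extract_colony_features <- function(image, seg_channel = "actin",
                                    dna_channel = "dna", sigma_um = 1.0,
                                    nuclei_args = list()) {
  meta <- image$metadata
  mask <- segment_colony(image, channel = seg_channel, sigma_um = sigma_um)
  labels <- do.call(segment_nuclei,
                    c(list(image = image, mask = mask,
                           dna_channel = dna_channel), nuclei_args))
  shape <- colony_shape_features(mask)
  prot <- protein_summaries(image, mask, labels)
  colony <- cbind(data.frame(colony_id = meta$colony_id, day = meta$day,
                             replicate = meta$replicate,
                             treatment = meta$treatment,
                             n_nuclei = labels$n,
                             stringsAsFactors = FALSE),
                  shape)
  for (ch in names(prot$colony_means))
    colony[[paste0("mean_", ch)]] <- prot$colony_means[[ch]]
  for (ch in names(prot$cv))
    colony[[paste0("cv_", ch)]] <- prot$cv[[ch]]

  nuclei <- NULL
  edu_means <- numeric(0)
  if (labels$n > 0) {
    hc <- heterochromatin_volume(image, labels, dna_channel)
    tex <- glcm_texture(image, labels, dna_channel)
    vor <- voronoi_cell_proxies(labels, mask)
    geom <- lapply(seq_len(labels$n), function(i) {
      sub <- labels$labels == i
      ax <- tryCatch(bounding_ellipsoid_axes(sub, labels$spacing),
                     error = function(e) rep(NA_real_, 6),
                     warning = function(w) suppressWarnings(
                       bounding_ellipsoid_axes(sub, labels$spacing)))
      data.frame(nucleus_elongation = ax[["elongation"]],
                 nucleus_flatness = ax[["flatness"]],
                 nucleus_major_radius = ax[["major_radius"]])
    })
    nuclei <- cbind(data.frame(colony_id = meta$colony_id, day = meta$day,
                               replicate = meta$replicate,
                               stringsAsFactors = FALSE),
                    hc, do.call(rbind, geom),
                    tex[, -1, drop = FALSE],
                    voronoi_volume = vor)
    edu_means <- nucleus_means(image, labels, "edu")
  }
  qc <- list(colony_id = meta$colony_id,
             colony_threshold = mask$threshold,
             nuclei_threshold = labels$threshold,
             n_nuclei = labels$n, nuclei_warning = labels$warning,
             mask_voxels = sum(mask$mask))
  if (!is.null(image$truth_masks)) {
    inter <- sum(mask$mask & image$truth_masks$envelope)
    uni <- sum(mask$mask | image$truth_masks$envelope)
    qc$mask_iou <- inter / uni
  }
  list(colony = colony, nuclei = nuclei, qc = qc, edu_means = edu_means,
       labels = labels, mask = mask)
}

#' Build colony and nucleus feature tables from a set of images
#'
#' Runs [extract_colony_features()] over all images, then applies the
#' batch-level EdU threshold (Otsu across all per-nucleus EdU means) to call
#' per-colony proliferation.
#'
#' @param images list of `colony_image`.
#' @param ... forwarded to [extract_colony_features()].
#' @return list: `colonies` (feature table with `proliferating` column),
#'   `nuclei` (per-nucleus table), `qc` (list per colony).
#' @export
build_feature_tables <- function(images, ...) {
  res <- lapply(images, extract_colony_features, ...)
  all_means <- unlist(lapply(res, `[[`, "edu_means"))
  bt <- edu_batch_threshold(all_means)
  prolif <- vapply(res, function(r)
    length(r$edu_means) > 0 && any(r$edu_means > bt$threshold), logical(1))
  colonies <- do.call(rbind, lapply(res, `[[`, "colony"))
  colonies$proliferating <- prolif
  nuclei <- do.call(rbind, Filter(Negate(is.null),
                                  lapply(res, `[[`, "nuclei")))
  list(colonies = colonies, nuclei = nuclei,
       qc = lapply(res, `[[`, "qc"), edu_threshold = bt)
}

.known_pipeline_keys <- c("out_dir", "seed", "stages", "generator",
                          "segmentation", "trajectory", "assay",
                          "write_images")

#' Pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed (propagated to every stochastic stage).
#' @param stages character vector of enabled stages, in order, among
#'   `simulate`, `segment`, `indices`, `trajectory`, `assay_ap`, `report`.
#' @param generator named list of [generator_config()] overrides.
#' @param segmentation named list: `seg_channel`, `dna_channel`,
#'   `sigma_um`, `nuclei_args`.
#' @param trajectory named list: `kernel_sigma`, `n_pc`, `k`.
#' @param assay named list: `n_images`, `positive_fraction`,
#'   `n_spheroids`.
#' @param write_images write per-colony TIFFs during simulate.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("colonymorph_run_"),
                            seed = 1L,
                            stages = c("simulate", "segment", "indices",
                                       "trajectory", "assay_ap", "report"),
                            generator = list(),
                            segmentation = list(),
                            trajectory = list(),
                            assay = list(),
                            write_images = FALSE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              generator = generator, segmentation = segmentation,
              trajectory = trajectory, assay = assay,
              write_images = write_images)
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and unknown stage names.
#'
#' @param cfg a `pipeline_config`.
#' @return the config, invisibly; errors on invalid input.
#' @export
validate_pipeline_config <- function(cfg) {
  unknown <- setdiff(names(unclass(cfg)), .known_pipeline_keys)
  if (length(unknown) > 0)
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(cfg$stages, c("simulate", "segment", "indices",
                               "trajectory", "assay_ap", "report"))
  if (length(bad) > 0)
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Read / write a pipeline config as YAML
#'
#' The YAML representation mirrors the config field-for-field and
#' round-trips losslessly; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config` to write.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order: simulate (synthetic time course),
#' segment (+ feature tables), indices (CGI, CRI, per-replicate
#' normalization, protein regressions, day-10 clustering), trajectory
#' (diffusion map on days 0-8, pseudotime, branches, day-10 projection),
#' assay_ap (brightfield AP quantification), report (manifest + QC +
#' validation metrics). Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (also written under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config, config_hash = config_hash(config))
  st <- config$stages

  if ("simulate" %in% st) {
    gen_args <- config$generator
    gen_args$rng_seed <- config$seed
    gcfg <- do.call(generator_config, gen_args)
    res$generator_config <- gcfg
    res$dataset <- generate_timecourse(gcfg)
    utils::write.csv(res$dataset$truth,
                     file.path(config$out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    if (isTRUE(config$write_images))
      write_dataset(res$dataset, file.path(config$out_dir, "images"), gcfg)
  }

  if ("segment" %in% st) {
    if (is.null(res$dataset)) stop("segment stage needs simulated images",
                                   call. = FALSE)
    ft <- do.call(build_feature_tables,
                  c(list(images = res$dataset$images), config$segmentation))
    res$features <- ft
    utils::write.csv(ft$colonies,
                     file.path(config$out_dir, "colony_features.csv"),
                     row.names = FALSE)
    utils::write.csv(ft$nuclei,
                     file.path(config$out_dir, "nucleus_features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(ft$qc, file.path(config$out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("indices" %in% st) {
    tab <- res$features$colonies
    cgi <- compute_cgi(tab, features = morphology_features(tab))
    tab$cgi <- cgi$scores
    res$cgi <- cgi
    nuc <- res$features$nuclei
    nuc_feats <- intersect(c("nucleus_volume", "hc_volume", "hc_fraction",
                             "nucleus_elongation", "nucleus_flatness",
                             "nucleus_major_radius", "texture_idm",
                             "texture_entropy", "texture_correlation",
                             "texture_contrast"), names(nuc))
    ok <- stats::complete.cases(nuc[, nuc_feats])
    cri <- tryCatch(compute_cri(nuc[ok, ], features = nuc_feats),
                    error = function(e) NULL)
    if (!is.null(cri)) {
      res$cri <- cri
      tab$cri <- as.numeric(cri$colony_scores[tab$colony_id])
    }
    prot_cols <- grep("^mean_", names(tab), value = TRUE)
    res$regressions <- lapply(setNames(prot_cols, prot_cols), function(p)
      tryCatch(fit_protein_model(tab, p, seed = config$seed),
               error = function(e) NULL))
    d10 <- tab[tab$day == max(tab$day), ]
    if (nrow(d10) >= 3)
      res$day10_clusters <- hierarchical_cluster_day10(
        d10, k = 3L, features = morphology_features(d10))
    res$features$colonies <- tab
    utils::write.csv(tab, file.path(config$out_dir, "colony_features.csv"),
                     row.names = FALSE)
  }

  if ("trajectory" %in% st) {
    tab <- res$features$colonies
    traj_args <- config$trajectory
    fit_days <- tab$day <= 8
    fit_tab <- tab[fit_days, ]
    emb <- build_diffusion_map(
      fit_tab, features = morphology_features(fit_tab),
      kernel_sigma = traj_args$kernel_sigma %||% 0.8,
      n_pc = traj_args$n_pc %||% 10L)
    pt <- compute_pseudotime(emb, root = "auto", days = fit_tab$day)
    br <- detect_branches(emb, metadata = fit_tab, seed = config$seed)
    fr <- branch_fractions(br$branch, fit_tab, group_by = "day")
    tab$pseudotime <- NA_real_
    tab$branch <- NA_character_
    tab$pseudotime[fit_days] <- pt$pseudotime
    tab$branch[fit_days] <- br$branch
    if (any(!fit_days)) {
      proj <- project_new_colonies(emb, tab[!fit_days, ],
                                   branch_fit = br, pseudotime_fit = pt)
      tab$pseudotime[!fit_days] <- proj$pseudotime
      tab$branch[!fit_days] <- proj$branch
    }
    res$embedding <- emb
    res$pseudotime <- pt
    res$branches <- br
    res$branch_fractions <- fr
    res$features$colonies <- tab
    utils::write.csv(tab, file.path(config$out_dir, "trajectory.csv"),
                     row.names = FALSE)
    utils::write.csv(fr, file.path(config$out_dir, "branch_fractions.csv"),
                     row.names = FALSE)
  }

  if ("assay_ap" %in% st) {
    a <- config$assay
    n_img <- a$n_images %||% 3L
    gcfg <- res$generator_config %||% generator_config(rng_seed = config$seed)
    per_img <- lapply(seq_len(n_img), function(i) {
      bf <- generate_brightfield_ap(
        gcfg, positive_fraction = a$positive_fraction %||% 0.6,
        n_spheroids = a$n_spheroids %||% 12L,
        seed = derive_seed(config$seed, 9000L + i))
      list(truth = bf$labels, result = ap_assay_image(bf$image))
    })
    ap <- do.call(rbind, lapply(per_img, `[[`, "result"))
    res$ap <- list(per_spheroid = ap,
                   truth = do.call(rbind, lapply(per_img, `[[`, "truth")),
                   positive_fraction = mean(ap$positive))
    utils::write.csv(ap, file.path(config$out_dir, "ap_assay.csv"),
                     row.names = FALSE)
  }

  if ("report" %in% st) {
    metrics <- if (!is.null(res$dataset))
      validate_against_truth(res, res$dataset$truth) else NULL
    res$metrics <- metrics
    manifest <- list(config_hash = res$config_hash, seed = config$seed,
                     stages = st,
                     n_colonies = if (!is.null(res$dataset))
                       length(res$dataset$images) else NA,
                     files = list.files(config$out_dir))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(metrics))
      jsonlite::write_json(metrics,
                           file.path(config$out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline results against planted ground truth
#'
#' Computes segmentation IoU, nuclei count error, CGI/pseudotime Spearman
#' correlations with day and planted progression, branch-recovery adjusted
#' Rand index (against the branch expressed at each day), and the
#' EdU-proliferation confusion matrix. Metrics whose inputs are missing are
#' reported as NULL.
#'
#' @param report result list from [run_pipeline()].
#' @param ground_truth the generator truth table.
#' @return named list of metrics.
#' @export
validate_against_truth <- function(report, ground_truth) {
  m <- list()
  qc <- report$features$qc
  if (!is.null(qc)) {
    ious <- unlist(lapply(qc, `[[`, "mask_iou"))
    if (length(ious) > 0) m$mask_iou_mean <- mean(ious)
  }
  tab <- report$features$colonies
  if (!is.null(tab)) {
    tr <- ground_truth[match(tab$colony_id, ground_truth$colony_id), ]
    rel_err <- abs(tab$n_nuclei - tr$n_nuclei) / pmax(tr$n_nuclei, 1)
    m$nuclei_count_within_10pct <- mean(rel_err <= 0.10 + 1e-9)
    if ("cgi" %in% names(tab))
      m$cgi_day_spearman <- spearman(tab$cgi, tab$day)
    if ("pseudotime" %in% names(tab)) {
      sel <- !is.na(tab$pseudotime)
      m$pseudotime_progression_spearman <-
        spearman(tab$pseudotime[sel], tr$progression_s[sel])
    }
    if ("branch" %in% names(tab)) {
      sel <- !is.na(tab$branch)
      m$branch_ari <- adjusted_rand_index(tab$branch[sel],
                                          tr$branch_expressed[sel])
    }
    if ("proliferating" %in% names(tab)) {
      m$edu_recovered_fraction <- mean(tab$proliferating)
      m$edu_true_fraction <- mean(tr$proliferating)
      m$edu_confusion <- as.list(table(paste0(
        "true_", tr$proliferating, "_called_", tab$proliferating)))
    }
  }
  if (!is.null(report$ap)) {
    m$ap_recovered_fraction <- report$ap$positive_fraction
    m$ap_true_fraction <- mean(report$ap$truth$positive)
  }
  m
}
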