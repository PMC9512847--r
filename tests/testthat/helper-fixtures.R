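# Shared fixtures, built in code. Heavy objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# reduced-resolution generator config used throughout the suite
test_gen_config <- function(...) {
  generator_config(voxel_spacing = c(0.6, 0.6, 1.2), ...)
}

# logical 3D ball mask; spacing 1 unless given
ball_mask <- function(r_vox = 20L, spacing = c(1, 1, 1), pad = 5L) {
  n <- 2L * (r_vox + pad) + 1L
  c0 <- r_vox + pad + 1L
  idx <- seq_len(n)
  dx2 <- (idx - c0)^2
  arr <- outer(outer(dx2, dx2, `+`), dx2, `+`) <= r_vox^2
  structure(list(mask = arr, spacing = spacing, threshold = 0,
                 channel = "test"),
            class = "colony_mask")
}

# axis-aligned ellipsoid mask with semi-axes in voxels
ellipsoid_mask <- function(a, b, c, spacing = c(1, 1, 1), pad = 3L) {
  d <- 2L * (ceiling(c(a, b, c)) + pad) + 1L
  ctr <- (d + 1) / 2
  x <- ((seq_len(d[1]) - ctr[1]) / a)^2
  y <- ((seq_len(d[2]) - ctr[2]) / b)^2
  z <- ((seq_len(d[3]) - ctr[3]) / c)^2
  arr <- outer(outer(x, y, `+`), z, `+`) <= 1
  structure(list(mask = arr, spacing = spacing, threshold = 0,
                 channel = "test"),
            class = "colony_mask")
}

# minimal colony_image around a single intensity array
image_from_array <- function(arr, channel = "dna", spacing = c(1, 1, 1)) {
  v <- array(arr, c(dim(arr), 1),
             dimnames = list(NULL, NULL, NULL, channel))
  structure(list(voxels = v, spacing = spacing, channel_names = channel,
                 metadata = list(colony_id = "test", day = 0L,
                                 replicate = 1L, treatment = "control")),
            class = "colony_image")
}

full_mask <- function(d, spacing = c(1, 1, 1)) {
  structure(list(mask = array(TRUE, d), spacing = spacing, threshold = 0,
                 channel = "test"),
            class = "colony_mask")
}

# nuclei_labels wrapper around a prebuilt label array
labels_from_array <- function(lab, spacing = c(1, 1, 1)) {
  structure(list(labels = lab, spacing = spacing, n = max(lab),
                 warning = FALSE, threshold = 0),
            class = "nuclei_labels")
}

# brute-force GLCM oracle: literal double loop over voxel pairs
glcm_oracle <- function(vals3d, sel3d, n_levels = 64L) {
  d <- dim(vals3d)
  rng <- range(vals3d[sel3d])
  lev <- array(0L, d)
  lev[sel3d] <- pmin(n_levels, 1L + as.integer(
    floor((vals3d[sel3d] - rng[1]) / diff(rng) * n_levels)))
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  M <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(offs))) {
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      if (lev[i, j, k] == 0L) next
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3])
        next
      if (lev[ii, jj, kk] == 0L) next
      M[lev[i, j, k], lev[ii, jj, kk]] <- M[lev[i, j, k], lev[ii, jj, kk]] + 1
      M[lev[ii, jj, kk], lev[i, j, k]] <- M[lev[ii, jj, kk], lev[i, j, k]] + 1
    }
  }
  M / sum(M)
}

# feature-level phantom at the default study size, cached
phantom_300 <- function(seed = 5L) {
  cached(paste0("phantom_", seed), function()
    simulate_feature_table(test_gen_config(n_colonies_per_day = 50L),
                           seed = seed))
}
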