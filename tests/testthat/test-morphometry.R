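test_that("sphericity of an ideal sphere is exactly 1", {
  r <- 10
  V <- 4 / 3 * pi * r^3
  SA <- 4 * pi * r^2
  expect_equal(sphericity(V, SA), 1, tolerance = 1e-12)
  # the alternative printed form evaluates to 81^(-1/3) for the same sphere
  expect_equal(sphericity(V, SA, printed_formula = TRUE), 81^(-1 / 3),
               tolerance = 1e-12)
})

test_that("digital ball shape features match analytic values", {
  mk <- cached("ball20_features", function()
    colony_shape_features(ball_mask(20L)))
  expect_gte(mk$sphericity, 0.95)
  expect_lte(mk$sphericity, 1.02)
  expect_equal(mk$elongation, 1, tolerance = 0.02)
  expect_equal(mk$flatness, 1, tolerance = 0.02)
  expect_equal(mk$feret, 40, tolerance = 0.06 * 40)
  expect_equal(mk$min_feret, 40, tolerance = 0.06 * 40)
  expect_lte(mk$min_feret, mk$feret)
  expect_equal(mk$circularity, 1, tolerance = 0.02)
  expect_equal(mk$aspect_ratio, 1, tolerance = 0.02)
})

test_that("bounding ellipsoid recovers planted semi-axes within 3%", {
  mk <- ellipsoid_mask(40, 20, 10)
  ax <- bounding_ellipsoid_axes(mk)
  expect_equal(unname(ax[c("a", "b", "c")]), c(40, 20, 10), tolerance = 0.03)
  expect_equal(unname(ax["elongation"]), 0.5, tolerance = 0.03)
  expect_equal(unname(ax["flatness"]), 0.25, tolerance = 0.03)
  # flat disc limit
  disc <- ellipsoid_mask(20, 20, 1)
  expect_lt(bounding_ellipsoid_axes(disc)[["flatness"]], 0.1)
})

test_that("Feret diameters match a brute-force corner-pair oracle", {
  # thin 1 x 1 x 10-voxel rod
  d <- c(5, 5, 14)
  rod <- array(FALSE, d)
  rod[3, 3, 3:12] <- TRUE
  mk <- structure(list(mask = rod, spacing = c(1, 1, 1)),
                  class = "colony_mask")
  fer <- feret_diameters(mk)
  # oracle: max pairwise distance over all 8 corners of all voxels
  ind <- which(rod, arr.ind = TRUE)
  corners <- do.call(rbind, lapply(list(-0.5, 0.5), function(o1)
    do.call(rbind, lapply(list(-0.5, 0.5), function(o2)
      do.call(rbind, lapply(list(-0.5, 0.5), function(o3)
        sweep(ind, 2, -c(o1, o2, o3))))))))
  oracle <- max(dist(corners))
  expect_equal(unname(fer["feret"]), oracle, tolerance = 0.01)
  ell <- bounding_ellipsoid_axes(rod, c(1, 1, 1))
  expect_lt(ell[["elongation"]], 0.2)
})

test_that("Feret of the micropattern rectangle equals its diagonal", {
  # 29 x 116 um footprint, one voxel thick, 1 um spacing
  d <- c(31, 118, 3)
  rect <- array(FALSE, d)
  rect[2:30, 2:117, 2] <- TRUE
  mk <- structure(list(mask = rect, spacing = c(1, 1, 1)),
                  class = "colony_mask")
  fer <- feret_diameters(mk)
  diagonal <- sqrt(29^2 + 116^2)
  expect_equal(unname(fer["feret"]), diagonal, tolerance = 1 / diagonal)
  expect_lte(fer["min_feret"], fer["feret"])
})

test_that("min Feret never exceeds Feret on random blobs", {
  set.seed(3)
  for (i in 1:5) {
    a <- runif(1, 4, 12); b <- runif(1, 4, 12); c <- runif(1, 2, 8)
    fer <- feret_diameters(ellipsoid_mask(a, b, c))
    expect_lte(fer["min_feret"], fer["feret"] + 1e-9)
  }
})

test_that("heterochromatin thresholding follows mean + k * SD with strict cut", {
  d <- c(20, 20, 10)
  lab <- array(0L, d)
  lab[5:16, 5:16, 3:8] <- 1L
  labels <- labels_from_array(lab)
  # constant nucleus: SD = 0, strict inequality gives zero HC
  img_c <- image_from_array(array(500, d))
  hc_c <- heterochromatin_volume(img_c, labels)
  expect_equal(hc_c$hc_volume, 0)
  # threshold offset is exactly k * SD
  set.seed(1)
  arr <- array(rnorm(prod(d), 1000, 100), d)
  img_g <- image_from_array(arr)
  hc_g <- heterochromatin_volume(img_g, labels, k = 1.5)
  vals <- arr[lab == 1L]
  expect_equal(hc_g$threshold, mean(vals) + 1.5 * sd(vals), tolerance = 1e-12)
})

test_that("Gaussian-texture HC fraction matches the normal upper tail", {
  d <- c(40, 40, 20)
  lab <- array(1L, d)
  labels <- labels_from_array(lab)
  set.seed(7)
  img <- image_from_array(array(rnorm(prod(d), 1000, 100), d))
  n <- prod(d)
  for (k in c(1, 1.5, 2)) {
    hc <- heterochromatin_volume(img, labels, k = k)
    p <- pnorm(k, lower.tail = FALSE)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(hc$hc_fraction - p), 3 * se + 2e-3)
  }
})

test_that("a planted bright blob is recovered as heterochromatin", {
  d <- c(30, 30, 16)
  lab <- array(1L, d)
  co <- expand.grid(x = 1:30, y = 1:30, z = 1:16)
  blob <- (co$x - 15)^2 + (co$y - 15)^2 + (co$z - 8)^2 <= 16
  arr <- array(300, d)
  arr[cbind(co$x, co$y, co$z)[blob, ]] <- 3000
  set.seed(2)
  arr <- arr + array(rnorm(prod(d), 0, 30), d)
  hc <- heterochromatin_volume(image_from_array(arr), labels_from_array(lab))
  expect_equal(hc$hc_volume, sum(blob), tolerance = 0.15)
})

test_that("GLCM features equal the brute-force double-loop oracle", {
  d <- c(16, 16, 16)
  lab <- array(1L, d)
  set.seed(11)
  for (rep in 1:3) {
    arr <- array(runif(prod(d), 0, 1000), d)
    got <- glcm_texture(image_from_array(arr), labels_from_array(lab))
    P <- glcm_oracle(arr, array(TRUE, d))
    want <- glcm_features(P)
    expect_equal(got$texture_idm, unname(want["idm"]), tolerance = 1e-10)
    expect_equal(got$texture_entropy, unname(want["entropy"]),
                 tolerance = 1e-10)
    expect_equal(got$texture_correlation, unname(want["correlation"]),
                 tolerance = 1e-10)
    expect_equal(got$texture_contrast, unname(want["contrast"]),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and checkerboard textures take their known values", {
  d <- c(12, 12, 4)
  lab <- array(1L, d)
  flat <- glcm_texture(image_from_array(array(7, d)), labels_from_array(lab))
  expect_equal(flat$texture_idm, 1)
  expect_equal(flat$texture_entropy, 0)
  # 2-level checkerboard: frozen expectation computed with the oracle
  chk <- array(as.numeric((outer(1:12, 1:12, `+`)) %% 2), d)
  got <- glcm_texture(image_from_array(chk), labels_from_array(lab))
  want <- glcm_features(glcm_oracle(chk, array(TRUE, d)))
  expect_equal(got$texture_idm, unname(want["idm"]), tolerance = 1e-10)
  # in-plane unit offsets: axis pairs always differ, diagonals always match,
  # so IDM sits near 1/2 for the symmetric matrix
  expect_equal(got$texture_idm, 0.5, tolerance = 0.05)
})

test_that("protein summaries compute population-SD CV over nuclei", {
  d <- c(24, 10, 6)
  lab <- array(0L, d)
  lab[2:11, 2:9, 2:5] <- 1L
  lab[14:23, 2:9, 2:5] <- 2L
  labels <- labels_from_array(lab)
  arr <- array(0, d)
  arr[lab == 1L] <- 10
  arr[lab == 2L] <- 30
  img <- image_from_array(arr, channel = "oct4")
  ps <- protein_summaries(img, full_mask(d), labels, channels = "oct4",
                          nuclear_channels = "oct4")
  expect_equal(unname(ps$cv["oct4"]), 0.5)   # pop SD 10 / mean 20
  expect_equal(unname(ps$colony_means["oct4"]), 20)
  # identical nuclei: CV 0
  arr2 <- array(0, d); arr2[lab > 0L] <- 15
  ps2 <- protein_summaries(image_from_array(arr2, channel = "oct4"),
                           full_mask(d), labels, channels = "oct4",
                           nuclear_channels = "oct4")
  expect_equal(unname(ps2$cv["oct4"]), 0)
  # single nucleus: CV undefined, not zero
  lab1 <- array(0L, d); lab1[2:11, 2:9, 2:5] <- 1L
  ps1 <- protein_summaries(img, full_mask(d), labels_from_array(lab1),
                           channels = "oct4", nuclear_channels = "oct4")
  expect_true(is.na(ps1$cv["oct4"]))
})

test_that("voronoi proxy volumes partition the colony exactly", {
  d <- c(30, 14, 8)
  mask <- full_mask(d)
  lab <- array(0L, d)
  lab[4:9, 5:10, 3:6] <- 1L
  vor1 <- voronoi_cell_proxies(labels_from_array(lab), mask)
  expect_equal(vor1, prod(d))              # single nucleus takes it all
  lab[22:27, 5:10, 3:6] <- 2L              # symmetric pair
  vor2 <- voronoi_cell_proxies(labels_from_array(lab), mask)
  expect_equal(sum(vor2), prod(d))         # exact partition
  expect_lt(abs(vor2[1] - vor2[2]), 1 + 1e-9)
})

test_that("features scale correctly when voxel spacing doubles", {
  mk1 <- ball_mask(12L, spacing = c(1, 1, 1))
  mk2 <- ball_mask(12L, spacing = c(2, 2, 2))
  f1 <- colony_shape_features(mk1)
  f2 <- colony_shape_features(mk2)
  expect_equal(f2$volume / f1$volume, 8, tolerance = 1e-9)
  expect_equal(f2$surface_area / f1$surface_area, 4, tolerance = 0.02)
  expect_equal(f2$feret / f1$feret, 2, tolerance = 0.02)
  expect_equal(f2$major_radius / f1$major_radius, 2, tolerance = 0.02)
  expect_equal(f2$projected_area / f1$projected_area, 4, tolerance = 0.02)
})

test_that("in-plane 90-degree rotation barely moves shape descriptors", {
  mk <- ellipsoid_mask(14, 7, 4)
  rot <- structure(list(mask = aperm(mk$mask, c(2, 1, 3)),
                        spacing = c(1, 1, 1)),
                   class = "colony_mask")
  f1 <- colony_shape_features(mk)
  f2 <- colony_shape_features(rot)
  for (f in c("sphericity", "elongation", "flatness", "feret")) {
    expect_lt(abs(f2[[f]] - f1[[f]]) / f1[[f]], 0.01)
  }
})
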