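test_that("colony mask recovers a synthetic spheroid with IoU >= 0.9", {
  cfg <- test_gen_config()
  out <- generate_colony(cfg, 8L, "success", seed = 12L)
  mask <- segment_colony(out$image)
  env <- out$image$truth_masks$envelope
  iou <- sum(mask$mask & env) / sum(mask$mask | env)
  expect_gte(iou, 0.90)
})

test_that("degenerate colony images fail loudly", {
  img <- image_from_array(array(0, c(8, 8, 4)), channel = "actin")
  expect_error(segment_colony(img), "segmentation failure")
})

test_that("only the largest component is kept", {
  d <- c(40, 20, 10)
  arr <- array(0, d)
  arr[5:30, 5:16, 3:8] <- 1000      # big blob
  arr[35:37, 17:19, 3:4] <- 1000    # small distant blob
  img <- image_from_array(arr, channel = "actin")
  mask <- segment_colony(img, sigma_um = 0.5)
  expect_true(all(which(mask$mask, arr.ind = TRUE)[, 1] <= 32))
})

test_that("watershed separates two overlapping spheres at 1.2 radii", {
  d <- c(60, 40, 40)
  r <- 12
  co <- expand.grid(x = 1:60, y = 1:40, z = 1:40)
  c1 <- c(23, 20, 20); c2 <- c(23 + 1.2 * r, 20, 20)
  b1 <- (co$x - c1[1])^2 + (co$y - c1[2])^2 + (co$z - c1[3])^2 <= r^2
  b2 <- (co$x - c2[1])^2 + (co$y - c2[2])^2 + (co$z - c2[3])^2 <= r^2
  img <- image_from_array(array((b1 | b2) * 3000, d))
  lab <- segment_nuclei(img, full_mask(d), sigma_um = 0, threshold = 0.5)
  expect_equal(lab$n, 2L)
  # the dividing surface lies between the centers: voxels of each label are
  # closer to their own center (brute-force distance check)
  ind <- which(lab$labels > 0, arr.ind = TRUE)
  l <- lab$labels[lab$labels > 0]
  d1 <- sqrt(rowSums(sweep(ind, 2, c1)^2))
  d2 <- sqrt(rowSums(sweep(ind, 2, c2)^2))
  own <- ifelse(l == lab$labels[c1[1], c1[2], c1[3]], d1 < d2 + 1.5,
                d2 < d1 + 1.5)
  expect_gte(mean(own), 0.99)
})

test_that("a single sphere yields exactly one label", {
  d <- c(40, 40, 30)
  co <- expand.grid(x = 1:40, y = 1:40, z = 1:30)
  b <- (co$x - 20)^2 + (co$y - 20)^2 + (co$z - 15)^2 <= 100
  img <- image_from_array(array(b * 3000, d))
  lab <- segment_nuclei(img, full_mask(d), sigma_um = 0, threshold = 0.5)
  expect_equal(lab$n, 1L)
})

test_that("nuclei voxels always lie inside the colony mask", {
  cfg <- test_gen_config()
  out <- generate_colony(cfg, 6L, "success", seed = 21L)
  mask <- segment_colony(out$image)
  lab <- segment_nuclei(out$image, mask)
  expect_true(all(mask$mask[lab$labels > 0]))
})

test_that("watershed is idempotent on its own output foreground", {
  cfg <- test_gen_config()
  out <- generate_colony(cfg, 8L, "success", seed = 12L)
  mask <- segment_colony(out$image)
  lab <- segment_nuclei(out$image, mask)
  fg_img <- image_from_array((lab$labels > 0) * 1.0,
                             spacing = out$image$spacing)
  lab2 <- segment_nuclei(fg_img, full_mask(dim(lab$labels),
                                           out$image$spacing),
                         sigma_um = 0, threshold = 0.5)
  expect_equal(lab2$n, lab$n)
})

test_that("raising min_volume_um3 never increases the label count", {
  cfg <- test_gen_config()
  out <- generate_colony(cfg, 8L, "success", seed = 13L)
  mask <- segment_colony(out$image)
  counts <- vapply(c(10, 50, 120, 400), function(mv)
    segment_nuclei(out$image, mask, min_volume_um3 = mv)$n, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("physical volumes are resolution-invariant within 5%", {
  vol_at <- function(r_vox, spacing) {
    mk <- ball_mask(r_vox, spacing = spacing)
    sum(mk$mask) * prod(spacing)
  }
  v_coarse <- vol_at(10L, c(1, 1, 1))       # radius 10 um
  v_fine <- vol_at(20L, c(0.5, 0.5, 0.5))   # same radius, finer grid
  expect_lt(abs(v_fine - v_coarse) / v_coarse, 0.05)
})

test_that("EdU classification follows the at-least-one-positive-nucleus rule", {
  d <- c(30, 12, 8)
  lab <- array(0L, d)
  lab[3:8, 4:9, 3:6] <- 1L
  lab[13:18, 4:9, 3:6] <- 2L
  lab[23:28, 4:9, 3:6] <- 3L
  labels <- labels_from_array(lab)
  # all-zero EdU channel: quiescent via the fallback threshold
  img0 <- image_from_array(array(0, d), channel = "edu")
  res0 <- classify_edu(img0, labels)
  expect_false(res0$proliferating)
  expect_true(res0$used_fallback)
  # one bright nucleus among dim ones: proliferating
  edu <- array(100, d)
  edu[lab == 2L] <- 5000
  res1 <- classify_edu(image_from_array(edu, channel = "edu"), labels)
  expect_true(res1$proliferating)
  expect_equal(which(res1$nucleus_positive), 2L)
})

test_that("batch EdU threshold recovers a planted proliferating fraction", {
  # per-nucleus means drawn from a planted bimodal mixture across colonies
  set.seed(42)
  n_col <- 120L
  prolif <- runif(n_col) < 0.6
  means <- lapply(seq_len(n_col), function(i) {
    n_nuc <- sample(2:6, 1)
    base <- rnorm(n_nuc, 300, 80)
    if (prolif[i]) base[sample(n_nuc, 1)] <- rnorm(1, 5000, 300)
    pmax(base, 0)
  })
  bt <- edu_batch_threshold(unlist(means))
  called <- vapply(means, function(m) any(m > bt$threshold), logical(1))
  p <- mean(prolif)
  expect_lt(abs(mean(called) - p), 3 * sqrt(p * (1 - p) / n_col))
})
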