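# small reference embedding shared across blocks
traj_fixture <- function() {
  cached("traj_fixture", function() {
    tab <- phantom_300()
    fit <- tab[tab$day <= 8, ]
    emb <- build_diffusion_map(fit, features = morphology_features(fit),
                               kernel_sigma = "auto")
    pt <- compute_pseudotime(emb, root = "auto", days = fit$day)
    br <- detect_branches(emb, metadata = fit, seed = 1L)
    list(tab = tab, fit = fit, emb = emb, pt = pt, br = br)
  })
}

test_that("the diffusion operator is a valid normalized Markov kernel", {
  fx <- traj_fixture()
  emb <- fx$emb
  # reconstruct the density-normalized kernel from stored reference pieces
  D2 <- as.matrix(dist(emb$ref_pc))^2
  K <- exp(-D2 / (2 * emb$kernel_sigma^2))
  K1 <- K / outer(emb$ref_q, emb$ref_q)
  P <- K1 / rowSums(K1)
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  expect_true(all(emb$eigenvalues <= 1 + 1e-9))
  expect_true(all(diff(emb$eigenvalues) <= 1e-12))
  expect_equal(emb$lambda0, 1, tolerance = 1e-9)
})

test_that("the first nontrivial eigenvector bisects two separated blobs", {
  set.seed(4)
  n <- 60L
  blob <- rep(c(0, 1), each = n / 2)
  tab <- data.frame(volume = rnorm(n, 100 + 400 * blob, 5),
                    elongation = rnorm(n, 0.3 + 0.5 * blob, 0.02),
                    feret = rnorm(n, 50 - 30 * blob, 1),
                    day = rep(c(0, 8), each = n / 2))
  emb <- build_diffusion_map(tab, features = c("volume", "elongation",
                                               "feret"),
                             n_pc = 3L, kernel_sigma = "auto")
  side <- emb$psi[, 1] > 0
  purity <- max(mean(side == (blob == 1)), mean(side == (blob == 0)))
  expect_equal(purity, 1.0)
})

test_that("embedding eigenvalues match an independent dense eigendecomposition", {
  set.seed(9)
  n <- 50L
  tab <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                    day = sample(0:5, n, TRUE))
  emb <- build_diffusion_map(tab, features = c("a", "b", "c"), n_pc = 3L,
                             kernel_sigma = 1.2, n_components = 10L)
  # oracle: independent reimplementation of the alpha = 1 normalization
  Z <- scale(as.matrix(tab[, c("a", "b", "c")]))
  Y <- prcomp(Z, center = FALSE)$x[, 1:3]
  D2 <- as.matrix(dist(Y))^2
  K <- exp(-D2 / (2 * 1.2^2))
  q <- rowSums(K)
  K1 <- K / outer(q, q)
  dg <- rowSums(K1)
  A <- K1 / outer(sqrt(dg), sqrt(dg))
  lam <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  expect_equal(emb$eigenvalues, lam[2:11], tolerance = 1e-8)
})

test_that("pseudotime is anchored at the root and tracks planted progression", {
  fx <- traj_fixture()
  pt <- fx$pt
  expect_equal(pt$pseudotime[pt$root_index], 0)
  expect_equal(max(pt$pseudotime), 1)
  expect_gte(spearman(pt$pseudotime, fx$fit$progression_s), 0.8)
  # rooting at the far end reverses the ordering
  far <- fx$emb$reference_rows[which.max(pt$pseudotime)]
  pt_rev <- compute_pseudotime(fx$emb, root = far)
  expect_lte(spearman(pt_rev$pseudotime, fx$fit$progression_s), -0.8)
})

test_that("branch detection recovers planted branches and is deterministic", {
  fx <- traj_fixture()
  expect_gte(adjusted_rand_index(fx$br$branch, fx$fit$branch_expressed),
             0.7)
  br2 <- detect_branches(fx$emb, metadata = fx$fit, seed = 1L)
  expect_identical(fx$br$branch, br2$branch)
  # k != 3 returns unnamed generic clusters
  br4 <- detect_branches(fx$emb, metadata = fx$fit, k = 4L, seed = 1L)
  expect_false(br4$named)
  expect_true(all(grepl("^cluster_", br4$branch)))
})

test_that("branch fractions are proper compositions with rising success", {
  fx <- traj_fixture()
  fr <- branch_fractions(fx$br$branch, fx$fit, group_by = "day")
  sums <- rowSums(fr[, setdiff(names(fr), "day")])
  expect_equal(sums, rep(1, nrow(fr)), tolerance = 1e-9)
  expect_true(all(diff(fr$success) >= -1e-9))
  expect_gt(fr$success[nrow(fr)], fr$success[1])
  # single-branch input
  fr1 <- branch_fractions(rep("success", 10),
                          data.frame(day = rep(c(0, 2), 5)))
  expect_equal(fr1$success, c(1, 1))
})

test_that("Nystrom projection is self-consistent and extends to new colonies", {
  fx <- traj_fixture()
  proj <- project_new_colonies(fx$emb, fx$fit, branch_fit = fx$br,
                               pseudotime_fit = fx$pt)
  expect_lt(max(abs(proj$coords - fx$emb$coords)), 1e-6)
  expect_identical(proj$branch, fx$br$branch)
  expect_lt(max(abs(proj$pseudotime - fx$pt$pseudotime)), 1e-6)
  # a duplicated reference row lands on the same branch
  dup <- fx$fit[7, ]
  pd <- project_new_colonies(fx$emb, dup, branch_fit = fx$br)
  expect_equal(pd$branch, fx$br$branch[7])
  # held-out day-10 colonies from the success archetype project to success
  d10 <- fx$tab[fx$tab$day == 10 & fx$tab$branch_expressed == "success", ]
  p10 <- project_new_colonies(fx$emb, d10, branch_fit = fx$br,
                              pseudotime_fit = fx$pt)
  expect_gte(mean(p10$branch == "success"), 0.8)
  expect_error(project_new_colonies(fx$emb, fx$fit[, 1:3]), "schema")
})

test_that("row permutation permutes the embedding outputs identically", {
  set.seed(13)
  tab <- phantom_300()[sample(300, 80), ]
  feats <- morphology_features(tab)
  emb1 <- build_diffusion_map(tab, features = feats, kernel_sigma = "auto")
  perm <- sample(nrow(tab))
  emb2 <- build_diffusion_map(tab[perm, ], features = feats,
                              kernel_sigma = "auto")
  expect_equal(emb2$coords, emb1$coords[perm, ], tolerance = 1e-6)
})
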