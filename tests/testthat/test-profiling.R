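test_that("correlation distance matches hand-computed Pearson values", {
  x <- c(1, 2, 3)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x), 2)
  # r([1,2,3],[1,2,4]) = 0.981981, d = 0.018019
  expect_lt(abs(correlation_distance(c(1, 2, 3), c(1, 2, 4)) - 0.0180), 1e-4)
  expect_error(correlation_distance(c(1, 1, 1), x), "zero-variance")
})

test_that("distance matrix reproduces the double-loop oracle on 20 wells", {
  set.seed(11)
  x <- matrix(rnorm(20 * 15), 20, 15)
  p <- make_profiles(x)
  d <- distance_matrix(p)
  expect_equal(unname(d), brute_distance_matrix(x), tolerance = 1e-12)
  expect_true(all(d >= 0 - 1e-12 & d <= 2 + 1e-12))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 20))
})

test_that("complete-linkage heights equal brute-force max pairwise distance", {
  set.seed(12)
  x <- matrix(rnorm(8 * 10), 8, 10)
  d <- distance_matrix(make_profiles(x))
  tree <- cluster_wells(d)
  # recompute each merge height as the max pairwise distance between clusters
  members <- lapply(seq_len(8), identity)
  for (step in seq_len(nrow(tree$merge))) {
    get <- function(k) if (k < 0) members[[-k]] else members[[8 + k]]
    a <- get(tree$merge[step, 1])
    b <- get(tree$merge[step, 2])
    expect_equal(tree$height[step], max(d[a, b]), tolerance = 1e-12)
    members[[8 + step]] <- c(a, b)
  }
  expect_true(all(diff(tree$height) >= -1e-12))
})

test_that("clustering recovers planted clusters and is order-invariant", {
  set.seed(16)
  base1 <- rnorm(10)
  base2 <- rnorm(10)
  x <- rbind(base1 + rnorm(10, 0, 0.01), base1 + rnorm(10, 0, 0.01),
             base2 + rnorm(10, 0, 0.01), base2 + rnorm(10, 0, 0.01))
  d <- distance_matrix(make_profiles(x))
  tree <- cluster_wells(d)
  top <- unname(cutree(tree, k = 2))
  expect_equal(top[1], top[2])
  expect_equal(top[3], top[4])
  expect_false(top[1] == top[3])
  # identical pair merges first at ~0 height; brute check over 2-partitions:
  # every other split has a larger maximum within-cluster distance
  expect_lt(tree$height[1], 0.01)

  perm <- c(3, 1, 4, 2)
  tree_p <- cluster_wells(distance_matrix(make_profiles(x[perm, ])))
  top_p <- cutree(tree_p, k = 2)[order(perm)]
  expect_equal(unname(top_p == top_p[1]), unname(top == top[1]))
  expect_equal(sort(tree$height), sort(tree_p$height), tolerance = 1e-12)
  expect_error(cluster_wells(d[1, 1, drop = FALSE]), "at least 2")
})

test_that("uniformity scores match fixtures and are group-permutation invariant", {
  # three identical like-treated wells: mean like distance 0, uniformity 1
  x <- matrix(rep(c(1, 2, 3, 1), each = 3), nrow = 3)
  p <- make_profiles(x, treatment = "drugA", concentration = 1)
  u <- uniformity_scores(distance_matrix(p), p)
  expect_equal(u$mean_like_distance, rep(0, 3))
  expect_equal(u$uniformity, rep(1, 3))

  # group {x, -x}: both wells at distance 2, uniformity -1
  y <- rbind(c(1, 2, 3, 0), -c(1, 2, 3, 0))
  p2 <- make_profiles(y, treatment = "drugA", concentration = 1)
  u2 <- uniformity_scores(distance_matrix(p2), p2)
  expect_equal(u2$mean_like_distance, c(2, 2))
  expect_equal(u2$uniformity, c(-1, -1))

  # permuting wells within a group leaves the multiset of scores unchanged
  set.seed(13)
  z <- matrix(rnorm(5 * 8), 5, 8)
  p3 <- make_profiles(z, treatment = "drugA", concentration = 1)
  u3 <- uniformity_scores(distance_matrix(p3), p3)
  perm <- sample(5)
  p4 <- make_profiles(z[perm, ], treatment = "drugA", concentration = 1)
  u4 <- uniformity_scores(distance_matrix(p4), p4)
  expect_equal(sort(u3$mean_like_distance), sort(u4$mean_like_distance),
               tolerance = 1e-12)

  # singleton groups are omitted and reported
  p5 <- make_profiles(z, treatment = c(rep("drugA", 4), "drugB"),
                      concentration = 1)
  u5 <- uniformity_scores(distance_matrix(p5), p5)
  expect_equal(nrow(u5), 4)
  expect_equal(attr(u5, "omitted"), "P1:W005")
})

test_that("PCA trajectories order centroids by dose with vehicle at 0", {
  set.seed(14)
  n_feat <- 12
  load_vec <- rnorm(n_feat)
  doses <- c(0.1, 1, 10)
  rows <- list(make_profiles(matrix(rnorm(4 * n_feat, sd = 0.1), 4, n_feat)))
  for (i in seq_along(doses)) {
    shift <- i * 2 # monotone planted shift along load_vec
    x <- matrix(rnorm(4 * n_feat, sd = 0.1), 4, n_feat) +
      rep(shift * load_vec / sqrt(sum(load_vec^2)), each = 4)
    rows[[i + 1]] <- make_profiles(x, treatment = "drugA",
                                   concentration = doses[i])
  }
  p <- do.call(rbind, rows)
  p$Metadata_well <- sprintf("W%03d", seq_len(nrow(p)))
  out <- pca_trajectories(p)
  path <- out$paths[out$paths$treatment == "drugA", ]
  expect_equal(path$concentration, c(0, doses))
  # centroid path is monotone in projection onto the planted direction:
  # reconstruct projections from the embedding
  emb <- out$embedding
  centroids <- sapply(c(0, doses), function(cc) {
    idx <- if (cc == 0) emb$Metadata_treatment == "DMSO" else
      emb$Metadata_concentration == cc
    colMeans(as.matrix(p[idx, feature_columns(p)])) %*% load_vec
  })
  expect_true(all(diff(as.numeric(centroids)) > 0))

  # feature-order permutation leaves PC scores unchanged up to sign
  perm <- sample(n_feat)
  p_perm <- p[, c(metadata_columns(p), feature_columns(p)[perm])]
  out2 <- pca_trajectories(p_perm)
  for (pc in c("PC1", "PC2")) {
    agree <- max(abs(out2$embedding[[pc]] - out$embedding[[pc]]),
                 abs(out2$embedding[[pc]] + out$embedding[[pc]]))
    expect_equal(min(max(abs(out2$embedding[[pc]] - out$embedding[[pc]])),
                     max(abs(out2$embedding[[pc]] + out$embedding[[pc]]))),
                 0, tolerance = 1e-8)
  }
  expect_error(pca_trajectories(p[1, , drop = FALSE], n_components = 2),
               "fewer wells")
})

test_that("null profiles keep group centroids near the vehicle centroid", {
  set.seed(15)
  cfg <- synthetic_config(seed = 15, effect_size = 0, n_features = 30,
                          n_replicate_wells = 6, outlier_well_rate = 0)
  prof <- generate_feature_matrix(cfg)$profiles
  norm <- normalize_to_control(prof)$profiles
  out <- pca_trajectories(norm)
  veh <- out$embedding[out$embedding$Metadata_treatment == "DMSO", ]
  veh_c <- colMeans(veh[, c("PC1", "PC2")])
  spread <- sqrt(mean(rowSums(sweep(as.matrix(
    out$embedding[, c("PC1", "PC2")]), 2, veh_c)^2)))
  for (i in seq_len(nrow(out$paths))) {
    gap <- sqrt(sum((unlist(out$paths[i, c("PC1", "PC2")]) - veh_c)^2))
    expect_lt(gap, 2 * spread) # centroids within sampling noise of vehicle
  }
})
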