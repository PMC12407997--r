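test_that("partial Hausdorff matches hand and brute-force oracles", {
  full <- cbind(c(0, 1, 5), 0)
  expect_equal(partial_hausdorff(full, full[1, , drop = FALSE], q = 1), 5)
  expect_equal(partial_hausdorff(full, full[1, , drop = FALSE], q = 0.5), 1)
  expect_equal(partial_hausdorff(full, full), 0)
  expect_error(partial_hausdorff(full, full[0, , drop = FALSE]), "at least one")

  set.seed(13)
  pts <- matrix(rnorm(500 * 3), 500, 3)
  sk <- pts[sample(500, 40), ]
  for (q in c(1, 0.99, 0.5, 0.1)) {
    expect_equal(partial_hausdorff(pts, sk, q), brute_hausdorff(pts, sk, q),
                 tolerance = 1e-9)
  }
})

test_that("partial Hausdorff is monotone in q and under sketch growth", {
  set.seed(14)
  pts <- matrix(runif(400), 200, 2)
  s1 <- sample(200, 10)
  s2 <- c(s1, sample(setdiff(1:200, s1), 15))
  qs <- c(0.1, 0.3, 0.5, 0.9, 1)
  v1 <- sapply(qs, function(q) partial_hausdorff(pts, pts[s1, ], q))
  expect_true(!is.unsorted(v1))
  for (q in qs) {
    expect_lte(partial_hausdorff(pts, pts[s2, ], q),
               partial_hausdorff(pts, pts[s1, ], q))
  }
})

test_that("adjusted Rand index matches pair-counting oracles", {
  a <- c(1, 1, 2, 2)
  b <- c(1, 2, 1, 2)
  expect_equal(adjusted_rand_index(a, b), brute_ari(a, b))

  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c(3, 3, 1, 1, 2)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")

  # exhaustive check over all partition pairs of small sets
  for (n in c(4, 5)) {
    parts <- all_partitions(n)
    for (i in seq_along(parts)) {
      for (j in seq(i, length(parts))) {
        got <- adjusted_rand_index(parts[[i]], parts[[j]])
        expect_equal(got, brute_ari(parts[[i]], parts[[j]]), tolerance = 1e-12)
        expect_equal(got, adjusted_rand_index(parts[[j]], parts[[i]]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("adjusted Rand index agrees with the mclust reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(15)
  for (trial in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("graph clustering separates well-separated Gaussian blobs", {
  set.seed(16)
  blobs <- rbind(matrix(rnorm(200, 0, 1), 100, 2),
                 matrix(rnorm(200, 40, 1), 100, 2))
  truth <- rep(1:2, each = 100)
  # coarse resolution asks for the macro structure: exactly the two blobs
  cl <- cluster_for_ari(blobs, resolution = 0.1, seed = 3)
  expect_equal(length(unique(cl)), 2)
  expect_equal(adjusted_rand_index(cl, truth), 1)
  expect_identical(cl, cluster_for_ari(blobs, resolution = 0.1, seed = 3))
  # at any resolution, no cluster ever straddles the two blobs
  fine <- cluster_for_ari(blobs, resolution = 1, seed = 3)
  expect_true(all(rowSums(table(fine, truth) > 0) == 1))
  expect_error(cluster_for_ari(blobs[1, , drop = FALSE]), "at least two")
})

test_that("PCA projection difference vanishes when the subspace is preserved", {
  X <- rand_matrix(60, 12, seed = 18)
  full <- pca_embedding(X, d = 4, seed = 1)
  expect_lt(pca_projection_difference(full$loadings, full$center, X, d = 4,
                                      seed = 2), 1e-6)

  # a sketch with the same second-moment structure (every row duplicated)
  # learns the same components, so the drift vanishes
  Xlow <- rand_matrix(80, 3, seed = 19) %*% rand_matrix(3, 10, seed = 20)
  fl <- pca_embedding(Xlow, d = 3, seed = 1)
  dup <- rbind(Xlow, Xlow)
  expect_lt(pca_projection_difference(fl$loadings, fl$center, dup, d = 3,
                                      seed = 2), 1e-6)
  expect_error(pca_projection_difference(fl$loadings, fl$center,
                                         Xlow[1:3, ], d = 3), "insufficient")
})

test_that("PCA projection difference shrinks with sketch size on isotropic data", {
  set.seed(21)
  X <- matrix(rnorm(400 * 10), 400, 10)
  full <- pca_embedding(X, d = 3, seed = 1)
  vals <- sapply(1:20, function(s) {
    set.seed(s)
    big <- X[sample(400, 200), ]
    small <- X[sample(400, 20), ]
    c(big = pca_projection_difference(full$loadings, full$center, big, 3, seed = s),
      small = pca_projection_difference(full$loadings, full$center, small, 3, seed = s))
  })
  expect_lte(mean(vals["big", ]), mean(vals["small", ]))
})

test_that("neighbourhood composition matches a hand enumeration and normalizes", {
  coords <- cbind(c(0, 1, 2, 10, 11, 12), 0)
  labels <- factor(c("A", "A", "B", "B", "B", "A"))
  comp <- neighborhood_composition(coords, labels, query_points = c(1, 4), k = 3)
  # cell 1 at x=0: neighbours x=1 (A), x=2 (B), x=10 (B)
  expect_equal(comp[1, ], c(A = 1 / 3, B = 2 / 3))
  # cell 4 at x=10: neighbours x=11 (B), x=12 (A), x=2 (B)
  expect_equal(comp[2, ], c(A = 1 / 3, B = 2 / 3))
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))

  mono <- neighborhood_composition(coords, factor(rep("A", 6)), 1:6, k = 2)
  expect_true(all(mono[, "A"] == 1))
  expect_error(neighborhood_composition(coords, labels, 1, k = 6), "smaller")
})

test_that("neighbourhood MSE is zero for faithful sketches and bounded by 2", {
  d <- small_stripe_dataset()
  n <- nrow(d$counts)
  full <- structure(list(indices = seq_len(n)), class = "st_sketch")
  expect_equal(neighborhood_mse(d, full, k = 10), 0)

  mono <- st_dataset(d$counts, d$coords, labels = rep("A", n))
  sk <- uniform_sketch(n, 0.2, seed = 2)
  expect_equal(neighborhood_mse(mono, sk, k = 10), 0)

  vals <- sapply(1:5, function(s)
    neighborhood_mse(d, uniform_sketch(n, 0.1, seed = s), k = 10))
  expect_true(all(vals >= 0 & vals <= 2))
  expect_error(neighborhood_mse(d, uniform_sketch(n, 0.01, seed = 1), k = 10),
               "more than")
})

test_that("uniform sketches distort mixed neighbourhoods less than type-biased ones", {
  # over-sampling one cell type inside locally mixed neighbourhoods skews
  # every within-sketch composition toward that type, while uniform sampling
  # only adds noise
  coords <- generate_coordinates("random", 800, seed = 31)
  lab <- assign_domain_labels(coords, "stripes", 6)
  set.seed(99)
  mix <- runif(800) < 0.3
  lab[mix] <- sample(LETTERS[1:6], sum(mix), replace = TRUE)
  d <- st_dataset(matrix(1, 800, 2), coords, labels = lab)
  w <- ifelse(lab == "A", 6, 1) # 6x over-sampling of type A
  k <- 80
  unif_mse <- conc_mse <- numeric(20)
  for (s in 1:20) {
    biased <- structure(list(indices = probability_sample(w, k, seed = s)),
                        class = "st_sketch")
    conc_mse[s] <- neighborhood_mse(d, biased, k = 10)
    unif_mse[s] <- neighborhood_mse(d, uniform_sketch(800, 0.1, seed = s), k = 10)
  }
  expect_lt(mean(unif_mse), mean(conc_mse))
  expect_gte(sum(unif_mse < conc_mse), 15)
})

test_that("rank-sum scoring follows forced rankings and tie-averaging", {
  rec1 <- expand.grid(method = "uniform", representation = "index",
                      fraction = 0.1, replicate = 1,
                      metric = c("ari", "hausdorff_coord", "neighborhood_mse"),
                      stringsAsFactors = FALSE)
  rec1$value <- c(0.5, 1, 0.1)
  rt1 <- rank_sum_score(rec1)
  expect_equal(rt1$overall_spatial_score, 3)

  # one condition dominating all three metrics
  rec2 <- rbind(
    data.frame(method = "a", representation = "pca", fraction = 0.1, replicate = 1,
               metric = c("ari", "hausdorff_coord", "neighborhood_mse"),
               value = c(0.9, 1, 0.01)),
    data.frame(method = "b", representation = "pca", fraction = 0.1, replicate = 1,
               metric = c("ari", "hausdorff_coord", "neighborhood_mse"),
               value = c(0.4, 2, 0.10)))
  rt2 <- rank_sum_score(rec2)
  expect_equal(rt2$overall_spatial_score[rt2$method == "a"], 3)
  expect_equal(rt2$overall_spatial_score[rt2$method == "b"], 6)

  # two-way tie on one metric -> average ranks of 1.5
  rec3 <- do.call(rbind, lapply(c("a", "b", "c"), function(m) {
    data.frame(method = m, representation = "pca", fraction = 0.1, replicate = 1,
               metric = c("ari", "hausdorff_coord", "neighborhood_mse"),
               value = c(ifelse(m == "c", 0.1, 0.8),
                         match(m, c("a", "b", "c")),
                         match(m, c("a", "b", "c")) / 10))
  }))
  rt3 <- rank_sum_score(rec3)
  expect_equal(rt3$rank_ari[rt3$method == "a"], 1.5)
  expect_equal(rt3$rank_ari[rt3$method == "b"], 1.5)
  expect_equal(rt3$rank_ari[rt3$method == "c"], 3)
  expect_equal(rt3$overall_spatial_score[rt3$method == "a"], 1.5 + 1 + 1)
  expect_equal(rt3$overall_spatial_score[rt3$method == "b"], 1.5 + 2 + 2)

  # without ties the per-metric ranks sum to m(m+1)/2
  expect_equal(sum(rt3$rank_hausdorff_coord), 6)
  expect_equal(sum(rt2$rank_ari) + sum(rt2$rank_hausdorff_coord) +
                 sum(rt2$rank_neighborhood_mse), 3 * 3)
  expect_error(rank_sum_score(rec1[rec1$metric != "ari", ]), "missing")
})
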