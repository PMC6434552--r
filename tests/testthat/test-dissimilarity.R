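test_that("bray-curtis: endpoints, hand value, conventions, zero-column invariance", {
  Y <- rbind(a = c(1, 2), b = c(3, 0))
  D <- bray_curtis(Y, transform = "none")
  expect_equal(D["a", "b"], 4 / 6)
  expect_equal(diag(unclass(D)), c(a = 0, b = 0))
  Yid <- rbind(c(2, 5, 1), c(2, 5, 1))
  expect_equal(max(bray_curtis(Yid, "none")), 0)
  Ydis <- rbind(c(3, 0, 1), c(0, 4, 0))
  expect_equal(bray_curtis(Ydis, "none")[1, 2], 1)
  # pair of all-zero rows -> 0 by convention, logged
  Yz <- rbind(c(0, 0), c(0, 0), c(1, 2))
  Dz <- bray_curtis(Yz, "none")
  expect_equal(Dz[1, 2], 0)
  expect_identical(attr(Dz, "zero_pairs"), 1L)
  # appending an all-zero species changes nothing
  Y2 <- cbind(Y, 0)
  expect_equal(unclass(bray_curtis(Y2, "sqrt")), unclass(bray_curtis(Y, "sqrt")),
               ignore_attr = TRUE)
  expect_true(all(unclass(D) >= 0 & unclass(D) <= 1))
  expect_error(bray_curtis(rbind(c(-1, 2), c(1, 1))), "non-negative")
  # sqrt transform really is applied
  expect_equal(bray_curtis(Y, "sqrt")[1, 2],
               sum(abs(sqrt(Y[1, ]) - sqrt(Y[2, ]))) / sum(sqrt(Y)))
})

test_that("centroid distances from D match coordinate-space centroids for Euclidean D", {
  set.seed(13)
  X <- matrix(rnorm(60), 20, 3)
  grp <- factor(rep(1:3, c(5, 8, 7)))
  D <- dissimilarity_matrix(as.matrix(dist(X)), measure = "euclidean")
  cd <- centroid_distances(D, grp)
  cents <- apply(X, 2, tapply, grp, mean)
  expect_equal(unclass(cd), as.matrix(dist(cents)), tolerance = 1e-10,
               ignore_attr = TRUE)
  # singleton groups return the original dissimilarities
  single <- factor(seq_len(5))
  D5 <- dissimilarity_matrix(as.matrix(dist(X[1:5, ])))
  expect_equal(unclass(centroid_distances(D5, single)), unclass(D5),
               ignore_attr = TRUE)
  # a one-group partition gives a 1x1 zero matrix
  one <- centroid_distances(D, factor(rep("a", 20)))
  expect_identical(dim(unclass(one)), c(1L, 1L))
  expect_equal(unclass(one)[1, 1], 0)
  # duplicated groups (same member rows) have coincident centroids
  Xd <- rbind(X[1:4, ], X[1:4, ])
  Dd <- dissimilarity_matrix(as.matrix(dist(Xd)))
  cdd <- centroid_distances(Dd, factor(rep(c("u", "v"), each = 4)))
  expect_lt(cdd["u", "v"], 1e-10)
  expect_error(centroid_distances(D, factor(rep(1, 5))), "one label per row")
})

test_that("pcoa recovers Euclidean rank, centers exactly, and keeps negative eigenvalues", {
  set.seed(5)
  X <- matrix(rnorm(36), 12, 3)
  pc <- pcoa(dissimilarity_matrix(as.matrix(dist(X))))
  expect_identical(sum(pc$values > max(pc$values) * 1e-9), 3L)
  expect_lt(max(abs(pc$values[4:12])), 1e-8)
  expect_equal(unname(as.matrix(dist(pc$points))), as.matrix(dist(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # Bray-Curtis on random counts is semi-metric: negative eigenvalues appear
  Y <- null_counts(15, 8)
  pb <- pcoa(bray_curtis(Y))
  expect_lt(min(pb$values), -1e-8)
  # double-centering: the Gower matrix reconstructed from all axes has zero row sums
  G <- pb$vectors %*% diag(pb$values) %*% t(pb$vectors)
  expect_lt(max(abs(rowSums(G))), 1e-8)
  D2 <- unclass(bray_curtis(Y))^2
  n <- nrow(D2); J <- diag(n) - 1 / n
  expect_equal(G, J %*% (-0.5 * D2) %*% J, tolerance = 1e-8)
})

test_that("mds: exact configurations embed with ~zero stress and stress shrinks with dimension", {
  set.seed(2)
  X <- matrix(rnorm(40), 20, 2)
  D <- dissimilarity_matrix(as.matrix(dist(X)), measure = "euclidean")
  f <- mds(D, 2, "metric", seed = 1, n_starts = 3)
  expect_lt(f$stress, 1e-6)
  Y <- null_counts(16, 10)
  Db <- bray_curtis(Y)
  s <- vapply(1:3, function(k) mds(Db, k, "metric", seed = 4, n_starts = 3)$stress,
              numeric(1))
  expect_true(all(diff(s) <= 1e-8))
  fn <- mds(Db, 2, "nonmetric", seed = 4, n_starts = 3)
  expect_true(fn$stress >= 0)
  expect_error(mds(Db, 0), "n_dim")
})

test_that("centroid clouds contain the observed centroids and overlap under a true null", {
  dat <- generate_community(tiny_spec(88))
  # H_A clouds from the ground-truth model: each observed centroid falls
  # inside the convex hull of its own group's simulated centroids
  cl <- centroid_cloud_pipeline(dat$Y, dat$groups, dat$model, N_sim = 40,
                                include_null = TRUE, seed = 31)
  co <- cl$coordinates
  expect_identical(sum(co$source == "observed"), 3L)
  expect_identical(sum(co$source == "simulated_HA"), 120L)
  for (g in levels(dat$groups)) {
    obs <- unlist(co[co$source == "observed" & co$group == g,
                     c("axis1", "axis2")])
    sim <- as.matrix(co[co$source == "simulated_HA" & co$group == g,
                        c("axis1", "axis2")])
    expect_true(in_hull_2d(obs, sim))
  }
  expect_true(is.finite(cl$stress))
  expect_true(length(cl$densities) > 0)
  # N_sim = 0 keeps only the observed centroids
  cl0 <- centroid_cloud_pipeline(dat$Y, dat$groups, dat$model, N_sim = 0,
                                 seed = 1)
  expect_identical(nrow(cl0$coordinates), 3L)
  # null-true data: per-group H0 permutation clouds share a common region
  pooled_gm <- dat$model$groups[[1]]
  Yn <- simulate_counts(pooled_gm, 30, seed = 9)
  mod_null <- community_model(list(g1 = pooled_gm, g2 = pooled_gm,
                                   g3 = pooled_gm), c(10, 10, 10),
                              dat$model$species)
  cln <- centroid_cloud_pipeline(Yn, dat$groups, mod_null, N_sim = 40,
                                 include_null = TRUE, seed = 7)
  h0 <- cln$coordinates[cln$coordinates$source == "simulated_H0", ]
  boxes <- lapply(split(h0, h0$group), function(d)
    c(range(d$axis1), range(d$axis2)))
  for (i in 1:2) for (j in (i + 1):3) {
    bi <- boxes[[i]]; bj <- boxes[[j]]
    expect_true(bi[1] <= bj[2] && bj[1] <= bi[2])   # axis-1 overlap
    expect_true(bi[3] <= bj[4] && bj[3] <= bi[4])   # axis-2 overlap
  }
})
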