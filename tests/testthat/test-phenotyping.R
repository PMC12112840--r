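test_that("standardization gives zero-mean unit-SD columns and inverts", {
  expect_equal(unname(standardize(cbind(v = c(1, 2, 3)))$Z[, 1]),
               c(-1, 0, 1))
  sim <- simulate_cohort(table1_config(seed = 2))
  std <- standardize(sim$parameters)
  expect_true(all(abs(colMeans(std$Z)) < 1e-10))
  expect_equal(unname(apply(std$Z, 2, sd)), rep(1, 4))
  expect_equal(unstandardize(std$Z, std$scaler),
               as.matrix(sim$parameters), tolerance = 1e-12)
  const <- cbind(sva = c(1, 1, 1), lordosis_deg = c(1, 2, 3))
  expect_error(standardize(const), "sva")
})

test_that("PCA retains variance structure and reconstructs losslessly", {
  # points on a line: one component explains everything
  t <- seq(-2, 2, length.out = 50)
  line <- cbind(t, 2 * t) + 0
  p1 <- pca_fit_transform(scale(line))
  expect_gt(p1$explained_ratio[1], 0.999)

  std <- standardize(simulate_cohort(table1_config(seed = 3))$parameters)
  p <- pca_fit_transform(std$Z)
  expect_true(all(diff(p$explained_ratio) <= 1e-12))
  expect_lte(sum(p$explained_ratio), 1 + 1e-9)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # scores have diagonal covariance
  cv <- cov(p$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-9, ignore_attr = TRUE)
  # full reconstruction
  expect_equal(p$scores %*% t(p$loadings), std$Z, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_fit_transform(std$Z, n_components = 5), "exceeds")
  # variance_threshold retains the smallest sufficient number
  pt <- pca_fit_transform(std$Z, variance_threshold = p$cumulative_ratio[2])
  expect_identical(pt$n_retained, 2L)
})

test_that("k-means handles canonical limits and is seed-deterministic", {
  pairs <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  m2 <- kmeans_fit(pairs, 2, seed = 1)
  expect_identical(sort(tabulate(m2$labels)), c(2L, 2L))
  expect_identical(m2$labels[1], m2$labels[2])
  expect_equal(m2$wcss, 2 * (0.05^2 + 0.05^2))  # within-pair variances

  m1 <- kmeans_fit(pairs, 1)
  expect_equal(m1$centers[1, ], colMeans(pairs), ignore_attr = TRUE)

  mn <- kmeans_fit(pairs, 4, seed = 1)
  expect_equal(mn$wcss, 0)

  X <- withr::with_seed(5, matrix(rnorm(60), ncol = 2))
  a <- kmeans_fit(X, 3, seed = 7)
  b <- kmeans_fit(X, 3, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centers, b$centers)
  expect_error(kmeans_fit(X, 31), "k must lie")
})

test_that("k-means beats random assignments and reaches the exhaustive optimum", {
  X <- withr::with_seed(8, matrix(rnorm(40), ncol = 2))
  m <- kmeans_fit(X, 3, seed = 8)
  withr::with_seed(9, for (r in 1:100) {
    lab <- sample(1:3, nrow(X), replace = TRUE)
    if (length(unique(lab)) == 3) expect_lte(m$wcss, wcss(X, lab) + 1e-9)
  })

  # n <= 8: global optimum by exhaustive enumeration of partitions
  for (seed in 1:3) {
    Xs <- withr::with_seed(seed, matrix(rnorm(14), ncol = 2))
    for (k in 2:3) {
      best <- oracle_kmeans_optimum(Xs, k)
      got <- kmeans_fit(Xs, k, seed = seed, n_init = 50)$wcss
      expect_equal(got, best, tolerance = 1e-9)
    }
  }
})

test_that("wcss matches its definition at the limits", {
  X <- withr::with_seed(2, matrix(rnorm(30), ncol = 3))
  expect_equal(wcss(X, rep(1, 10)), sum(sweep(X, 2, colMeans(X))^2))
  expect_equal(wcss(X, 1:10), 0)
  lab <- rep(1:2, 5)
  expect_equal(wcss(X, lab), oracle_wcss(X, lab), tolerance = 1e-12)
})

test_that("validity indices match brute-force implementations", {
  # hand-checkable 4-point silhouette example
  F4 <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab4 <- c(1, 1, 2, 2)
  expect_equal(silhouette_mean(F4, lab4), oracle_silhouette(F4, lab4),
               tolerance = 1e-12)
  expect_gt(silhouette_mean(F4, lab4), 0.85)  # tight, far clusters

  # 6-point worked example for CH and DB
  F6 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(8, 8), c(9, 8), c(8, 9))
  lab6 <- c(1, 1, 1, 2, 2, 2)
  expect_equal(calinski_harabasz(F6, lab6), oracle_calinski_harabasz(F6, lab6),
               tolerance = 1e-12)
  expect_equal(davies_bouldin(F6, lab6), oracle_davies_bouldin(F6, lab6),
               tolerance = 1e-12)

  # random 20-point instances, 3 labels
  for (seed in 1:5) {
    F <- withr::with_seed(seed, matrix(rnorm(40), ncol = 2))
    lab <- withr::with_seed(seed + 100, sample(1:3, 20, replace = TRUE))
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_mean(F, lab), oracle_silhouette(F, lab),
                 tolerance = 1e-9)
    expect_equal(calinski_harabasz(F, lab), oracle_calinski_harabasz(F, lab),
                 tolerance = 1e-9)
    expect_equal(davies_bouldin(F, lab), oracle_davies_bouldin(F, lab),
                 tolerance = 1e-9)
  }

  # third-party cross-check of the silhouette
  F <- withr::with_seed(12, matrix(rnorm(60), ncol = 2))
  lab <- rep(1:3, each = 10)
  sil <- cluster::silhouette(lab, dist(F))
  expect_equal(silhouette_mean(F, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-9)

  expect_error(silhouette_mean(F, rep(1, 30)), "single cluster")
  expect_error(calinski_harabasz(F, rep(1, 30)), "single cluster")

  # two point-mass clusters: zero scatter, DB = 0
  pm <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_equal(davies_bouldin(pm, c(1, 1, 2, 2)), 0)
  # coincident centroids are flagged
  cc <- rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0))
  expect_warning(db <- davies_bouldin(cc, c(1, 1, 2, 2)), "coincident")
  expect_true(is.infinite(db))

  # random labels on isotropic data: silhouette near 0, CH small
  Fr <- withr::with_seed(21, matrix(rnorm(200), ncol = 2))
  labr <- withr::with_seed(22, sample(1:3, 100, replace = TRUE))
  expect_lt(abs(silhouette_mean(Fr, labr)), 0.12)
  expect_lt(calinski_harabasz(Fr, labr), 5)
})

three_blob_data <- function(seed = 42, n = 60, sep = 12) {
  centers <- rbind(c(0, 0), c(sep, 0), c(sep / 2, sep))
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(1:3, function(i)
      cbind(rnorm(n, centers[i, 1]), rnorm(n, centers[i, 2]))))
  })
  list(X = X, labels = rep(1:3, each = n))
}

test_that("scan_k produces a monotone WCSS curve and finds clean structure", {
  blobs <- three_blob_data()
  scan <- scan_k(blobs$X, k_range = 2:6, seed = 0)
  expect_true(all(diff(scan$wcss) <= 1e-9))
  expect_true(all(scan$silhouette >= -1 & scan$silhouette <= 1))
  expect_true(all(scan$calinski_harabasz >= 0))
  expect_true(all(scan$davies_bouldin >= 0))
  expect_identical(scan$k[which.max(scan$silhouette)], 3L)
  expect_identical(select_k(scan, "silhouette_max"), 3L)

  single <- scan_k(blobs$X, k_range = 4, seed = 0)
  expect_identical(nrow(as.data.frame(single)), 1L)
})

test_that("select_k strategies behave as defined", {
  scan <- data.frame(k = 2:6, wcss = c(100, 40, 30, 25, 22),
                     silhouette = c(0.3, 0.52, 0.4, 0.2, 0.1))
  expect_identical(select_k(scan, "silhouette_max"), 3L)
  # knee by maximal perpendicular distance to the chord, computed here
  # from the two-point line form as an independent check
  chord <- function(x, y) {
    x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
    abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
      sqrt((y2 - y1)^2 + (x2 - x1)^2)
  }
  expect_identical(select_k(scan, "elbow_knee"),
                   scan$k[which.max(chord(scan$k, scan$wcss))])
  expect_identical(select_k(scan, "elbow_knee"), 3L)
  expect_identical(select_k(scan, "manual", k = 4), 4L)
  expect_error(select_k(scan, "manual"), "explicit k")
  expect_error(select_k(scan[0, ], "silhouette_max"), "empty")
})

test_that("phenotype naming follows the cluster statistics, not indices", {
  sim <- simulate_cohort(table1_config(seed = 1))
  summ <- cluster_summary(sim$parameters, sim$labels)
  expect_identical(unname(label_clusters(summ)[c("1", "2", "3")]),
                   c("forward-head", "normal", "long-neck"))

  # permute cluster indices: names must follow the statistics
  perm_labels <- c(3L, 1L, 2L)[sim$labels]
  summ_p <- cluster_summary(sim$parameters, perm_labels)
  got <- label_clusters(summ_p)
  expect_identical(unname(got[c("3", "1", "2")]),
                   c("forward-head", "normal", "long-neck"))

  two <- cluster_summary(sim$parameters, (sim$labels %% 2) + 1L)
  expect_identical(unname(label_clusters(two)), c("cluster_1", "cluster_2"))
})

test_that("profile z-scores are cohort-referenced standardized means", {
  sim <- simulate_cohort(table1_config(seed = 1))
  std <- standardize(sim$parameters)
  summ <- cluster_summary(sim$parameters, sim$labels)
  prof <- profile_zscores(summ, std$scaler)
  # the normal cluster (2) has the top lordosis z-score
  expect_identical(which.max(prof[, "lordosis_deg"]), c(`2` = 2L))
  # single cluster: all zeros
  one <- cluster_summary(sim$parameters, rep(1L, nrow(sim$parameters)))
  expect_equal(unname(profile_zscores(one, std$scaler)),
               matrix(0, 1, 4), tolerance = 1e-10)
  # two symmetric clusters: opposite-sign profiles
  Xs <- data.frame(sva = c(-2, -1, 1, 2), lordosis_deg = c(2, 1, -1, -2),
                   vertical_length = c(-2, -1, 1, 2),
                   curved_length = c(-2, -1, 1, 2))
  stds <- standardize(Xs)
  profs <- profile_zscores(cluster_summary(Xs, c(1, 1, 2, 2)), stds$scaler)
  expect_equal(profs[1, ], -profs[2, ], tolerance = 1e-10)
})

test_that("clustering the reference-style cohort recovers the generating labels", {
  sim <- simulate_cohort(table1_config(seed = 1))
  std <- standardize(sim$parameters)
  model <- kmeans_fit(std$Z, 3, seed = 1)
  ari <- mclust::adjustedRandIndex(model$labels, sim$labels)
  # overlapping Gaussians: a smoke bound, not perfect recovery
  expect_gt(ari, 0.5)
  phen <- label_clusters(cluster_summary(sim$parameters, model$labels))
  expect_setequal(phen, c("forward-head", "normal", "long-neck"))
})

test_that("k-means agrees with an independent implementation on blobs", {
  blobs <- three_blob_data(seed = 17, n = 40)
  ours <- kmeans_fit(blobs$X, 3, seed = 5)
  ref <- withr::with_seed(5,
    stats::kmeans(blobs$X, 3, nstart = 10, algorithm = "Lloyd",
                  iter.max = 300))
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-6)
  expect_equal(mclust::adjustedRandIndex(ours$labels, ref$cluster), 1)
})
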