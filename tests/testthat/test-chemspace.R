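test_that("PCA maps are deterministic with orthonormal loadings", {
  # collinear 2-D data: PC1 explains everything
  t <- seq(-2, 2, length.out = 30)
  Xc <- cbind(a = t, b = 3 * t)
  map <- pcaMap(Xc)
  expect_equal(map@explained[1], 100, tolerance = 1e-8)

  # isotropic Gaussian: PC1 near 50%
  set.seed(1)
  Xi <- matrix(rnorm(2e4), 1e4, 2, dimnames = list(NULL, c("u", "v")))
  mi <- pcaMap(Xi)
  expect_lt(abs(mi@explained[1] - 50), 2)

  # loadings orthonormal; sign convention: dominant element positive
  set.seed(2)
  Xr <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("d", 1:4)))
  mr <- pcaMap(Xr, 4)
  expect_equal(unname(crossprod(mr@loadings)), diag(4), tolerance = 1e-10)
  for (j in 1:4)
    expect_gt(mr@loadings[which.max(abs(mr@loadings[, j])), j], 0)
  expect_equal(sum(mr@explained), 100, tolerance = 1e-9)
  expect_true(all(diff(mr@explained) <= 1e-9))

  # scores reproduce the z-scored data within numerical tolerance
  Z <- scale(Xr)
  expect_equal(unname(Z %*% mr@loadings), unname(mr@scores[, 1:4]),
               tolerance = 1e-10)

  # zero-variance column dropped with a message
  expect_message(pcaMap(cbind(Xr, const = 1)), "zero-variance")
})

test_that("K-means recovers the exhaustive-best toy partition", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  km <- kmeansCluster(X, k = 2, n_init = 5, seed = 1)
  expect_equal(km$labels[1], km$labels[2])
  expect_equal(km$labels[3], km$labels[4])
  expect_false(km$labels[1] == km$labels[3])
  expect_equal(km$inertia, 0.01, tolerance = 1e-12)

  # k = n: singletons, zero inertia
  kmn <- kmeansCluster(X, k = 4, n_init = 2, seed = 1)
  expect_equal(kmn$inertia, 0)
  expect_equal(sort(kmn$labels), 1:4)

  # seeded determinism
  set.seed(8)
  Xr <- matrix(rnorm(100), 50, 2)
  expect_identical(kmeansCluster(Xr, 5, seed = 42)$labels,
                   kmeansCluster(Xr, 5, seed = 42)$labels)

  # cross-check against stats::kmeans on well-separated blobs
  set.seed(9)
  blobs <- rbind(matrix(rnorm(40, 0), 20, 2),
                 matrix(rnorm(40, 8), 20, 2),
                 matrix(rnorm(40, -8), 20, 2))
  ours <- kmeansCluster(blobs, 3, n_init = 10, seed = 3)
  ref <- kmeans(blobs, 3, nstart = 10)
  expect_equal(ours$inertia, ref$tot.withinss, tolerance = 1e-6)
})

test_that("cluster response ranges report exact per-cluster extremes", {
  labels <- c(1, 1, 1, 2, 2, 2)
  y <- c(-2.4, -1.0, -1.8, 0.2, 0.9, 0.5)
  rg <- clusterResponseRanges(labels, y)
  expect_equal(rg$min, c(-2.4, 0.2))
  expect_equal(rg$max, c(-1.0, 0.9))
  expect_equal(rg$n, c(3L, 3L))

  one <- clusterResponseRanges(rep(1, 6), y)
  expect_equal(c(one$min, one$max), range(y))

  singl <- clusterResponseRanges(1:6, y)
  expect_equal(singl$min, singl$max)
})

test_that("the regression tree reproduces the exhaustive root split", {
  X <- matrix(1:4, ncol = 1, dimnames = list(NULL, "B1"))
  y <- c(0, 0, 1, 1)
  tr <- regressionTree(X, y, max_depth = 1, min_leaf = 1)
  expect_false(tr$leaf)
  expect_equal(tr$threshold, 2.5)
  expect_equal(tr$left$mean, 0)
  expect_equal(tr$right$mean, 1)
  expect_equal(predict(tr, X), y)

  # constant response: a single leaf
  trc <- regressionTree(X, rep(3, 4), max_depth = 3, min_leaf = 1)
  expect_true(trc$leaf)

  # fitted SSE never exceeds the root SSE; deepening never hurts
  set.seed(5)
  Xr <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  yr <- ifelse(Xr[, 1] > 0.3, 1.5, -0.5) + rnorm(100, sd = 0.3)
  t1 <- regressionTree(Xr, yr, max_depth = 1, min_leaf = 5)
  t3 <- regressionTree(Xr, yr, max_depth = 3, min_leaf = 5)
  expect_lte(treeSSE(t1, Xr, yr), t1$sse)
  expect_lte(treeSSE(t3, Xr, yr), treeSSE(t1, Xr, yr) + 1e-9)

  # min_leaf is honored everywhere
  leafCounts <- function(node)
    if (node$leaf) node$n else c(leafCounts(node$left),
                                 leafCounts(node$right))
  expect_true(all(leafCounts(t3) >= 5))
})

test_that("the tree agrees with rpart on a clean fixture", {
  skip_if_not_installed("rpart")
  set.seed(6)
  X <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- ifelse(X[, 1] <= 0.2, -1, 1) + rnorm(60, sd = 0.1)
  ours <- regressionTree(X, y, max_depth = 1, min_leaf = 5)
  ref <- rpart::rpart(y ~ ., data = data.frame(X, y),
                      control = rpart::rpart.control(
                        maxdepth = 1, minbucket = 5, minsplit = 10,
                        cp = 0, xval = 0))
  refSplit <- ref$splits[1, "index"]
  expect_equal(ours$feature, rownames(ref$splits)[1])
  expect_equal(ours$threshold, unname(refSplit), tolerance = 1e-9)

  # classification mode thresholds the response first
  trc <- regressionTree(X, y, max_depth = 1, min_leaf = 5,
                        class_cutoff = 0)
  expect_true(all(c(trc$left$mean, trc$right$mean) >= 0))
  expect_true(all(c(trc$left$mean, trc$right$mean) <= 1))
})
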