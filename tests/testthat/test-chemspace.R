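# PCA, Butina clustering, trustworthiness. (UMAP contracts are exercised in
# the acceptance suite to keep a single python round trip.)

test_that("PCA satisfies its algebraic contracts", {
  set.seed(407)
  X <- matrix(rnorm(200), ncol = 4)
  colnames(X) <- paste0("v", 1:4)
  p <- pca_project(X)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-8)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  # orthonormal loadings
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # 2-d input: two components carry all the variance
  p2 <- pca_project(X[, 1:2])
  expect_equal(sum(p2$explained_variance[1:2]), 1, tolerance = 1e-8)
  # projection of the mean row is the origin under z-scoring
  Xm <- rbind(X, colMeans(X))
  pm <- pca_project(Xm)
  expect_equal(unname(pm$coords[nrow(Xm), ]), c(0, 0), tolerance = 1e-8)
  # constant column dropped with a warning
  Xc <- cbind(X, konst = 1)
  expect_warning(pc <- pca_project(Xc), "konst")
  expect_identical(pc$dropped_columns, "konst")
  expect_error(pca_project(rbind(X, NA)), "missing")
})

test_that("butina clustering matches a hand-traced execution", {
  # 8-point similarity matrix built by hand. cutoff 0.5 => neighbours are
  # pairs with similarity >= 0.5.
  s <- diag(8)
  pair <- function(i, j, v) { s[i, j] <<- v; s[j, i] <<- v }
  pair(1, 2, 0.9); pair(1, 3, 0.8); pair(2, 3, 0.7)   # triangle 1-2-3
  pair(4, 1, 0.55)                                     # 4 hangs off 1
  pair(5, 6, 0.6)                                      # pair 5-6
  pair(7, 8, 0.3)                                      # below cutoff
  rownames(s) <- colnames(s) <- paste0("p", 1:8)
  # hand trace: neighbour counts are 1:3, 2:2, 3:2, 4:1, 5:1, 6:1, 7:0, 8:0.
  # point 1 leads -> cluster {1,2,3,4}; then 5 -> {5,6}; 7 -> {7}; 8 -> {8}.
  bc <- butina_cluster(sims = s, cutoff = 0.5)
  expect_identical(unname(bc$labels), c(0L, 0L, 0L, 0L, 1L, 1L, 2L, 3L))
  expect_identical(bc$centroids[1:2], c(1L, 5L))
  # row-order invariance up to relabeling: permute and compare partitions
  perm <- c(3, 5, 1, 8, 2, 7, 4, 6)
  bc2 <- butina_cluster(sims = s[perm, perm], cutoff = 0.5)
  sig <- function(b) sort(vapply(split(names(b$labels), b$labels),
                                 function(m) paste(sort(m), collapse = "|"),
                                 character(1)))
  expect_identical(unname(sig(bc)), unname(sig(bc2)))
})

test_that("butina degenerate cases", {
  same <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_identical(unique(unname(butina_cluster(sims = same)$labels)), 0L)
  apart <- diag(4); dimnames(apart) <- dimnames(same)
  expect_identical(unname(butina_cluster(sims = apart)$labels), 0:3)
  # every non-centroid member lies within the cutoff of its centroid
  fps <- fixture_fps()[1:60, ]
  bc <- butina_cluster(fps, cutoff = 0.5)
  sims <- tanimoto_matrix(fps)
  for (cl in unique(bc$labels)) {
    cen <- bc$centroids[cl + 1L]
    members <- which(bc$labels == cl)
    expect_true(all(1 - sims[cen, members] <= 0.5 + 1e-12))
  }
})

test_that("trustworthiness equals the brute-force rank oracle", {
  set.seed(408)
  for (n in c(12, 20, 50)) {
    X <- matrix(rnorm(n * 6), ncol = 6)
    Y <- matrix(rnorm(n * 2), ncol = 2)
    dX <- as.matrix(dist(X)); dY <- as.matrix(dist(Y))
    for (k in c(3, 5)) {
      expect_equal(trustworthiness(dX, dY, k),
                   brute_force_trustworthiness(dX, dY, k),
                   tolerance = 1e-12)
    }
  }
  # identical spaces are perfectly trustworthy; range respected
  X <- matrix(rnorm(40), ncol = 2)
  dX <- as.matrix(dist(X))
  expect_equal(trustworthiness(dX, dX, 5), 1)
  vals <- replicate(10, {
    Y <- matrix(rnorm(40), ncol = 2)
    trustworthiness(dX, as.matrix(dist(Y)), 4)
  })
  expect_true(all(vals >= 0 & vals <= 1))
  expect_error(trustworthiness(dX, dX, 20), "k must be smaller")
})

test_that("trustworthiness reproduces an external reference value", {
  # frozen from scikit-learn's implementation on this closed-form fixture
  X <- outer(1:20, 1:5, function(i, j) sin(i * j))
  Y <- cbind(cos(1:20), sin(2 * (1:20)))
  dX <- as.matrix(dist(X)); dY <- as.matrix(dist(Y))
  expect_equal(trustworthiness(dX, dY, 3), 0.6888888888888889,
               tolerance = 1e-12)
  expect_equal(trustworthiness(dX, dY, 5), 0.6125, tolerance = 1e-12)
})
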