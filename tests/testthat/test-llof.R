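test_that("k-distance within a cluster matches sorted pairwise distances", {
  cl <- rbind(c(1, 0), c(2, 0), c(3, 0))
  expect_equal(knn_distance_in_cluster(c(0, 0), cl, k = 2), 2)
  # k+1 identical points: zero distance
  cl0 <- matrix(0, 3, 2)
  expect_equal(knn_distance_in_cluster(c(0, 0), cl0, k = 2), 0)
  expect_error(knn_distance_in_cluster(c(0, 0), cl, k = 5), "skip")

  set.seed(9)
  for (i in 1:10) {
    cl <- matrix(rnorm(40), 20, 2)
    x <- rnorm(2)
    k <- sample(1:10, 1)
    brute <- sort(apply(cl, 1, function(r) sqrt(sum((r - x)^2))))[k]
    expect_equal(knn_distance_in_cluster(x, cl, k), brute)
  }
})

test_that("reachability distance floors the pairwise distance at the k-distance", {
  cl <- rbind(c(1, 0), c(2, 0), c(3, 0))  # C's companions
  C <- c(0, 0)
  # far D: plain distance wins
  expect_equal(reachability_distance(C, c(10, 0), cl, k = 2), 10)
  # close D: floored at C's k-distance
  expect_equal(reachability_distance(C, c(0.5, 0), cl, k = 2), 2)
  # D = C: exactly the k-distance
  expect_equal(reachability_distance(C, C, cl, k = 2), 2)
})

test_that("LLOF is ~1 inside tight clusters and flags the planted outlier", {
  set.seed(6)
  # uniform cloud: a genuinely tight cluster with no straggling tail
  X <- rbind(matrix(runif(200), 100, 2), c(30, 30))
  labels <- rep("LIA", 101)
  scores <- llof_score(X, labels, llof_params(k_neighbors = 10, eps1 = 1.5))
  expect_true(all(abs(scores[1:100] - 1) < 0.6))
  expect_gt(scores[101], 3)

  flt <- filter_outliers(X, labels, llof_params(10, 1.5))
  expect_equal(flt$removed_index, 101L)
  expect_equal(nrow(flt$kept) + length(flt$removed_index), nrow(X))

  # identical points: degenerate densities score 1
  Xdup <- matrix(1, 25, 2)
  s <- llof_score(Xdup, rep("LIA", 25), llof_params(5, 1.5))
  expect_true(all(s == 1))

  # infinite threshold removes nothing
  flt2 <- filter_outliers(X, labels, llof_params(10, Inf))
  expect_length(flt2$removed_index, 0L)
})

test_that("label-restricted scores equal the textbook LOF oracle per cluster", {
  set.seed(20)
  for (trial in 1:3) {
    n1 <- sample(30:80, 1); n2 <- sample(30:80, 1)
    X <- rbind(matrix(rnorm(2 * n1, mean = 0), n1, 2),
               matrix(rnorm(2 * n2, mean = 6), n2, 2))
    labels <- c(rep("LIA", n1), rep("MIA", n2))
    k <- sample(5:15, 1)
    scores <- llof_score(X, labels, llof_params(k, 1.5))
    expect_equal(scores[labels == "LIA"],
                 oracle_lof(X[labels == "LIA", ], k), tolerance = 1e-9)
    expect_equal(scores[labels == "MIA"],
                 oracle_lof(X[labels == "MIA", ], k), tolerance = 1e-9)
  }
})

test_that("scores are invariant under translation, rotation and scaling", {
  set.seed(21)
  X <- rbind(matrix(rnorm(100), 50, 2), c(8, 8))
  labels <- rep("LIA", 51)
  p <- llof_params(10, 1.5)
  base <- llof_score(X, labels, p)
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  expect_equal(llof_score(sweep(X, 2, c(5, -3), "+"), labels, p), base,
               tolerance = 1e-9)
  expect_equal(llof_score(X %*% R, labels, p), base, tolerance = 1e-9)
  expect_equal(llof_score(X * 7.3, labels, p), base, tolerance = 1e-9)
})

test_that("clusters too small to score pass through unfiltered with a warning", {
  X <- rbind(matrix(rnorm(60), 30, 2), matrix(5 + rnorm(6), 3, 2))
  labels <- c(rep("LIA", 30), rep("MIA", 3))
  expect_warning(flt <- filter_outliers(X, labels, llof_params(10, 1.5)),
                 "MIA")
  expect_true(all(which(labels == "MIA") %in% flt$kept_index))
  expect_true(all(is.na(flt$scores[labels == "MIA"])))
})
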