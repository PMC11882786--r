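test_that("profile distance is Manhattan by default", {
  p <- rep(0, 210); q <- rep(0, 210)
  expect_equal(profile_distance(p, q), 0)
  q[5] <- 0.25
  expect_equal(profile_distance(p, q), 0.25)
  p2 <- rep(0, 210); p2[1] <- 1
  q2 <- rep(0, 210); q2[2] <- 1
  expect_equal(profile_distance(p2, q2), 2)
  expect_error(profile_distance(rep(0, 210), rep(0, 209)), "dimension")
})

test_that("distance_matrix matches a naive double loop and is metric", {
  X <- random_profiles(10, seed = 31)
  D <- distance_matrix(X)
  for (i in 1:10) {
    for (j in 1:10) {
      expect_lt(abs(D[i, j] - sum(abs(X[i, ] - X[j, ]))), 1e-12)
    }
  }
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 10))
  # triangle inequality on random triples
  for (t in 1:20) {
    ijk <- sample(10, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
  Xdup <- X[c(1, 1), ]
  rownames(Xdup) <- c("a", "a")
  expect_error(distance_matrix(Xdup), "duplicate")
})

test_that("1-NN LOOCV agrees with the brute-force oracle", {
  set.seed(17)
  for (trial in 1:100) {
    n <- sample(8:30, 1)
    X <- matrix(rnorm(n * 5), n, 5)
    rownames(X) <- paste0("s", seq_len(n))
    D <- as.matrix(dist(X, method = "manhattan"))
    labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    while (min(table(labels)) < 2 || length(unique(labels)) < 2) {
      labels <- sample(c("a", "b", "c"), n, replace = TRUE)
    }
    rep <- knn_loocv(D, labels)
    expect_equal(rep$accuracy, oracle_knn_loocv_accuracy(D, labels))
  }
})

test_that("1-NN LOOCV separates planted clusters perfectly and is deterministic under ties", {
  gp <- gaussian_profile_clusters(k = 2, n_per = 6, separation = 100,
                                  noise_sd = 0.01, seed = 3)
  D <- distance_matrix(gp$profiles)
  rep <- knn_loocv(D, gp$labels)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(unname(rep$per_class_f1), c(1, 1))
  expect_equal(rep$macro_f1, 1.0)
  # all-equal distances: every prediction falls to the smallest-index rule
  n <- 6
  D2 <- matrix(1, n, n) - diag(n)
  dimnames(D2) <- list(paste0("s", 1:n), paste0("s", 1:n))
  labels <- c("x", "y", "y", "x", "y", "x")
  rep2 <- expect_warning(knn_loocv(D2, labels), NA)
  # nearest other sample is always index 1 (or 2 for the first sample)
  expect_equal(unname(rep2$predicted),
               c(labels[2], labels[1], labels[1], labels[1], labels[1],
                 labels[1]))
})

test_that("adjusted Rand index behaves canonically and matches pair counting", {
  x <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(x, x), 1)
  relabeled <- c("b", "b", "c", "c", "a", "a")
  expect_equal(adjusted_rand_index(x, relabeled), 1)
  singletons <- seq_len(6)
  expect_equal(adjusted_rand_index(singletons, rep(1, 6)), 0)
  set.seed(23)
  for (trial in 1:100) {
    n <- sample(6:40, 1)
    a <- sample(3, n, replace = TRUE)
    b <- sample(4, n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("Spearman correlation handles order, reversal and ties", {
  expect_equal(spearman_rank(1:8, 1:8), 1)
  expect_equal(spearman_rank(1:8, 8:1), -1)
  set.seed(29)
  for (trial in 1:100) {
    n <- sample(5:25, 1)
    x <- sample(5, n, replace = TRUE)  # many ties
    y <- sample(5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rank(x, y), oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(v <- spearman_rank(rep(1, 5), 1:5), "constant")
  expect_true(is.na(v))
})

worked_example_distmat <- function() {
  ids <- c("a1", "a2", "b1", "b2")
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["a1", "b1"] <- D["b1", "a1"] <- 1
  D["a1", "b2"] <- D["b2", "a1"] <- 5
  D["a2", "b1"] <- D["b1", "a2"] <- 3
  D["a2", "b2"] <- D["b2", "a2"] <- 7
  D["a1", "a2"] <- D["a2", "a1"] <- 2
  D["b1", "b2"] <- D["b2", "b1"] <- 4
  D
}

test_that("closest-set distance evaluates the displayed formula", {
  D <- worked_example_distmat()
  expect_equal(closest_set_distance(c("a1", "a2"), c("b1", "b2"), D), 2.5)
  expect_equal(closest_set_distance("a1", "b1", D), 1)
  expect_equal(closest_set_distance("a1", "a1", D), 0)  # singleton within
  # random instances against the naive oracle
  set.seed(37)
  for (trial in 1:100) {
    n <- sample(9:16, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    rownames(X) <- paste0("s", seq_len(n))
    D2 <- as.matrix(dist(X, method = "manhattan"))
    A <- sample(rownames(X), sample(2:4, 1))
    B <- sample(setdiff(rownames(X), A), sample(2:4, 1))
    expect_equal(closest_set_distance(A, B, D2),
                 oracle_closest_set(A, B, D2), tolerance = 1e-12)
    expect_equal(closest_set_distance(A, A, D2),
                 oracle_closest_set(A, A, D2, within = TRUE),
                 tolerance = 1e-12)
  }
  expect_error(closest_set_distance("zz", "a1", worked_example_distmat()),
               "unknown")
})

test_that("the separation measure reproduces the hand-checked example", {
  D <- worked_example_distmat()
  res <- separation(c("a1", "a2"), c("b1", "b2"), D)
  expect_equal(res$d_AB, 2.5)
  expect_equal(res$d_AA, 2)
  expect_equal(res$d_BB, 4)
  expect_equal(res$E_AB, -0.5)
  # symmetry
  res2 <- separation(c("b1", "b2"), c("a1", "a2"), D)
  expect_equal(res2$E_AB, res$E_AB)
  # singletons
  res3 <- separation("a1", "b2", D)
  expect_equal(res3$E_AB, 5)
  # A = B: cross distance 0, so E_AB = -<d_AA> <= 0
  res4 <- separation(c("a1", "a2"), c("a1", "a2"), D)
  expect_equal(res4$d_AB, 0)
  expect_equal(res4$E_AB, -res4$d_AA)
  expect_lte(res4$E_AB, 0)
})
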