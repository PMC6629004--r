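test_that("lambda grid is the midpoint grid on (0, 1)", {
  g <- lambda_grid(101)
  expect_equal(g[1], 1 / 202, tolerance = 1e-12)
  expect_equal(g[40], 79 / 202, tolerance = 1e-12)
  expect_equal(g[85], 169 / 202, tolerance = 1e-12)
  ## the three reported penalty values are grid members
  expect_equal(g[c(1, 40, 85)], c(0.004950495, 0.391089109, 0.836633663),
               tolerance = 1e-9)
  expect_true(all(g > 0 & g < 1))
  expect_true(all(diff(g) > 0))
  expect_error(lambda_grid(1), ">= 2")
})

make_two_cluster_layers <- function(n = 60, seed = 2, sep = 2) {
  set.seed(seed)
  lab <- rep(1:2, each = n / 2)
  X1 <- named_matrix(rnorm(40 * n), 40, n, rpre = "a") +
    outer(rnorm(40), ifelse(lab == 1, sep, -sep))
  X2 <- named_matrix(rnorm(30 * n), 30, n, rpre = "b") +
    outer(rnorm(30), ifelse(lab == 1, -sep, sep))
  colnames(X2) <- colnames(X1)
  list(layers = list(X1, X2), truth = lab)
}

test_that("unpenalized fit separates well-separated clusters exactly", {
  d <- make_two_cluster_layers()
  fit <- icluster_fit(d$layers, K = 2, lambdas = 0, max_iter = 50, seed = 1)
  expect_equal(adjusted_rand_index(fit$labels, d$truth), 1)
  expect_true(all(fit$psi > 0))
  expect_true(fit$pod >= 0 && fit$pod <= 1)
})

test_that("log-likelihood is non-decreasing across EM iterations at lambda 0", {
  d <- make_two_cluster_layers(seed = 5)
  fit <- icluster_fit(d$layers, K = 2, lambdas = 0, max_iter = 40, seed = 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-6 * abs(fit$loglik_trace[-1])))
})

test_that("full shrinkage drives all loadings to zero and flags the fit", {
  d <- make_two_cluster_layers(seed = 7)
  fit <- icluster_fit(d$layers, K = 2, lambdas = 1, max_iter = 10, seed = 1)
  expect_true(fit$degenerate)
  expect_equal(fit$pod, 1)
  expect_true(all(abs(do.call(rbind, fit$loadings)) < 1e-12))
})

test_that("the same data and seed give identical labels", {
  d <- make_two_cluster_layers(seed = 9, sep = 1)
  f1 <- icluster_fit(d$layers, K = 2, lambdas = 0.3, seed = 4)
  f2 <- icluster_fit(d$layers, K = 2, lambdas = 0.3, seed = 4)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$Z, f2$Z)
})

test_that("soft-thresholding zeroes exactly the sub-threshold loadings", {
  set.seed(11)
  for (rep in 1:10) {
    W <- matrix(rnorm(25), 5, 5)
    lambda <- runif(1)
    got <- triomics:::soft_threshold_layer(W, lambda)
    thr <- lambda * max(abs(W))
    ## brute-force elementwise oracle
    want <- W
    for (i in 1:5) for (j in 1:5)
      want[i, j] <- if (abs(W[i, j]) <= thr) 0 else
        sign(W[i, j]) * (abs(W[i, j]) - thr)
    expect_equal(got, want, tolerance = 1e-12)
    expect_identical(got == 0, abs(W) <= thr)
  }
})

test_that("the adjusted Rand index matches an established implementation", {
  set.seed(12)
  for (rep in 1:10) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, rep(1:5, 2)) ,
               mclust::adjustedRandIndex(1:10, rep(1:5, 2)), tolerance = 1e-12)
})

test_that("pod is invariant to cluster relabeling", {
  set.seed(13)
  A <- triomics:::icluster_cosim(matrix(rnorm(200), 10, 20))
  lab <- sample(1:3, 20, replace = TRUE)
  perm <- c(3, 1, 2)
  expect_equal(triomics:::icluster_pod(A, lab),
               triomics:::icluster_pod(A, perm[lab]))
  expect_equal(adjusted_rand_index(lab, perm[lab]), 1)
})

test_that("undersized clusters merge into their nearest neighbour", {
  ## latent layout mirroring cluster sizes 1 / 65 / 128 / 156: the singleton
  ## sits next to the 65-cluster, so they merge into one subtype of 66
  sizes <- c(1, 65, 128, 156)
  centers <- c(0, 0.6, 5, 10)
  labels <- rep(1:4, sizes)
  Z <- matrix(rep(centers, sizes) + rnorm(sum(sizes), 0, 0.05), nrow = 1)
  merged <- merge_small_clusters(labels, Z, min_size = 10)
  expect_setequal(as.integer(table(merged)), c(66, 128, 156))
  expect_true(all(table(merged) >= 10))
  expect_equal(length(merged), length(labels))   # universe unchanged
  ## relabeled by increasing size
  expect_equal(as.integer(table(merged)[as.character(1:3)]), c(66, 128, 156))
})

test_that("tuning recovers a planted three-subtype cohort", {
  set.seed(19)
  n <- 90
  lab <- rep(1:3, each = 30)
  mk <- function(p, rpre) {
    M <- named_matrix(rnorm(p * n), p, n, rpre = rpre)
    for (b in 1:3) {
      rows <- ((b - 1) * p / 3 + 1):(b * p / 3)
      M[rows, lab == b] <- M[rows, lab == b] + 1.6
    }
    M
  }
  layers <- list(mk(30, "a"), mk(30, "b"), mk(60, "c"))
  fit <- tune_and_cluster(layers, K_range = 2:3, grid = lambda_grid(11),
                          seed = 19)
  expect_equal(fit$K, 3)
  expect_gte(adjusted_rand_index(fit$labels, lab), 0.9)
  expect_true(all(table(fit$labels) >= 10))
})

test_that("structureless data returns the smallest K with a warning", {
  set.seed(23)
  layers <- list(named_matrix(rnorm(40 * 50), 40, 50, rpre = "a"),
                 named_matrix(rnorm(30 * 50), 30, 50, rpre = "b"))
  expect_warning(
    fit <- tune_and_cluster(layers, K_range = 2:3, grid = lambda_grid(5),
                            min_cluster_size = 2, seed = 23),
    "little cluster structure")
  expect_equal(fit$K, 2)
})

test_that("partition overlap test matches hypergeometric enumeration", {
  ## identical partitions: diagonal pairs overlap fully
  a <- rep(1:2, each = 5); names(a) <- paste0("s", 1:10)
  res <- partition_overlap_test(a, a)
  diag_pairs <- res$pairs[res$pairs$cluster_a == res$pairs$cluster_b, ]
  off_pairs <- res$pairs[res$pairs$cluster_a != res$pairs$cluster_b, ]
  expect_true(all(diag_pairs$overlap_frac == 1))
  expect_true(all(off_pairs$overlap_frac == 0))
  ## cluster pair of size 5 in a universe of 10: P(overlap = 5) = 1/252
  expect_equal(diag_pairs$p[1], 1 / choose(10, 5), tolerance = 1e-12)

  ## null calibration: independent random partitions
  set.seed(29)
  hits <- replicate(300, {
    x <- sample(1:2, 40, TRUE); names(x) <- paste0("s", 1:40)
    y <- sample(1:2, 40, TRUE); names(y) <- names(x)
    mean(partition_overlap_test(x, y)$pairs$p < 0.05)
  })
  ## discrete exact p-values are conservative: nominal 5% is an upper bound
  expect_lte(mean(hits), 0.07)
  expect_gt(mean(hits), 0.005)

  ## ks mode returns a test object
  ks <- partition_overlap_test(a, a, mode = "ks")
  expect_s3_class(ks$ks, "htest")
})
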