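## Integrative clustering of CNV + MET + EXP by a joint sparse Gaussian
## latent factor model: X_d = W_d Z + e_d per layer d, with K-1 shared latent
## factors, fit by EM with lasso-style soft-thresholding of the loadings.
## The algorithmic internals are our own reconstruction of this model class
## and are documented as such in the methods vignette.

#' Midpoint penalty grid on (0, 1)
#'
#' `n` equally spaced midpoints: `(2i - 1) / (2n)` for `i = 1..n`. The
#' default 101-point grid starts at 1/202 = 0.004950495...
#'
#' @param n number of grid points (>= 2); default 101.
#' @return strictly increasing numeric vector inside (0, 1).
#' @export
lambda_grid <- function(n = 101) {
  if (n < 2) stop("n must be >= 2")
  (2 * seq_len(n) - 1) / (2 * n)
}

standardize_rows <- function(X) {
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  sdv[sdv == 0] <- 1
  (X - mu) / sdv
}

## observed-data log-likelihood of the factor model via Woodbury
icluster_loglik <- function(X, W, psi_vec, n) {
  q <- ncol(W)
  WtPiX <- t(W / psi_vec) %*% X          # q x n
  Mi <- diag(q) + t(W / psi_vec) %*% W   # I + W' Psi^-1 W
  M <- solve(Mi)
  logdet <- determinant(Mi, logarithm = TRUE)$modulus + sum(log(psi_vec))
  trace_term <- (sum(X^2 / psi_vec) - sum((M %*% WtPiX) * WtPiX)) / n
  -n / 2 * (as.numeric(logdet) + trace_term + nrow(X) * log(2 * pi))
}

## proportion-of-deviance score: deviation of the cluster co-membership
## indicator from the sample co-similarity of the stacked standardized data
## ((cor + 1) / 2, fixed across candidate K so scores are comparable between
## cluster counts); 0 = ideal block structure, 1 = worst. Degenerate fits
## are pinned at 1.
icluster_cosim <- function(X) (stats::cor(X) + 1) / 2

## lasso-style soft-thresholding of a layer's loading matrix; the threshold
## is lambda times the layer's largest unpenalized loading so that lambda = 1
## zeroes the whole layer
soft_threshold_layer <- function(Wd, lambda) {
  thr <- lambda * max(abs(Wd))
  sign(Wd) * pmax(abs(Wd) - thr, 0)
}

icluster_pod <- function(A, labels) {
  B <- outer(labels, labels, "==") * 1
  mean(abs(A - B))
}

#' Fit the joint latent factor model at fixed K and lambda
#'
#' EM fit of the sparse Gaussian latent factor model with `K - 1` shared
#' factors across the data layers. The E-step computes `E[Z|X]` in closed
#' form; the M-step updates each layer's loading matrix by least squares
#' followed by soft-thresholding at `lambda_d` times the layer's largest
#' unpenalized loading (so `lambda = 0` is unpenalized and `lambda = 1`
#' shrinks every loading to zero), and updates the per-layer noise variance.
#' Cluster labels come from k-means (with `nstart` restarts at a fixed seed)
#' on the columns of `E[Z|X]`.
#'
#' @param datasets list of feature x sample matrices sharing the sample
#'   axis; each is standardized feature-wise internally.
#' @param K number of clusters (the model uses K - 1 factors).
#' @param lambdas penalty in \[0, 1\]: a single shared value or one per layer.
#' @param max_iter EM iteration cap; default 20 (the tuning cap).
#' @param tol relative log-likelihood change tolerance; default 1e-6.
#' @param seed seed for the k-means labeling step.
#' @param nstart k-means restarts; default 10.
#' @return object of class `"icluster_model"`: list with `K`, `lambdas`,
#'   `Z` (expected latent factors, (K-1) x n), `loadings` (per layer),
#'   `psi` (per layer), `labels`, `pod`, `loglik_trace`, `degenerate`,
#'   `converged`, `samples`.
#' @export
icluster_fit <- function(datasets, K, lambdas, max_iter = 20, tol = 1e-6,
                         seed = 1L, nstart = 10, W_init = NULL, A_cor = NULL) {
  K <- as.integer(unname(K))
  if (K < 2) stop("K must be >= 2")
  ns <- vapply(datasets, ncol, integer(1))
  if (length(unique(ns)) != 1) stop("datasets must share the sample axis")
  samples <- colnames(datasets[[1]])
  for (d in datasets[-1])
    if (!is.null(samples) && !identical(colnames(d), samples))
      stop("datasets must share the sample axis (column order differs)")
  D <- length(datasets)
  if (length(lambdas) == 1) lambdas <- rep(lambdas, D)
  if (length(lambdas) != D || any(lambdas < 0 | lambdas > 1))
    stop("lambdas must be one value per layer inside [0, 1]")

  Xd <- lapply(datasets, function(x) standardize_rows(unclass(x)))
  p_d <- vapply(Xd, nrow, integer(1))
  X <- do.call(rbind, Xd)
  n <- ncol(X); q <- K - 1L
  layer_of <- rep(seq_len(D), p_d)

  ## deterministic init: leading principal directions of the stacked data
  if (is.null(W_init)) {
    sv <- svd(X, nu = q, nv = 0)
    W <- sv$u %*% diag(sv$d[seq_len(q)] / sqrt(n), q, q)
  } else {
    W <- W_init[, seq_len(q), drop = FALSE]
  }
  psi <- rep(1, D)

  ll_prev <- -Inf; ll_trace <- numeric(0); converged <- FALSE
  EZ <- matrix(0, q, n)
  for (it in seq_len(max_iter)) {
    psi_vec <- psi[layer_of]
    ## E-step
    M <- solve(diag(q) + t(W / psi_vec) %*% W)
    EZ <- M %*% (t(W / psi_vec) %*% X)
    EZZ <- n * M + EZ %*% t(EZ)
    ## M-step: unpenalized least-squares loadings, then per-layer
    ## soft-thresholding scaled so lambda = 1 zeroes everything
    W_ls <- X %*% t(EZ) %*% solve(EZZ)
    for (d in seq_len(D)) {
      rows <- layer_of == d
      Wd <- W_ls[rows, , drop = FALSE]
      W[rows, ] <- soft_threshold_layer(Wd, lambdas[d])
      ## noise variance from the expected residual sum of squares
      rss <- sum(Xd[[d]]^2) -
        2 * sum(W[rows, , drop = FALSE] * (Xd[[d]] %*% t(EZ))) +
        sum((W[rows, , drop = FALSE] %*% EZZ) * W[rows, , drop = FALSE])
      psi[d] <- max(rss / (n * p_d[d]), 1e-8)
    }
    ll <- icluster_loglik(X, W, psi[layer_of], n)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * max(abs(ll_prev), 1)) { converged <- TRUE; break }
    ll_prev <- ll
  }
  ## final E-step with the final parameters
  psi_vec <- psi[layer_of]
  M <- solve(diag(q) + t(W / psi_vec) %*% W)
  EZ <- M %*% (t(W / psi_vec) %*% X)

  degenerate <- max(abs(EZ)) < 1e-8
  if (degenerate) {
    labels <- rep(1L, n)
    pod <- 1
  } else {
    set.seed(seed)
    km <- stats::kmeans(t(EZ), centers = K, nstart = nstart, iter.max = 50)
    labels <- km$cluster
    if (is.null(A_cor)) A_cor <- icluster_cosim(X)
    pod <- icluster_pod(A_cor, labels)
  }
  if (!is.null(samples)) names(labels) <- samples
  structure(list(K = K, lambdas = lambdas, Z = EZ,
                 loadings = split.data.frame(W, layer_of), psi = psi,
                 labels = labels, pod = pod, loglik_trace = ll_trace,
                 degenerate = degenerate, converged = converged,
                 samples = samples),
            class = "icluster_model")
}

#' @export
print.icluster_model <- function(x, ...) {
  cat(sprintf("Integrative cluster fit: K = %d, lambda = %s, pod = %.4f%s\n",
              x$K, paste(signif(x$lambdas, 4), collapse = "/"), x$pod,
              if (x$degenerate) " (degenerate)" else ""))
  cat("cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Merge undersized clusters
#'
#' Repeatedly merges the smallest cluster below `min_size` into its nearest
#' cluster by centroid distance in latent space, then renumbers the
#' surviving clusters 1..K' by increasing size. Never changes the sample
#' universe.
#'
#' @param labels integer cluster labels.
#' @param Z latent factor matrix, factors x samples.
#' @param min_size minimum allowed cluster size; default 10.
#' @return relabeled integer vector.
#' @export
merge_small_clusters <- function(labels, Z, min_size = 10) {
  nms <- names(labels)
  labels <- as.integer(factor(labels))
  names(labels) <- nms
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) < 2) break
    victim <- as.integer(small[which.min(sizes[small])])
    cents <- vapply(sort(unique(labels)),
                    function(k) rowMeans(Z[, labels == k, drop = FALSE]),
                    numeric(nrow(Z)))
    cents <- matrix(cents, nrow = nrow(Z))
    ks <- sort(unique(labels))
    vi <- which(ks == victim)
    d <- colSums((cents - cents[, vi])^2)
    d[vi] <- Inf
    target <- ks[which.min(d)]
    tri_log("merging cluster of size %d into its nearest neighbour", sizes[as.character(victim)])
    labels[labels == victim] <- target
  }
  sizes <- table(labels)
  remap <- stats::setNames(rank(sizes, ties.method = "first"), names(sizes))
  out <- as.integer(remap[as.character(labels)])
  names(out) <- names(labels)
  out
}

#' Tune (K, lambda) and produce the integrative subtypes
#'
#' Fits the model for every combination of `K` in `K_range` and `lambda` in
#' `grid` (a single lambda shared across layers by default), scores each fit
#' by its proportion-of-deviance (pod), refits the best combination to
#' convergence, and merges clusters smaller than `min_cluster_size` into
#' their nearest neighbour.
#'
#' @param datasets list of feature x sample matrices.
#' @param K_range candidate cluster counts; default `2:3`.
#' @param grid lambda grid from [lambda_grid()].
#' @param min_cluster_size minimum final cluster size; default 10.
#' @param max_iter_tune EM cap during tuning; default 20.
#' @param seed seed for the labeling step.
#' @param per_layer_lambda when TRUE, `grid` is searched independently per
#'   layer (combinatorial; only sensible for short grids). Default FALSE.
#' @return the refit `"icluster_model"` with merged `labels`, plus `tuning`
#'   (data frame of K, lambda, pod) attached.
#' @export
tune_and_cluster <- function(datasets, K_range = 2:3, grid = lambda_grid(101),
                             min_cluster_size = 10, max_iter_tune = 20,
                             seed = 1L, per_layer_lambda = FALSE) {
  combos <- if (per_layer_lambda) {
    lam <- as.matrix(expand.grid(rep(list(grid), length(datasets))))
    do.call(rbind, lapply(K_range, function(K)
      cbind(K = K, lam)))
  } else {
    as.matrix(expand.grid(K = K_range, lambda = grid))
  }
  ## shared deterministic initialization across the whole grid
  Xs <- do.call(rbind, lapply(datasets, function(x) standardize_rows(unclass(x))))
  qmax <- max(K_range) - 1L
  sv <- svd(Xs, nu = qmax, nv = 0)
  W0 <- sv$u %*% diag(sv$d[seq_len(qmax)] / sqrt(ncol(Xs)), qmax, qmax)
  A0 <- icluster_cosim(Xs)
  scores <- numeric(nrow(combos)); degen <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fit <- icluster_fit(datasets, K = combos[i, "K"],
                        lambdas = combos[i, -1],
                        max_iter = max_iter_tune, seed = seed,
                        W_init = W0, A_cor = A0)
    scores[i] <- fit$pod
    degen[i] <- fit$degenerate
  }
  if (all(degen)) stop("all (K, lambda) fits degenerate")
  scores[degen] <- Inf
  ## minimal pod, ties to the smaller K
  ord <- order(scores, combos[, "K"])
  best <- ord[1]
  ## near-uniform pod across cluster counts means the extra clusters explain
  ## no real structure: fall back to the smallest K with a warning
  in_min_K <- which(combos[, "K"] == min(K_range) & is.finite(scores))
  best_min_K <- in_min_K[which.min(scores[in_min_K])]
  if (combos[best, "K"] != min(K_range) &&
      (scores[best_min_K] - scores[best]) < 0.01 * scores[best_min_K]) {
    warning("pod nearly uniform across cluster counts ",
            "(improvement < 1%): little cluster structure; ",
            "returning the smallest K")
    best <- best_min_K
  }
  fit <- icluster_fit(datasets, K = combos[best, "K"], lambdas = combos[best, -1],
                      max_iter = 200, tol = 1e-6, seed = seed,
                      W_init = W0, A_cor = A0)
  fit$labels_unmerged <- fit$labels
  fit$labels <- merge_small_clusters(fit$labels, fit$Z, min_cluster_size)
  fit$tuning <- data.frame(K = combos[, "K"],
                           lambda = if (per_layer_lambda) NA else combos[, "lambda"],
                           pod = scores)
  fit
}

#' Cluster-pair overlap between two partitions
#'
#' For every cluster pair (a in A, b in B) the Jaccard overlap fraction
#' `|a n b| / |a u b|` and, in the default mode, a one-sided hypergeometric
#' p-value for an overlap at least as large. `mode = "ks"` additionally
#' performs a Kolmogorov-Smirnov test comparing the overlap fractions of
#' matched (mutually best) cluster pairs against the remaining pairs.
#'
#' @param labels_a,labels_b named cluster label vectors over the same
#'   samples.
#' @param mode `"hypergeometric"` (default) or `"ks"`.
#' @return list with `pairs` (data frame: cluster_a, cluster_b, n_a, n_b,
#'   overlap, overlap_frac, p) and, in ks mode, `ks` (htest).
#' @export
partition_overlap_test <- function(labels_a, labels_b,
                                   mode = c("hypergeometric", "ks")) {
  mode <- match.arg(mode)
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    labels_a <- labels_a[common]; labels_b <- labels_b[common]
  }
  if (length(labels_a) != length(labels_b)) stop("partitions must share samples")
  N <- length(labels_a)
  rows <- list()
  for (a in sort(unique(labels_a))) for (b in sort(unique(labels_b))) {
    ia <- labels_a == a; ib <- labels_b == b
    if (!any(ia) || !any(ib)) next
    k <- sum(ia & ib)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_a = a, cluster_b = b, n_a = sum(ia), n_b = sum(ib), overlap = k,
      overlap_frac = k / sum(ia | ib),
      p = stats::phyper(k - 1, sum(ia), N - sum(ia), sum(ib), lower.tail = FALSE))
  }
  pairs <- do.call(rbind, rows)
  out <- list(pairs = pairs)
  if (mode == "ks") {
    matched <- logical(nrow(pairs))
    for (a in unique(pairs$cluster_a)) {
      sub <- pairs$cluster_a == a
      matched[sub][which.max(pairs$overlap_frac[sub])] <- TRUE
    }
    out$ks <- suppressWarnings(
      stats::ks.test(pairs$overlap_frac[matched], pairs$overlap_frac[!matched]))
  }
  out
}
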