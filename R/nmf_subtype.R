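## Consensus non-negative matrix factorization subtyping: Brunet
## multiplicative updates minimizing generalized Kullback-Leibler divergence,
## a consensus matrix over random restarts, and rank selection by cophenetic
## correlation, dispersion and silhouette with a minimum-cluster-size rule.

#' Generalized KL divergence D(V || WH)
#'
#' Terms with v = 0 contribute only the reconstruction (0 * log(0/x) = 0).
#'
#' @param V non-negative data matrix; `W`, `H` current factors.
#' @param W,H current factor matrices.
#' @return numeric scalar >= 0.
#' @export
kl_divergence <- function(V, W, H) {
  R <- W %*% H
  pos <- V > 0
  sum(V[pos] * log(V[pos] / R[pos])) - sum(V[pos]) + sum(R)
}

#' Embed a real-valued matrix into the non-negative orthant
#'
#' Stacks the positive part over the negative part, the standard embedding
#' that lets real-valued copy-number matrices enter NMF.
#'
#' @param V numeric matrix.
#' @return non-negative matrix with `2 * nrow(V)` rows.
#' @export
nonneg_embed <- function(V) {
  out <- rbind(pmax(V, 0), pmax(-V, 0))
  rownames(out) <- c(paste0(rownames(V), "+"), paste0(rownames(V), "-"))
  out
}

#' Brunet NMF by multiplicative updates
#'
#' Factorizes a non-negative matrix V (features x samples) as W H with k
#' components by the Brunet variant of the multiplicative update rules,
#' which monotonically decrease the generalized KL divergence. Stopping
#' follows the original connectivity rule: the fit ends once the hard
#' sample-to-factor assignment has been unchanged for `conn_stop`
#' iterations (checked every `trace_every`), or when the relative
#' divergence change over a check interval drops below `tol`, or at
#' `max_iter`, whichever comes first.
#'
#' @param V non-negative numeric matrix.
#' @param k rank, `k < min(dim(V))`.
#' @param seed RNG seed for the uniform random initialization.
#' @param max_iter iteration cap; default 2000.
#' @param tol relative divergence-change tolerance; default 1e-6.
#' @param trace_every record the divergence every this many iterations
#'   (also the convergence-check interval); default 10.
#' @param conn_stop stop after this many iterations with an unchanged
#'   sample assignment; default 40. `Inf` disables the connectivity rule.
#' @return object of class `"nmf_model"`: list with `W`, `H`, `k`,
#'   `divergence`, `trace`, `iterations`, `seed`.
#' @export
nmf_factorize <- function(V, k, seed = 1L, max_iter = 2000, tol = 1e-6,
                          trace_every = 10L, conn_stop = 40L) {
  if (any(V < 0)) stop("V must be non-negative")
  if (k >= min(dim(V))) stop("k must be smaller than both dimensions of V")
  set.seed(seed)
  eps <- .Machine$double.eps
  n <- nrow(V); m <- ncol(V)
  scale0 <- sqrt(mean(V) / k)
  W <- matrix(stats::runif(n * k, 0.1, 1) * scale0, n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1) * scale0, k, m)
  d_prev <- kl_divergence(V, W, H)
  trace <- d_prev
  iter_done <- 0L
  lab_prev <- integer(0); lab_stable <- 0L
  for (it in seq_len(max_iter)) {
    ## H update: H <- H * (W' (V / WH)) / colSums(W)
    R <- W %*% H + eps
    H <- H * crossprod(W, V / R) / (colSums(W) + eps)
    ## W update: W <- W * ((V / WH) H') / rowSums(H)
    R <- W %*% H + eps
    W <- W * tcrossprod(V / R, H) / rep(rowSums(H) + eps, each = n)
    iter_done <- it
    if (it %% trace_every == 0L || it == max_iter) {
      d <- kl_divergence(V, W, H)
      trace <- c(trace, d)
      lab <- max.col(t(H))
      if (identical(lab, lab_prev)) {
        lab_stable <- lab_stable + trace_every
      } else {
        lab_stable <- 0L
        lab_prev <- lab
      }
      if (k >= 2L && lab_stable >= conn_stop) break  # meaningless at k = 1
      if (abs(d_prev - d) <= tol * max(abs(d_prev), eps)) break
      d_prev <- d
    }
  }
  structure(list(W = W, H = H, k = k, divergence = kl_divergence(V, W, H),
                 trace = trace, iterations = iter_done, seed = seed),
            class = "nmf_model")
}

#' @export
print.nmf_model <- function(x, ...) {
  cat(sprintf("Brunet NMF: rank %d, %d iterations, KL divergence %.6g\n",
              x$k, x$iterations, x$divergence))
  invisible(x)
}

## hard sample assignment: argmax over the k rows of H
nmf_hard_labels <- function(model) {
  apply(model$H, 2, which.max)
}

#' Consensus NMF clustering over random restarts
#'
#' Runs `n_runs` random restarts of [nmf_factorize()] at rank `k` (restart r
#' uses seed `seed + r`), hard-assigns each sample to its dominant factor,
#' and builds the sample co-assignment consensus matrix. Final labels come
#' from average-linkage hierarchical clustering of `1 - consensus` cut at k.
#' Restarts in which some factor attracts no sample are re-seeded (logged).
#'
#' Stability metrics: `cophenetic` is the correlation between consensus
#' distances and the dendrogram's cophenetic distances; `dispersion` is the
#' mean of `4 * (c_ij - 1/2)^2` over off-diagonal consensus entries (1 when
#' the consensus is binary, 0 when every entry is 1/2); `silhouette` is the
#' mean silhouette width of the final labels on `1 - consensus`.
#'
#' @param V non-negative matrix (features x samples).
#' @param k rank / number of subtypes.
#' @param n_runs number of restarts; default 50.
#' @param seed base seed.
#' @param ... further arguments to [nmf_factorize()].
#' @return object of class `"nmf_consensus"`: list with `consensus`, `k`,
#'   `n_runs`, `cophenetic`, `dispersion`, `silhouette`, `labels`,
#'   `cluster_sizes`, `seed`.
#' @export
consensus_cluster <- function(V, k, n_runs = 50, seed = 1L, ...) {
  m <- ncol(V)
  co <- matrix(0, m, m)
  r <- 0L; attempts <- 0L
  while (r < n_runs) {
    run_seed <- as.integer((seed + r + 1L + attempts * 100003L) %% .Machine$integer.max)
    model <- nmf_factorize(V, k, seed = run_seed, ...)
    lab <- nmf_hard_labels(model)
    if (length(unique(lab)) < k && attempts <= 2L * n_runs) {
      ## an empty factor: re-seed the run; after the attempt budget is spent
      ## such runs are accepted and the rank left to the min-cluster-size rule
      attempts <- attempts + 1L
      tri_log("consensus_cluster: empty factor at rank %d, re-seeding run %d",
              k, r + 1L)
      next
    }
    co <- co + outer(lab, lab, "==")
    r <- r + 1L
  }
  consensus <- co / n_runs
  dimnames(consensus) <- list(colnames(V), colnames(V))
  dmat <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(dmat, method = "average")
  labels <- stats::cutree(hc, k = k)
  coph <- suppressWarnings(stats::cor(dmat, stats::cophenetic(hc)))
  if (!is.finite(coph)) coph <- 1  # zero-variance distances: perfectly stable
  off <- consensus[row(consensus) != col(consensus)]
  dispersion <- if (length(off)) mean(4 * (off - 0.5)^2) else 1
  sil <- if (length(unique(labels)) > 1)
    mean(cluster::silhouette(labels, dmat)[, "sil_width"]) else NA_real_
  structure(list(consensus = consensus, k = k, n_runs = n_runs,
                 cophenetic = coph, dispersion = dispersion, silhouette = sil,
                 labels = labels, cluster_sizes = as.integer(table(labels)),
                 seed = seed),
            class = "nmf_consensus")
}

#' @export
print.nmf_consensus <- function(x, ...) {
  cat(sprintf(
    "NMF consensus: k = %d (%d runs); cophenetic %.3f, dispersion %.3f, silhouette %.3f\n",
    x$k, x$n_runs, x$cophenetic, x$dispersion, x$silhouette))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.nmf_consensus <- function(x, ...) {
  ord <- order(x$labels)
  graphics::image(x$consensus[ord, ord], axes = FALSE,
                  main = sprintf("consensus, k = %d", x$k), ...)
  invisible(x)
}

#' Select the NMF rank
#'
#' Ranks whose best partition contains a cluster smaller than
#' `min_cluster_size` are disqualified; among the rest the rank maximizing
#' the cophenetic coefficient wins, with ties broken by silhouette, then
#' dispersion, then the smaller k.
#'
#' @param results list of [consensus_cluster()] results over candidate ranks.
#' @param min_cluster_size minimum subtype size; default 10.
#' @return the selected k (integer), with the metric table attached as
#'   attribute `"metrics"`.
#' @export
select_rank <- function(results, min_cluster_size = 10) {
  if (length(results) < 2) stop("at least 2 candidate ranks required")
  metrics <- do.call(rbind, lapply(results, function(res) data.frame(
    k = res$k, cophenetic = res$cophenetic, dispersion = res$dispersion,
    silhouette = res$silhouette, min_cluster = min(res$cluster_sizes))))
  ok <- metrics$min_cluster >= min_cluster_size
  if (!any(ok))
    stop("all candidate ranks disqualified by min_cluster_size = ",
         min_cluster_size, "; smallest clusters: ",
         paste(metrics$k, metrics$min_cluster, sep = ":", collapse = ", "))
  cand <- metrics[ok, ]
  ord <- order(-cand$cophenetic, -cand$silhouette, -cand$dispersion, cand$k)
  structure(as.integer(cand$k[ord[1]]), metrics = metrics)
}
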