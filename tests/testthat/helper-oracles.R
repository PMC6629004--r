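## Independent brute-force oracles used to check the package's fast paths.
## Each is written from the definition, not from the implementation it checks.

options(triomics.verbose = FALSE)

## all 2x3 (or 2xC) tables with the same margins as `tab`, and the exact
## (Freeman-Halton) p: sum of probabilities of tables no more probable than
## the observed one
oracle_exact_rxc_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  logp_tab <- function(t)
    sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
    sum(lgamma(t + 1))
  stopifnot(nrow(tab) == 2)
  C <- ncol(tab)
  obs <- logp_tab(tab)
  total <- 0
  ## enumerate first row; second row is forced by the margins
  grid <- expand.grid(lapply(cs[-C], function(m) 0:min(m, rs[1])))
  for (i in seq_len(nrow(grid))) {
    r1 <- as.numeric(grid[i, ])
    last <- rs[1] - sum(r1)
    if (last < 0 || last > cs[C]) next
    t1 <- c(r1, last)
    t2 <- cs - t1
    if (any(t2 < 0)) next
    lp <- logp_tab(rbind(t1, t2))
    if (lp <= obs + 1e-7) total <- total + exp(lp)
  }
  total
}

## pairwise merge oracle for copy-number regions: repeatedly merge the first
## qualifying pair (reciprocal overlap >= frac), value = mean over original
## constituents, until no pair qualifies
oracle_merge_segments <- function(segments, frac = 0.5) {
  segs <- split(segments, paste(segments$sample_id, segments$chrom))
  out <- lapply(segs, function(ss) {
    parts <- lapply(seq_len(nrow(ss)), function(i)
      list(start = ss$start[i], end = ss$end[i], probes = ss$num_probes[i],
           vals = ss$seg_value[i]))
    repeat {
      merged <- FALSE
      for (i in seq_along(parts)) {
        for (j in seq_along(parts)) {
          if (j <= i) next
          a <- parts[[i]]; b <- parts[[j]]
          ov <- min(a$end, b$end) - max(a$start, b$start)
          if (ov >= frac * (a$end - a$start) && ov >= frac * (b$end - b$start)) {
            parts[[i]] <- list(start = min(a$start, b$start),
                               end = max(a$end, b$end),
                               probes = a$probes + b$probes,
                               vals = c(a$vals, b$vals))
            parts[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    data.frame(sample_id = ss$sample_id[1], chrom = ss$chrom[1],
               start = sapply(parts, `[[`, "start"),
               end = sapply(parts, `[[`, "end"),
               num_probes = sapply(parts, `[[`, "probes"),
               seg_value = sapply(parts, function(p) mean(p$vals)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$chrom, res$start), ]
}

## direct generalized KL divergence from the definition
oracle_kl <- function(V, W, H) {
  R <- W %*% H
  s <- 0
  for (i in seq_len(nrow(V))) for (j in seq_len(ncol(V))) {
    v <- V[i, j]; r <- R[i, j]
    s <- s + if (v > 0) v * log(v / r) - v + r else r
  }
  s
}

## two-group log-rank chi-square from the observed-minus-expected definition
oracle_logrank_chi2 <- function(times, events, groups) {
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  stopifnot(length(gs) == 2)
  taus <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in taus) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & groups == gs[1])
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & groups == gs[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

## product-limit survival by hand
oracle_km <- function(times, events, at) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t > at) break
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n)
  }
  s
}

## frozen reference values for the skewness test, computed independently
## with scipy.stats.skewtest on the vectors below
skew_right_x <- c(
  3.08657, 4.92576, 3.44016, 2.91954, 4.1784, 0.201588, 2.58405, 1.52756,
  5.43086, 2.25253, 1.91928, 2.19397, -1.10772, 1.48441, 0.048912, 0.81152,
  -1.37642, -0.436371, -1.29109, -0.775679, 0.903063, -1.48058, -0.534093,
  0.163789, -0.66847, -0.25229, -0.221862, 0.418139, -0.431255, 0.272261,
  0.056819, 0.424569, 0.224943, 1.65768, -0.663676, 1.19919, -0.402612,
  -0.957926, 1.21119, -0.439506, -0.387636, -1.38868, -2.0982, 0.634301,
  -1.16527, 0.778273, 1.84817, -0.114798, -1.12661, 0.394199, 0.761728,
  -0.26179, 0.017464, 1.33527, 1.26545, 0.709978, -0.866401, -0.053676,
  0.602917, -0.211866)
skew_right_stat <- 3.239108900066
skew_right_p <- 1.199037831527e-03
skew_sym_y <- c(
  -1.22004, -1.53078, -1.26402, -1.34321, -0.902223, 2.29135, -1.60128,
  1.7738, 0.835169, 0.279499, -1.6548, -0.913388, 3.94711, 0.198136,
  1.07641, 1.32606, 2.11128, -0.475033, -1.22039, -0.119228, -0.521639,
  1.58135, 0.379221, 0.478541, 0.290019, 2.45674, -1.08525, -0.956712,
  1.77026, -0.21282, 0.721756, -1.45798, 0.046662, 0.863668, -2.65487,
  -1.38987, 0.846125, 4.49762, 0.924572, -0.117839, -1.69042, 0.783252,
  -5.00281, -0.099059, -0.660289, -1.03883, 4.64071, -4.94708, -0.04455,
  0.137958)
skew_sym_stat <- 0.084491932587
skew_sym_p <- 9.326653167700e-01
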