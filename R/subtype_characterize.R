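## Molecular characterization of a subtype pair: exact contingency tests on
## per-gene aberration states, negative-binomial differential expression,
## candidate-gene intersection, mutation-spectrum contrasts and
## SNV-expression correlations.

#' Exact contingency test on aberration states between two subtypes
#'
#' Builds the 2 x 3 table of subtype x aberration state and computes the
#' exact (Freeman-Halton) p-value: the sum of the probabilities of all
#' tables with the same margins whose probability does not exceed the
#' observed one. State columns with zero total are collapsed away (logged).
#' When the table total exceeds `budget` the test falls back to a chi-square
#' approximation with a logged flag.
#'
#' @param states per-sample state labels (e.g. Gain/Loss/Normal).
#' @param groups per-sample subtype labels; exactly two groups, each with at
#'   least 2 samples.
#' @param budget table-total budget for the exact computation; default 10000.
#' @return the p-value, with attributes `method` (`"fisher"` or
#'   `"chisq"`) and `table`.
#' @export
aberration_contingency_test <- function(states, groups, budget = 10000) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  tab <- table(groups, states)
  zero_cols <- colSums(tab) == 0
  if (any(zero_cols)) {
    tri_log("contingency test: collapsing %d empty state column(s)", sum(zero_cols))
    tab <- tab[, !zero_cols, drop = FALSE]
  }
  if (ncol(tab) < 2) return(structure(1, method = "degenerate", table = tab))
  if (sum(tab) > budget) {
    tri_log("contingency test: table total %d exceeds budget %d, using chi-square",
            sum(tab), budget)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    return(structure(unname(p), method = "chisq", table = tab))
  }
  p <- tryCatch(stats::fisher.test(tab, workspace = 2e7)$p.value,
                error = function(e) {
                  tri_log("contingency test: exact test failed (%s), using chi-square",
                          conditionMessage(e))
                  structure(suppressWarnings(stats::chisq.test(tab)$p.value),
                            fallback = TRUE)
                })
  method <- if (is.null(attr(p, "fallback"))) "fisher" else "chisq"
  structure(unname(min(as.numeric(p), 1)), method = method, table = tab)
}

## ---- negative binomial differential expression ------------------------------

## DESeq-style median-of-ratios size factors
size_factors_mor <- function(counts) {
  loggeo <- rowMeans(log(counts))
  usable <- is.finite(loggeo)
  if (sum(usable) < 10) {
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  apply(counts[usable, , drop = FALSE], 2,
        function(cj) exp(stats::median(log(cj) - loggeo[usable])))
}

#' Differential expression between two groups (NB Wald test)
#'
#' Per-gene negative-binomial Wald test on a two-group design: library sizes
#' are normalized by median-of-ratios size factors, the NB dispersion is
#' estimated by the method of moments on normalized counts and shrunk toward
#' a 1/mean trend, group means are fit by Newton iterations on the NB score
#' equation at the shrunken dispersion, and the log-fold-change is tested
#' with a Wald statistic referred to a t distribution with n - 2 df.
#' All-zero genes are excluded (logged).
#'
#' `method = "deseq2"` delegates to the DESeq2 package (when installed)
#' behind the same interface; the result carries its method tag either way.
#'
#' @param counts [omics_matrix()] with layer `"EXP_COUNTS"`.
#' @param groups per-sample group labels (two groups, >= 3 samples each);
#'   named by sample id or aligned with the matrix columns.
#' @param method `"nbwald"` (default) or `"deseq2"`.
#' @return data frame with `gene_id`, `base_mean`, `log2fc` (second group
#'   level vs first), `p`, `fdr`; attribute `method`.
#' @export
differential_expression <- function(counts, groups, method = c("nbwald", "deseq2")) {
  method <- match.arg(method)
  if (!is.null(names(groups))) {
    samples <- intersect(colnames(counts), names(groups))
    counts <- counts[, samples, drop = FALSE]
    groups <- groups[samples]
  }
  ## respect incoming factor levels: log2fc is second level vs first
  groups <- droplevels(if (is.factor(groups)) groups else as.factor(groups))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 3)) stop("at least 3 samples per group required")
  C <- unclass(counts)
  nonzero <- rowSums(C) > 0
  if (any(!nonzero))
    tri_log("differential_expression: excluded %d all-zero gene(s)", sum(!nonzero))
  C <- C[nonzero, , drop = FALSE]

  if (method == "deseq2") {
    if (!requireNamespace("DESeq2", quietly = TRUE))
      stop("DESeq2 not installed")
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = round(C), colData = data.frame(group = groups),
      design = ~ group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds, cooksCutoff = FALSE, independentFiltering = FALSE)
    out <- data.frame(gene_id = rownames(C), base_mean = res$baseMean,
                      log2fc = res$log2FoldChange, p = res$pvalue,
                      fdr = res$padj, row.names = NULL)
    return(structure(out, method = "deseq2"))
  }

  sf <- size_factors_mor(C)
  Q <- sweep(C, 2, sf, "/")
  g1 <- groups == levels(groups)[1]; g2 <- !g1
  n1 <- sum(g1); n2 <- sum(g2)

  ## moment dispersion on normalized counts, pooled within groups
  mu1 <- rowMeans(Q[, g1, drop = FALSE]); mu2 <- rowMeans(Q[, g2, drop = FALSE])
  v1 <- apply(Q[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(Q[, g2, drop = FALSE], 1, stats::var)
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mu0 <- rowMeans(Q)
  mean_inv_sf <- mean(1 / sf)
  alpha_mom <- (vpool - mu0 * mean_inv_sf) / mu0^2
  ## 1/mean dispersion trend fit on informative genes, then shrinkage
  pos <- which(alpha_mom > 1e-6 & mu0 > 1)
  alpha_tr <- if (length(pos) >= 20) {
    co <- stats::coef(stats::lm(alpha_mom[pos] ~ I(1 / mu0[pos])))
    pmax(co[1] + co[2] / mu0, 1e-6)
  } else rep(max(stats::median(alpha_mom, na.rm = TRUE), 1e-6), length(mu0))
  w <- (n1 + n2) / (n1 + n2 + 10)
  alpha <- pmax(w * pmax(alpha_mom, 0) + (1 - w) * alpha_tr, 1e-8)

  ## NB group means at fixed dispersion: Newton on the score equation
  nb_group_mean <- function(sub, alpha) {
    Cs <- C[, sub, drop = FALSE]; s <- sf[sub]
    mu <- pmax(rowSums(Cs) / sum(s), 1e-8)
    for (it in 1:12) {
      S <- sweep(matrix(mu, nrow(Cs), ncol(Cs)), 2, s, "*")   # mu_i * s_j
      denom <- 1 + alpha * S
      f <- rowSums((Cs - S) / denom)
      fp <- -rowSums(sweep((1 + alpha * Cs) / denom^2, 2, s, "*"))
      mu <- pmax(mu - f / fp, 1e-10)
    }
    info <- rowSums(sweep(matrix(mu, nrow(Cs), ncol(Cs)), 2, s, "*") /
                      (1 + alpha * sweep(matrix(mu, nrow(Cs), ncol(Cs)), 2, s, "*")))
    list(mu = mu, var_eta = 1 / info)
  }
  fit1 <- nb_group_mean(g1, alpha)
  fit2 <- nb_group_mean(g2, alpha)
  beta <- log(fit2$mu) - log(fit1$mu)
  beta <- pmax(pmin(beta, 20 * log(2)), -20 * log(2))
  se <- sqrt(fit1$var_eta + fit2$var_eta)
  stat <- beta / se
  p <- 2 * stats::pt(-abs(stat), df = n1 + n2 - 2)
  out <- data.frame(gene_id = rownames(C), base_mean = mu0,
                    log2fc = beta / log(2), p = p, fdr = bh_adjust(p),
                    row.names = NULL)
  structure(out, method = "nbwald_moment")
}

#' Intersect the three per-gene contrasts
#'
#' Genes passing the CNV-state contingency test, the MET-state contingency
#' test and the differential-expression test, all at threshold `p`.
#'
#' @param diffs data frame with `gene_id`, `fisher_p_cnv`, `fisher_p_met`,
#'   `de_p` (missing p-values fail).
#' @param p threshold; default 0.05.
#' @return character vector of candidate gene ids.
#' @export
intersect_candidates <- function(diffs, p = 0.05) {
  ok <- !is.na(diffs$fisher_p_cnv) & diffs$fisher_p_cnv < p &
    !is.na(diffs$fisher_p_met) & diffs$fisher_p_met < p &
    !is.na(diffs$de_p) & diffs$de_p < p
  diffs$gene_id[ok]
}

#' Top differing genes for display
#'
#' Ranks genes by the smallest of their three contrast p-values and returns
#' the top `n`.
#'
#' @param diffs as in [intersect_candidates()].
#' @param n number of genes; default 100.
#' @return character vector of gene ids.
#' @export
top_diff_genes <- function(diffs, n = 100) {
  score <- pmin(diffs$fisher_p_cnv, diffs$fisher_p_met, diffs$de_p, na.rm = TRUE)
  diffs$gene_id[order(score)][seq_len(min(n, nrow(diffs)))]
}

#' Mutation-spectrum comparison between two subtypes
#'
#' Per gene, a 2 x 2 Fisher exact test of mutated/not-mutated x subtype,
#' ranked by p. Genes carried by fewer than `min_carriers` samples overall
#' are skipped. Mutations should be pre-filtered with [filter_snv()].
#'
#' @param mutations mutation data frame (`sample_id`, `gene_name`).
#' @param groups named per-sample subtype labels (two groups); samples
#'   absent from `groups` are ignored.
#' @param min_carriers minimum number of mutated samples; default 3.
#' @param alternative passed to [stats::fisher.test()]; default two-sided.
#' @return data frame with `gene_name`, carrier counts per group, group
#'   sizes and `fisher_p`, ordered by p.
#' @export
mutation_spectrum_compare <- function(mutations, groups, min_carriers = 3,
                                      alternative = "two.sided") {
  samples <- names(groups)
  if (is.null(samples)) stop("`groups` must be named by sample id")
  groups <- stats::setNames(droplevels(as.factor(as.character(groups))), samples)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  mutations <- mutations[mutations$sample_id %in% samples, , drop = FALSE]
  nA <- sum(groups == levels(groups)[1]); nB <- sum(groups == levels(groups)[2])
  rows <- lapply(split(mutations, mutations$gene_name), function(mm) {
    carriers <- unique(mm$sample_id)
    if (length(carriers) < min_carriers) return(NULL)
    a <- sum(groups[carriers] == levels(groups)[1])
    b <- length(carriers) - a
    tab <- matrix(c(a, nA - a, b, nB - b), nrow = 2)
    data.frame(gene_name = mm$gene_name[1], carriers_a = a, carriers_b = b,
               n_a = nA, n_b = nB,
               fisher_p = stats::fisher.test(tab, alternative = alternative)$p.value)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_name = character(), carriers_a = integer(),
                      carriers_b = integer(), n_a = integer(), n_b = integer(),
                      fisher_p = numeric()))
  rownames(out) <- NULL
  out[order(out$fisher_p), , drop = FALSE]
}

#' Correlation between expression and mutation carrier status
#'
#' Point-biserial Pearson correlation between a gene's expression and the
#' 0/1 carrier indicator of a specific mutation, with two-sided p-value.
#' A constant carrier vector cannot be tested and returns NULL (logged).
#'
#' @param expression per-sample expression values.
#' @param carrier per-sample 0/1 carrier indicator.
#' @param target_gene,snv_gene,hgvs_c optional labels copied to the output.
#' @return one-row data frame (`target_gene`, `snv_gene`, `hgvs_c`, `corr`,
#'   `corr_p`, `n`), or NULL.
#' @export
snv_expression_correlation <- function(expression, carrier, target_gene = NA,
                                       snv_gene = NA, hgvs_c = NA) {
  if (length(expression) != length(carrier) || length(expression) < 3)
    stop("need >= 3 paired samples")
  if (!all(carrier %in% c(0, 1))) stop("carrier must be 0/1")
  if (length(unique(carrier)) < 2 || stats::sd(expression) == 0) {
    tri_log("snv_expression_correlation: constant vector for %s/%s, omitted",
            target_gene, snv_gene)
    return(NULL)
  }
  ct <- stats::cor.test(expression, carrier, method = "pearson")
  data.frame(target_gene = target_gene, snv_gene = snv_gene, hgvs_c = hgvs_c,
             corr = unname(ct$estimate), corr_p = ct$p.value,
             n = length(expression), stringsAsFactors = FALSE)
}
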