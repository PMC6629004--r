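## CNVcor / METcor gene screen: per-gene Pearson correlation between a
## molecular layer (copy number or promoter methylation) and expression,
## Fisher-z characterization of the correlation distribution, chromosomal
## enrichment, set overlap and a prognostic sub-screen.

#' Fisher z-transform of a correlation coefficient
#'
#' `z = ln((1 + r) / (1 - r))`, i.e. `2 * artanh(r)`. To keep z finite,
#' `|r|` is capped at `1 - cap` before the transform; capped values are the
#' caller's responsibility to flag.
#'
#' @param r Pearson correlation(s) in \[-1, 1\].
#' @param cap cap distance from |r| = 1; default 1e-12.
#' @return z value(s).
#' @export
fisher_z <- function(r, cap = 1e-12) {
  r <- pmax(pmin(r, 1 - cap), -1 + cap)
  log((1 + r) / (1 - r))
}

#' Per-gene correlation between a molecular layer and expression
#'
#' For every gene shared by the two matrices, the Pearson correlation over
#' the shared samples, its two-sided t-test p-value (n - 2 df) and the
#' Fisher z-value. Genes with fewer than 3 complete pairs or zero variance
#' in either vector are omitted (logged).
#'
#' @param molecular [omics_matrix()] with layer `"CNV"` or `"MET"`.
#' @param expression [omics_matrix()] with layer `"EXP_FPKM"`.
#' @param layer_label label stored in the result (`"CNVcor"` or `"METcor"`);
#'   inferred from the molecular layer when missing.
#' @return data frame with `gene_id`, `r`, `z`, `p`, `n`, `capped`, `layer`.
#' @export
gene_correlation <- function(molecular, expression, layer_label = NULL) {
  if (is.null(layer_label))
    layer_label <- if (omics_layer(molecular) == "CNV") "CNVcor" else "METcor"
  genes <- intersect(rownames(molecular), rownames(expression))
  samples <- intersect(colnames(molecular), colnames(expression))
  if (length(samples) < 3) stop("fewer than 3 shared samples")
  X <- unclass(molecular)[genes, samples, drop = FALSE]
  Y <- unclass(expression)[genes, samples, drop = FALSE]
  ok_pair <- is.finite(X) & is.finite(Y)
  n <- rowSums(ok_pair)
  X[!ok_pair] <- NA; Y[!ok_pair] <- NA
  mx <- rowMeans(X, na.rm = TRUE); my <- rowMeans(Y, na.rm = TRUE)
  sxx <- rowSums((X - mx)^2, na.rm = TRUE)
  syy <- rowSums((Y - my)^2, na.rm = TRUE)
  sxy <- rowSums((X - mx) * (Y - my), na.rm = TRUE)
  omit <- n < 3 | sxx <= 0 | syy <= 0
  if (any(omit))
    tri_log("gene_correlation: omitted %d gene(s) with < 3 complete pairs or zero variance",
            sum(omit))
  r <- sxy / sqrt(sxx * syy)
  r <- pmax(pmin(r, 1), -1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out <- data.frame(gene_id = genes, r = r, z = fisher_z(r), p = p, n = n,
                    capped = abs(r) >= 1 - 1e-12, layer = layer_label,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[!omit, , drop = FALSE]
}

#' Select correlated genes at a significance threshold
#'
#' @param records output of [gene_correlation()] for one layer.
#' @param p_set p-value threshold; default 0.01.
#' @return character vector of selected gene ids, with the selected set's
#'   median z attached as attribute `"median_z"`.
#' @export
screen_corgenes <- function(records, p_set = 0.01) {
  sel <- records$gene_id[records$p < p_set]
  structure(sel, median_z = if (length(sel))
    stats::median(records$z[records$p < p_set]) else NA_real_)
}

#' D'Agostino skewness test for a z-value distribution
#'
#' Tests whether the distribution of Fisher z-values is skewed away from
#' symmetry (a right shift indicates predominantly positive correlations, a
#' left shift negative ones). Uses D'Agostino's normalizing transformation
#' of the sample skewness.
#'
#' @param z_values numeric vector, at least 20 values (the approximation is
#'   unreliable below that).
#' @return list with `statistic` (approximately standard normal under
#'   symmetry), `skewness`, `p` (two-sided) and `direction` (`"right"`,
#'   `"left"` or `"none"`; `"none"` when p >= 0.05).
#' @export
zshift_test <- function(z_values) {
  z_values <- z_values[is.finite(z_values)]
  n <- length(z_values)
  if (n < 20) stop("at least 20 values required")
  x <- z_values - mean(z_values)
  m2 <- mean(x^2); m3 <- mean(x^3)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  zstat <- delta * asinh(y / alpha)
  p <- 2 * stats::pnorm(-abs(zstat))
  med <- stats::median(z_values)
  direction <- if (p >= 0.05 || med == 0) "none" else
    if (med > 0) "right" else "left"
  list(statistic = zstat, skewness = b1, p = p, direction = direction)
}

#' Prognostic sub-screen of a gene set
#'
#' Retains the genes whose molecular value is associated with overall
#' survival. Default mode fits a univariate Cox model on the continuous
#' value (Wald p); `mode = "logrank"` instead median-splits the value and
#' runs a log-rank test.
#'
#' @param genes candidate gene ids.
#' @param values [omics_matrix()] holding the molecular values.
#' @param clinical clinical data frame with `sample_id`, `os_time`,
#'   `os_event`.
#' @param p_surv significance threshold; default 0.05.
#' @param mode `"cox"` (default) or `"logrank"`.
#' @return data frame with `gene_id`, `p`, `coef` (Cox mode) and logical
#'   `selected`; constant-valued genes are omitted (logged).
#' @export
prognostic_screen <- function(genes, values, clinical, p_surv = 0.05,
                              mode = c("cox", "logrank")) {
  mode <- match.arg(mode)
  samples <- intersect(colnames(values), clinical$sample_id)
  if (length(samples) < 20) stop("fewer than 20 samples with clinical follow-up")
  cl <- clinical[match(samples, clinical$sample_id), ]
  if (sum(cl$os_event) < 1) stop("no events in cohort")
  genes <- intersect(genes, rownames(values))
  res <- lapply(genes, function(g) {
    v <- unclass(values)[g, samples]
    if (length(unique(v)) < 2) return(NULL)
    if (mode == "cox") {
      fit <- tryCatch(cox_univariate(v, cl$os_time, cl$os_event),
                      error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      data.frame(gene_id = g, p = fit$p, coef = fit$coef)
    } else {
      grp <- median_split(v)
      lr <- logrank_test(cl$os_time, cl$os_event, grp)
      data.frame(gene_id = g, p = lr$p, coef = NA_real_)
    }
  })
  dropped <- sum(vapply(res, is.null, logical(1)))
  if (dropped)
    tri_log("prognostic_screen: omitted %d constant or unfittable gene(s)", dropped)
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), p = numeric(), coef = numeric())
  out$selected <- out$p < p_surv
  rownames(out) <- NULL
  out
}

#' Chromosomal enrichment of a gene set
#'
#' Per chromosome, a one-sided Fisher exact test (enrichment only) on the
#' 2x2 table in-set/out-of-set x on-chromosome/off-chromosome, with BH
#' adjustment across the tested chromosomes. Chromosomes absent from the
#' universe are skipped.
#'
#' @param gene_set character vector of gene ids (subset of the universe).
#' @param universe gene model data frame (`gene_id`, `chrom`).
#' @return data frame with `chrom`, `gene_count`, `fisher_p`, `fdr`, ordered
#'   by p.
#' @export
chromosome_enrichment <- function(gene_set, universe) {
  gene_set <- intersect(gene_set, universe$gene_id)
  in_set <- universe$gene_id %in% gene_set
  chroms <- unique(universe$chrom)
  rows <- lapply(chroms, function(ch) {
    on <- universe$chrom == ch
    if (!any(on)) return(NULL)
    tab <- matrix(c(sum(in_set & on), sum(in_set & !on),
                    sum(!in_set & on), sum(!in_set & !on)),
                  nrow = 2, byrow = TRUE)
    data.frame(chrom = ch, gene_count = tab[1, 1],
               fisher_p = stats::fisher.test(tab, alternative = "greater")$p.value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$fisher_p)
  out[order(out$fisher_p), , drop = FALSE]
}

#' Hypergeometric overlap test between two gene sets
#'
#' One-sided p-value for observing at least the given overlap when drawing
#' the two sets independently from a common universe.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @param universe_size size of the common universe.
#' @return list with `overlap` and `p`.
#' @export
set_overlap_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(set_a) > universe_size || length(set_b) > universe_size)
    stop("set larger than universe")
  k <- length(intersect(set_a, set_b))
  p <- stats::phyper(k - 1, length(set_a), universe_size - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = k, p = p)
}

#' Simple composition breakdowns
#'
#' Proportions of gene types in a gene set and of methylation probe region
#' classes, as reported alongside the correlation screen.
#'
#' @param gene_set gene ids; `universe` the gene model; `probes` the probe
#'   annotation.
#' @return list with `gene_type_props` and `region_class_props` (either may
#'   be NULL when its input is missing).
#' @param universe gene model data frame.
#' @param probes probe annotation data frame.
#' @export
composition_breakdown <- function(gene_set = NULL, universe = NULL, probes = NULL) {
  gt <- if (!is.null(gene_set) && !is.null(universe)) {
    tt <- table(universe$gene_type[universe$gene_id %in% gene_set])
    prop.table(tt)
  }
  rc <- if (!is.null(probes)) prop.table(table(probes$region_class))
  list(gene_type_props = gt, region_class_props = rc)
}
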