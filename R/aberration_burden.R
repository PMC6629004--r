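## Per-sample aberration burdens: gene-level CNV and methylation values are
## classified into aberration states at fixed beta thresholds, counted per
## sample, and the burden types correlated across samples.

#' Aberration thresholds
#'
#' Copy-number gain/loss and methylation hyper/hypo cutoffs on the beta
#' (segment-mean / methylation-fraction) scale. All comparisons are strict:
#' values exactly at a threshold are Normal.
#'
#' @param cnv_gain,cnv_loss CNV cutoffs; defaults +0.3 / -0.3.
#' @param met_hyper,met_hypo methylation cutoffs; defaults 0.8 / 0.2.
#' @return named list of the four thresholds.
#' @export
aberration_thresholds <- function(cnv_gain = 0.3, cnv_loss = -0.3,
                                  met_hyper = 0.8, met_hypo = 0.2) {
  stopifnot(cnv_loss < cnv_gain, met_hypo < met_hyper)
  list(cnv_gain = cnv_gain, cnv_loss = cnv_loss,
       met_hyper = met_hyper, met_hypo = met_hypo)
}

#' Classify a value into an aberration state
#'
#' CNV: Gain when beta > `cnv_gain`, Loss when beta < `cnv_loss`, otherwise
#' Normal. MET: Hyper when beta > `met_hyper`, Hypo when beta < `met_hypo`,
#' otherwise Normal. Vectorized; boundary values map to Normal.
#'
#' @param value numeric value(s); for MET must lie in \[0, 1\].
#' @param layer `"CNV"` or `"MET"`.
#' @param thresholds from [aberration_thresholds()].
#' @return character vector of states.
#' @export
classify_aberration <- function(value, layer = c("CNV", "MET"),
                                thresholds = aberration_thresholds()) {
  layer <- match.arg(layer)
  if (layer == "MET" && any(value < 0 | value > 1, na.rm = TRUE))
    stop("MET beta values must lie in [0, 1]")
  if (layer == "CNV")
    ifelse(value > thresholds$cnv_gain, "Gain",
           ifelse(value < thresholds$cnv_loss, "Loss", "Normal"))
  else
    ifelse(value > thresholds$met_hyper, "Hyper",
           ifelse(value < thresholds$met_hypo, "Hypo", "Normal"))
}

#' Per-sample aberration burden counts
#'
#' Counts, for every sample in the shared universe of the two gene-level
#' matrices, the number of genes in each aberration state.
#'
#' @param cnv,met gene-level [omics_matrix()] objects without missing values.
#' @param thresholds from [aberration_thresholds()].
#' @return data frame with `sample_id`, `n_gain`, `n_loss`, `n_methyper`,
#'   `n_methypo`.
#' @export
burden_counts <- function(cnv, met, thresholds = aberration_thresholds()) {
  samples <- intersect(colnames(cnv), colnames(met))
  C <- unclass(cnv)[, samples, drop = FALSE]
  M <- unclass(met)[, samples, drop = FALSE]
  data.frame(
    sample_id = samples,
    n_gain = colSums(C > thresholds$cnv_gain),
    n_loss = colSums(C < thresholds$cnv_loss),
    n_methyper = colSums(M > thresholds$met_hyper),
    n_methypo = colSums(M < thresholds$met_hypo),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-correlations between burden types
#'
#' Pearson correlation (with two-sided p) across samples for all six pairs
#' of the four burden counts. A zero-variance burden vector yields a missing
#' correlation for its pairs (logged).
#'
#' @param profiles output of [burden_counts()]; at least 10 samples.
#' @return data frame with `pair`, `r`, `p`.
#' @export
burden_correlations <- function(profiles) {
  if (nrow(profiles) < 10) stop("at least 10 burden profiles required")
  cols <- c(Gain = "n_gain", Loss = "n_loss",
            MetHyper = "n_methyper", MetHypo = "n_methypo")
  combos <- utils::combn(names(cols), 2)
  rows <- apply(combos, 2, function(pr) {
    x <- profiles[[cols[pr[1]]]]; y <- profiles[[cols[pr[2]]]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      tri_log("burden_correlations: zero-variance burden in pair %s-%s",
              pr[1], pr[2])
      return(data.frame(pair = paste(pr, collapse = "-"),
                        r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(pair = paste(pr, collapse = "-"),
               r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, rows)
}
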