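#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules: the omics matrix container,
## lightweight logging, and small numeric utilities.

#' Construct an omics matrix
#'
#' The shared container for all three molecular layers: a numeric
#' feature-by-sample matrix with unique row (feature) and column (sample)
#' names and a `layer` attribute. Layer-specific invariants are enforced:
#' methylation beta values must lie in \[0, 1\] (missing allowed), FPKM must
#' be non-negative, and counts must be non-negative integers.
#'
#' @param values numeric matrix, features in rows, samples in columns; both
#'   dimensions named.
#' @param layer one of `"CNV"`, `"MET"`, `"EXP_FPKM"`, `"EXP_COUNTS"`.
#' @return the matrix with class `"omics_matrix"` and a `layer` attribute.
#' @export
omics_matrix <- function(values, layer = c("CNV", "MET", "EXP_FPKM", "EXP_COUNTS")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  v <- values[is.finite(values)]
  if (layer == "MET" && length(v) && (min(v) < 0 || max(v) > 1))
    stop("MET beta values must lie in [0, 1]")
  if (layer %in% c("EXP_FPKM", "EXP_COUNTS") && length(v) && min(v) < 0)
    stop("expression values must be non-negative")
  if (layer == "EXP_COUNTS" && length(v) && any(abs(v - round(v)) > 1e-8))
    stop("EXP_COUNTS values must be integers")
  structure(values, layer = layer, class = c("omics_matrix", class(values)))
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, layer = attr(x, "layer"),
                     class = c("omics_matrix", "matrix", "array"))
  out
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              attr(x, "layer"), nrow(x), ncol(x)))
  if (nrow(x) && ncol(x)) {
    ii <- seq_len(min(5L, nrow(x))); jj <- seq_len(min(5L, ncol(x)))
    print(unclass(x)[ii, jj, drop = FALSE])
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

omics_layer <- function(x) attr(x, "layer")

## message-based logging with a common prefix so pipeline runs are greppable
tri_log <- function(fmt, ..., verbose = getOption("triomics.verbose", TRUE)) {
  if (isTRUE(verbose)) message(sprintf(paste0("[triomics] ", fmt), ...))
  invisible(NULL)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same samples;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b cluster label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  mx <- (ai + bj) / 2
  if (mx == expected) return(1)  # degenerate: both partitions trivial
  (nij - expected) / (mx - expected)
}

## intersection of sample universes with a logged report
reconcile_samples <- function(sample_sets) {
  common <- Reduce(intersect, sample_sets)
  for (nm in names(sample_sets)) {
    dropped <- setdiff(sample_sets[[nm]], common)
    if (length(dropped))
      tri_log("sample reconciliation: %d sample(s) in %s absent from the shared universe (%s)",
              length(dropped), nm, paste(utils::head(dropped, 5), collapse = ", "))
  }
  if (!length(common)) stop("sample reconciliation produced an empty universe")
  common
}

## deterministic derived seeds kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}
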