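## Cohort input and preprocessing: SEG-style segmented copy number, 450K-style
## methylation betas with probe annotation, FPKM + count expression matrices,
## MAF-like somatic mutations, clinical follow-up and a gene model.
##
## Coordinate convention: everything is 0-based half-open internally. SEG
## input is treated as 1-based inclusive (the format's convention) and
## converted on read; BED input is already 0-based half-open.

SEG_COLS <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
VARIANT_CLASSES <- c("Missense", "Nonsense", "Frameshift", "Splice", "Silent",
                     "Intron", "other")
REGION_CLASSES <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf", "OpenSea")

read_numeric_matrix <- function(path, layer) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix file ", path, " needs a feature column plus samples")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated feature id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(apply(raw, 2, as.numeric))
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = nrow(raw), dimnames = dimnames(raw))
  bad <- which(is.na(vals) & !is.na(raw) & !(raw %in% c("NA", "", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell in %s at row %d (feature %s), column %s: '%s'",
                 path, bad[1, 1] + 1L, ids[bad[1, 1]],
                 colnames(raw)[bad[1, 2]], raw[bad[1, 1], bad[1, 2]]))
  rownames(vals) <- ids
  omics_matrix(vals, layer)
}

read_seg <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  missing_cols <- setdiff(SEG_COLS, colnames(df))
  if (length(missing_cols))
    stop("SEG file ", path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  segs <- data.frame(
    sample_id = as.character(df$Sample),
    chrom = as.character(df$Chromosome),
    start = as.numeric(df$Start) - 1,  # 1-based inclusive -> 0-based half-open
    end = as.numeric(df$End),
    num_probes = as.integer(df$Num_Probes),
    seg_value = as.numeric(df$Segment_Mean),
    stringsAsFactors = FALSE)
  bad <- which(!is.finite(segs$start) | !is.finite(segs$end) |
                 segs$start >= segs$end | is.na(segs$num_probes) |
                 segs$num_probes < 0 | !is.finite(segs$seg_value) |
                 !nzchar(segs$chrom))
  if (length(bad)) {
    tri_log("SEG: rejecting %d malformed row(s) (data lines %s)",
            length(bad), paste(utils::head(bad, 10), collapse = ", "))
    segs <- segs[-bad, , drop = FALSE]
  }
  segs
}

read_gene_model <- function(path) {
  if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE)) {
    df <- utils::read.delim(path, header = FALSE, sep = "\t", check.names = FALSE)
    if (ncol(df) < 6) stop("BED gene model needs at least 6 columns")
    gm <- data.frame(
      gene_id = as.character(df[[4]]),
      gene_name = as.character(if (ncol(df) >= 7) df[[7]] else df[[4]]),
      chrom = as.character(df[[1]]),
      strand = as.character(df[[6]]),
      gene_start = as.numeric(df[[2]]),
      gene_end = as.numeric(df[[3]]),
      gene_type = as.character(if (ncol(df) >= 8) df[[8]] else "protein_coding"),
      stringsAsFactors = FALSE)
    gm$tss <- ifelse(gm$strand == "+", gm$gene_start, gm$gene_end - 1)
  } else {
    gm <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  need <- c("gene_id", "gene_name", "chrom", "strand", "tss",
            "gene_start", "gene_end", "gene_type")
  missing_cols <- setdiff(need, colnames(gm))
  if (length(missing_cols))
    stop("gene model lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(gm$strand %in% c("+", "-"))) stop("gene model strand must be +/-")
  if (any(gm$gene_start >= gm$gene_end)) stop("gene model has gene_start >= gene_end")
  gm[, need]
}

#' Load a multi-omics cohort from disk
#'
#' Reads the five molecular/clinical tables plus gene model and methylation
#' probe annotation, validates each against its type invariants, and
#' reconciles the sample universe to the intersection of the molecular
#' matrices and clinical table (the reconciliation is logged).
#'
#' @param paths named list of file paths: `seg`, `met`, `exp_fpkm`,
#'   `exp_counts`, `mutations`, `clinical`, `gene_model`, `probes`.
#' @return list with elements `segments`, `met`, `exp_fpkm`, `exp_counts`,
#'   `mutations`, `clinical`, `gene_model`, `probes` and `samples` (the
#'   reconciled universe).
#' @export
load_cohort <- function(paths) {
  need <- c("seg", "met", "exp_fpkm", "exp_counts", "mutations", "clinical",
            "gene_model", "probes")
  missing_paths <- setdiff(need, names(paths))
  if (length(missing_paths))
    stop("missing path(s): ", paste(missing_paths, collapse = ", "))
  for (p in unlist(paths[need]))
    if (!file.exists(p)) stop("missing file: ", p)

  segments <- read_seg(paths$seg)
  met <- read_numeric_matrix(paths$met, "MET")
  exp_fpkm <- read_numeric_matrix(paths$exp_fpkm, "EXP_FPKM")
  exp_counts <- read_numeric_matrix(paths$exp_counts, "EXP_COUNTS")

  mut <- utils::read.delim(paths$mutations, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  mutations <- data.frame(
    sample_id = as.character(mut$Tumor_Sample_Barcode),
    gene_name = as.character(mut$Hugo_Symbol),
    hgvs_c = as.character(mut$HGVSc),
    variant_class = as.character(mut$Variant_Classification),
    stringsAsFactors = FALSE)
  bad <- which(!mutations$variant_class %in% VARIANT_CLASSES)
  if (length(bad)) {
    tri_log("mutations: coercing %d unknown variant class(es) to 'other'", length(bad))
    mutations$variant_class[bad] <- "other"
  }

  clinical <- utils::read.delim(paths$clinical, header = TRUE, sep = "\t",
                                check.names = FALSE, stringsAsFactors = FALSE)
  names(clinical)[names(clinical) == "sample"] <- "sample_id"
  if (any(clinical$os_time < 0, na.rm = TRUE)) stop("negative os_time")
  if (!all(clinical$os_event %in% c(0, 1))) stop("os_event must be 0/1")

  gene_model <- read_gene_model(paths$gene_model)
  probes <- utils::read.delim(paths$probes, header = TRUE, sep = "\t",
                              check.names = FALSE, stringsAsFactors = FALSE)
  names(probes)[names(probes) == "probe"] <- "probe_id"
  names(probes)[names(probes) == "pos"] <- "position"
  if (!all(probes$region_class %in% REGION_CLASSES))
    stop("unknown methylation region class: ",
         paste(setdiff(probes$region_class, REGION_CLASSES), collapse = ", "))
  if (any(probes$position < 0)) stop("negative probe position")

  samples <- reconcile_samples(list(
    CNV = unique(segments$sample_id), MET = colnames(met),
    EXP_FPKM = colnames(exp_fpkm), EXP_COUNTS = colnames(exp_counts),
    clinical = clinical$sample_id))

  list(segments = segments[segments$sample_id %in% samples, , drop = FALSE],
       met = met[, samples, drop = FALSE],
       exp_fpkm = exp_fpkm[, samples, drop = FALSE],
       exp_counts = exp_counts[, samples, drop = FALSE],
       mutations = mutations[mutations$sample_id %in% samples, , drop = FALSE],
       clinical = clinical[match(samples, clinical$sample_id), , drop = FALSE],
       gene_model = gene_model, probes = probes, samples = samples)
}

segments_granges <- function(segments, split_by_sample = TRUE) {
  seqn <- if (split_by_sample)
    paste(segments$sample_id, segments$chrom, sep = "\r") else segments$chrom
  GenomicRanges::GRanges(
    seqnames = seqn,
    ranges = IRanges::IRanges(start = segments$start + 1L, end = segments$end))
}

#' Merge equivalent copy-number regions
#'
#' Within a sample and chromosome, two segments whose reciprocal overlap is
#' at least `overlap_frac` (overlap length >= `overlap_frac` times each
#' segment's length) are considered the same region and replaced by their
#' union interval; the merged value is the unweighted mean of all original
#' segment values absorbed into the region and probe counts are summed.
#' Merging is applied transitively until a fixpoint.
#'
#' @param segments segment data frame (`sample_id`, `chrom`, `start`, `end`,
#'   `num_probes`, `seg_value`), 0-based half-open.
#' @param overlap_frac reciprocal overlap fraction in (0, 1\]; default 0.5.
#' @return merged segment data frame.
#' @export
merge_equivalent_regions <- function(segments, overlap_frac = 0.5) {
  stopifnot(overlap_frac > 0, overlap_frac <= 1)
  if (!nrow(segments)) return(segments)
  segs <- segments
  ## each working segment carries the values of its original constituents so
  ## the merged mean is order-independent
  segs$.constituents <- lapply(segs$seg_value, identity)

  repeat {
    gr <- segments_granges(segs)
    hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
    hits <- hits[S4Vectors::queryHits(hits) < S4Vectors::subjectHits(hits)]
    if (!length(hits)) break
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- pmin(segs$end[q], segs$end[s]) - pmax(segs$start[q], segs$start[s])
    lenq <- segs$end[q] - segs$start[q]
    lens <- segs$end[s] - segs$start[s]
    ok <- ov >= overlap_frac * lenq & ov >= overlap_frac * lens
    if (!any(ok)) break
    ## merge one pair, then rescan (transitive closure to fixpoint)
    i <- q[which(ok)[1]]; j <- s[which(ok)[1]]
    segs$start[i] <- min(segs$start[i], segs$start[j])
    segs$end[i] <- max(segs$end[i], segs$end[j])
    segs$num_probes[i] <- segs$num_probes[i] + segs$num_probes[j]
    segs$.constituents[[i]] <- c(segs$.constituents[[i]], segs$.constituents[[j]])
    segs$seg_value[i] <- mean(segs$.constituents[[i]])
    segs <- segs[-j, , drop = FALSE]
  }
  segs$.constituents <- NULL
  rownames(segs) <- NULL
  segs
}

#' Drop segments supported by too few probes
#'
#' @param segments segment data frame.
#' @param min_probes minimum probe support; segments with fewer probes are
#'   deleted. Default 5 (i.e. regions covered by fewer than 5 probes go).
#' @return filtered segment data frame.
#' @export
filter_low_probe_segments <- function(segments, min_probes = 5) {
  keep <- segments$num_probes >= min_probes
  if (any(!keep))
    tri_log("probe filter: removed %d of %d segments with < %d probes",
            sum(!keep), nrow(segments), min_probes)
  segments[keep, , drop = FALSE]
}

#' Map copy-number segments to gene-level values
#'
#' Per (gene, sample), the CNV value is the unweighted mean of the segment
#' values of all segments overlapping the gene body by at least 1 bp (when a
#' gene is touched by several regions they are merged into one gene value by
#' averaging). Genes with no overlapping segment in a sample are missing
#' there; genes missing in more than `max_missing_frac` of samples are
#' dropped and the remaining missing entries are imputed with the per-gene
#' median.
#'
#' @param segments merged, probe-filtered segment data frame.
#' @param gene_model gene model data frame.
#' @param max_missing_frac missingness tolerance per gene; default 0.3.
#' @param length_weighted use overlap-length-weighted means instead of
#'   unweighted means (off by default).
#' @return an [omics_matrix()] with layer `"CNV"`.
#' @export
map_cnv_to_genes <- function(segments, gene_model, max_missing_frac = 0.3,
                             length_weighted = FALSE) {
  if (!nrow(gene_model)) stop("empty gene model")
  samples <- sort(unique(segments$sample_id))
  mat <- matrix(NA_real_, nrow = nrow(gene_model), ncol = length(samples),
                dimnames = list(gene_model$gene_id, samples))
  if (nrow(segments)) {
    seg_gr <- segments_granges(segments, split_by_sample = FALSE)
    gene_gr <- GenomicRanges::GRanges(
      seqnames = gene_model$chrom,
      ranges = IRanges::IRanges(start = gene_model$gene_start + 1L,
                                end = gene_model$gene_end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gene_gr, seg_gr, minoverlap = 1L))
    gi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ## same sample only (seqnames already force same chromosome)
    key <- paste(gi, match(segments$sample_id[si], samples))
    if (length_weighted) {
      ov <- pmin(gene_model$gene_end[gi], segments$end[si]) -
        pmax(gene_model$gene_start[gi], segments$start[si])
      num <- tapply(segments$seg_value[si] * ov, key, sum)
      den <- tapply(ov, key, sum)
      vals <- num / den
    } else {
      vals <- tapply(segments$seg_value[si], key, mean)
    }
    idx <- do.call(rbind, lapply(strsplit(names(vals), " "), as.integer))
    mat[idx] <- as.numeric(vals)
  }
  miss_frac <- rowMeans(is.na(mat))
  drop <- miss_frac > max_missing_frac
  if (any(drop))
    tri_log("CNV gene mapping: dropped %d gene(s) missing in > %.0f%% of samples",
            sum(drop), 100 * max_missing_frac)
  mat <- mat[!drop, , drop = FALSE]
  ## impute residual missingness with the per-gene median
  nmiss <- which(rowSums(is.na(mat)) > 0)
  for (i in nmiss) {
    med <- stats::median(mat[i, ], na.rm = TRUE)
    mat[i, is.na(mat[i, ])] <- med
  }
  omics_matrix(mat, "CNV")
}

#' Filter and KNN-impute a methylation beta matrix
#'
#' Probes missing in more than `max_missing_frac` of samples are removed;
#' each remaining missing entry is imputed as the mean beta of the `k`
#' nearest complete probes, with probe-probe distance the Euclidean distance
#' over the samples where the incomplete probe is observed.
#'
#' @param met [omics_matrix()] with layer `"MET"`.
#' @param max_missing_frac missingness tolerance; default 0.7 (probes absent
#'   in > 70% of samples go).
#' @param k number of neighbours; default 10.
#' @return imputed [omics_matrix()] with no missing values.
#' @export
filter_and_impute_met <- function(met, max_missing_frac = 0.7, k = 10) {
  stopifnot(omics_layer(met) == "MET")
  miss_frac <- rowMeans(is.na(met))
  drop <- miss_frac > max_missing_frac
  if (any(drop))
    tri_log("MET filter: removed %d probe(s) missing in > %.0f%% of samples",
            sum(drop), 100 * max_missing_frac)
  m <- unclass(met)[!drop, , drop = FALSE]
  incomplete <- which(rowSums(is.na(m)) > 0)
  if (length(incomplete)) {
    complete <- which(rowSums(is.na(m)) == 0)
    if (length(complete) < k)
      stop("k = ", k, " exceeds the number of complete probes (", length(complete), ")")
    ref <- m[complete, , drop = FALSE]
    for (i in incomplete) {
      obs <- !is.na(m[i, ])
      d2 <- rowSums((ref[, obs, drop = FALSE] -
                       matrix(m[i, obs], nrow(ref), sum(obs), byrow = TRUE))^2)
      nn <- order(d2)[seq_len(k)]
      fill <- colMeans(ref[nn, !obs, drop = FALSE])
      m[i, !obs] <- fill
    }
  }
  omics_matrix(m, "MET")
}

#' Aggregate methylation probes to gene-level promoter betas
#'
#' Keeps probes inside the promoter window spanning `upstream` bp upstream
#' to `downstream` bp downstream of the TSS in transcription orientation
#' (the genomic window flips on the minus strand), then averages the
#' retained probe betas per gene. Genes with no retained probe are absent
#' from the output.
#'
#' @param met imputed [omics_matrix()] with layer `"MET"` (probes in rows).
#' @param probes probe annotation data frame (`probe_id`, `chrom`,
#'   `position`, `region_class`).
#' @param gene_model gene model data frame.
#' @param upstream,downstream promoter window, default 2000 / 200 bp.
#' @param aggregate `"mean"` (default) or `"median"` across retained probes.
#' @return gene-level [omics_matrix()] with layer `"MET"`.
#' @export
aggregate_met_to_genes <- function(met, probes, gene_model,
                                   upstream = 2000, downstream = 200,
                                   aggregate = c("mean", "median")) {
  stopifnot(omics_layer(met) == "MET")
  aggregate <- match.arg(aggregate)
  probes <- probes[probes$probe_id %in% rownames(met), , drop = FALSE]
  plus <- gene_model$strand == "+"
  win_lo <- ifelse(plus, gene_model$tss - upstream, gene_model$tss - downstream)
  win_hi <- ifelse(plus, gene_model$tss + downstream, gene_model$tss + upstream)
  agg_fun <- if (aggregate == "mean") colMeans else
    function(x) apply(x, 2, stats::median)
  rows <- list()
  for (g in seq_len(nrow(gene_model))) {
    sel <- probes$chrom == gene_model$chrom[g] &
      probes$position >= win_lo[g] & probes$position <= win_hi[g]
    if (!any(sel)) next
    rows[[gene_model$gene_id[g]]] <-
      agg_fun(unclass(met)[probes$probe_id[sel], , drop = FALSE])
  }
  if (!length(rows)) stop("no gene received any promoter probe")
  omics_matrix(do.call(rbind, rows), "MET")
}

#' Filter lowly expressed genes
#'
#' Keeps genes expressed (FPKM > 0) in at least `min_expressed_frac` of
#' samples; the same gene filter is applied to the companion count matrix
#' when given.
#'
#' @param exp_fpkm [omics_matrix()] with layer `"EXP_FPKM"`.
#' @param exp_counts optional matching `"EXP_COUNTS"` matrix.
#' @param min_expressed_frac minimum expressed fraction; default 0.005.
#' @return the filtered FPKM matrix, or a list `(exp_fpkm, exp_counts)` when
#'   counts are supplied.
#' @export
filter_expression <- function(exp_fpkm, exp_counts = NULL,
                              min_expressed_frac = 0.005) {
  stopifnot(omics_layer(exp_fpkm) == "EXP_FPKM")
  keep <- rowMeans(unclass(exp_fpkm) > 0) >= min_expressed_frac
  if (any(!keep))
    tri_log("expression filter: removed %d gene(s) expressed in < %.2f%% of samples",
            sum(!keep), 100 * min_expressed_frac)
  out <- exp_fpkm[keep, , drop = FALSE]
  if (is.null(exp_counts)) return(out)
  list(exp_fpkm = out,
       exp_counts = exp_counts[rownames(exp_counts) %in% rownames(out), , drop = FALSE])
}

#' Filter somatic mutations
#'
#' Removes intronic and silent mutations.
#'
#' @param mutations mutation record data frame with a `variant_class` column.
#' @return filtered data frame.
#' @export
filter_snv <- function(mutations) {
  keep <- !mutations$variant_class %in% c("Intron", "Silent")
  if (any(!keep))
    tri_log("SNV filter: removed %d intronic/silent mutation(s)", sum(!keep))
  mutations[keep, , drop = FALSE]
}
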