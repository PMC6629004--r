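## End-to-end orchestration: preprocess -> correlation screen -> NMF subtypes
## per layer -> integrative clustering -> aberration burdens -> subtype
## characterization of the extreme-prognosis pair -> survival statistics.
## The pipeline is a pure function of (inputs, config, seed).

#' Pipeline configuration
#'
#' Collects every stage threshold with its default: correlation screen at
#' p < 0.01, prognostic screen at p < 0.05, aberration thresholds +-0.3 and
#' 0.8/0.2, NMF ranks 2-10 with 50 restarts, a 101-point lambda grid with
#' K = 2-3, minimum cluster size 10, and the characterization threshold
#' p < 0.05.
#'
#' @param simulate a [simulation_config()] to generate the cohort, or NULL.
#' @param paths input file paths for [load_cohort()] when not simulating.
#' @param seed mandatory seed for all stochastic stages.
#' @param p_set correlation-screen threshold.
#' @param p_surv prognostic threshold.
#' @param p_char characterization threshold.
#' @param thresholds an [aberration_thresholds()] list.
#' @param overlap_frac,min_probes,met_missing_frac,knn_k,min_expressed_frac,max_cnv_missing
#'   preprocessing parameters (see the respective functions).
#' @param nmf_k_range,nmf_runs consensus-NMF settings.
#' @param nmf_force_k override the metric-based rank choice with a fixed
#'   number of subtypes for both layers (NULL = pick by the metrics).
#' @param lambda_points,K_range,min_cluster_size integrative-clustering
#'   settings.
#' @param min_screen_genes smallest usable prognostic gene set; below it the
#'   stage falls back to the full correlated set (logged).
#' @param outdir optional directory for TSV artifacts and the manifest.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, seed = NULL,
                            p_set = 0.01, p_surv = 0.05, p_char = 0.05,
                            thresholds = aberration_thresholds(),
                            overlap_frac = 0.5, min_probes = 5,
                            met_missing_frac = 0.7, knn_k = 10,
                            min_expressed_frac = 0.005, max_cnv_missing = 0.3,
                            nmf_k_range = 2:10, nmf_runs = 50, nmf_force_k = NULL,
                            lambda_points = 101, K_range = 2:3,
                            min_cluster_size = 10, min_screen_genes = 20,
                            outdir = NULL) {
  if (is.null(seed)) stop("`seed` is mandatory: the pipeline has stochastic stages")
  if (is.null(simulate) && is.null(paths)) stop("either `simulate` or `paths` required")
  structure(as.list(environment()), class = "pipeline_config")
}

km_median_or_inf <- function(times, events) {
  med <- km_estimate(times, events)$median
  if (is.na(med)) Inf else med
}

#' Run the full multi-omics subtyping pipeline
#'
#' Executes all stages in order and returns a structured report. Every
#' filter logs its in/out record counts; the `manifest` element captures
#' seeds, thresholds and stage counts so two identical runs produce
#' identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return object of class `"pipeline_report"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t - t0, 1)
    t0 <<- t
  }

  ## ---- cohort ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
  } else {
    cohort <- load_cohort(config$paths)
    cohort$truth <- NULL
  }
  tick("cohort")

  ## ---- preprocess --------------------------------------------------------
  segs <- merge_equivalent_regions(cohort$segments, config$overlap_frac)
  segs <- filter_low_probe_segments(segs, config$min_probes)
  cnv <- map_cnv_to_genes(segs, cohort$gene_model, config$max_cnv_missing)
  met_probe <- filter_and_impute_met(cohort$met, config$met_missing_frac,
                                     config$knn_k)
  metg <- aggregate_met_to_genes(met_probe, cohort$probes, cohort$gene_model)
  ef <- filter_expression(cohort$exp_fpkm, cohort$exp_counts,
                          config$min_expressed_frac)
  fpkm <- ef$exp_fpkm; counts <- ef$exp_counts
  mutations <- filter_snv(cohort$mutations)
  samples <- Reduce(intersect, list(colnames(cnv), colnames(metg),
                                    colnames(fpkm), cohort$clinical$sample_id))
  cnv <- cnv[, samples, drop = FALSE]
  metg <- metg[, samples, drop = FALSE]
  fpkm <- fpkm[, samples, drop = FALSE]
  counts <- counts[, samples, drop = FALSE]
  clinical <- cohort$clinical[match(samples, cohort$clinical$sample_id), ]
  tick("preprocess")

  ## ---- correlation screen ------------------------------------------------
  rec_cnv <- gene_correlation(cnv, fpkm, "CNVcor")
  rec_met <- gene_correlation(metg, fpkm, "METcor")
  cnvcor <- screen_corgenes(rec_cnv, config$p_set)
  metcor <- screen_corgenes(rec_met, config$p_set)
  zshift <- list(
    CNVcor = if (length(cnvcor) >= 20)
      zshift_test(rec_cnv$z[rec_cnv$gene_id %in% cnvcor]),
    METcor = if (length(metcor) >= 20)
      zshift_test(rec_met$z[rec_met$gene_id %in% metcor]))
  prog_cnv <- prognostic_screen(cnvcor, cnv, clinical, config$p_surv)
  prog_met <- prognostic_screen(metcor, metg, clinical, config$p_surv)
  sel_cnv <- prog_cnv$gene_id[prog_cnv$selected]
  sel_met <- prog_met$gene_id[prog_met$selected]
  if (length(sel_cnv) < config$min_screen_genes) {
    tri_log("prognostic CNVcor set too small (%d); falling back to the full set",
            length(sel_cnv))
    sel_cnv <- as.character(cnvcor)
  }
  if (length(sel_met) < config$min_screen_genes) {
    tri_log("prognostic METcor set too small (%d); falling back to the full set",
            length(sel_met))
    sel_met <- as.character(metcor)
  }
  universe_n <- length(intersect(rownames(cnv), rownames(fpkm)))
  overlap <- set_overlap_test(sel_cnv, sel_met, universe_n)
  enrichment <- list(CNVcor = chromosome_enrichment(cnvcor, cohort$gene_model),
                     METcor = chromosome_enrichment(metcor, cohort$gene_model))
  tick("corgene_screen")

  ## ---- NMF subtypes per layer -------------------------------------------
  run_nmf <- function(V, label) {
    results <- lapply(config$nmf_k_range, function(k)
      consensus_cluster(V, k, n_runs = config$nmf_runs,
                        seed = derive_seed(config$seed, k)))
    k_sel <- select_rank(results, config$min_cluster_size)
    if (!is.null(config$nmf_force_k)) {
      tri_log("NMF (%s): overriding metric-selected k = %d with forced k = %d",
              label, as.integer(k_sel), config$nmf_force_k)
      k_sel <- structure(as.integer(config$nmf_force_k),
                        metrics = attr(k_sel, "metrics"))
    }
    best <- results[[which(config$nmf_k_range == as.integer(k_sel))]]
    tri_log("NMF (%s): selected k = %d", label, k_sel)
    list(k = as.integer(k_sel), metrics = attr(k_sel, "metrics"), best = best,
         labels = best$labels)
  }
  nmf_cnv <- run_nmf(nonneg_embed(unclass(cnv)[sel_cnv, , drop = FALSE]), "CNVcor")
  nmf_met <- run_nmf(unclass(metg)[sel_met, , drop = FALSE], "METcor")
  tick("nmf")

  ## ---- integrative clustering -------------------------------------------
  exp_genes <- intersect(union(sel_cnv, sel_met), rownames(fpkm))
  datasets <- list(CNV = unclass(cnv)[sel_cnv, , drop = FALSE],
                   MET = unclass(metg)[sel_met, , drop = FALSE],
                   EXP = unclass(fpkm)[exp_genes, , drop = FALSE])
  ic <- tune_and_cluster(datasets, K_range = config$K_range,
                         grid = lambda_grid(config$lambda_points),
                         min_cluster_size = config$min_cluster_size,
                         seed = derive_seed(config$seed, 97))
  ic_labels <- ic$labels
  nmf_overlap <- list(
    cnv_vs_ic = partition_overlap_test(nmf_cnv$labels, ic_labels),
    met_vs_ic = partition_overlap_test(nmf_met$labels, ic_labels),
    cnv_vs_met = partition_overlap_test(nmf_cnv$labels, nmf_met$labels))
  tick("icluster")

  ## ---- aberration burdens ------------------------------------------------
  burdens <- burden_counts(cnv, metg, config$thresholds)
  burden_cors <- burden_correlations(burdens)
  tick("burden")

  ## ---- survival across integrative subtypes -----------------------------
  os_logrank <- logrank_test(clinical$os_time, clinical$os_event, ic_labels)
  pfs_logrank <- if (!is.null(clinical$pfs_time) && !anyNA(clinical$pfs_time))
    logrank_test(clinical$pfs_time, clinical$pfs_event, ic_labels)
  medians <- vapply(sort(unique(ic_labels)), function(k) {
    idx <- ic_labels == k
    km_median_or_inf(clinical$os_time[idx], clinical$os_event[idx])
  }, numeric(1))
  names(medians) <- sort(unique(ic_labels))
  worst <- as.integer(names(medians)[which.min(medians)])
  best <- as.integer(names(medians)[which.max(medians)])
  tick("survival_subtypes")

  ## ---- characterize worst vs best subtype -------------------------------
  pair_idx <- ic_labels %in% c(worst, best)
  pair_samples <- samples[pair_idx]
  pair_groups <- factor(ifelse(ic_labels[pair_idx] == worst, "worst", "best"),
                        levels = c("worst", "best"))
  names(pair_groups) <- pair_samples

  de <- differential_expression(counts[, pair_samples, drop = FALSE], pair_groups)
  genes_all <- Reduce(intersect, list(rownames(cnv), rownames(metg), de$gene_id))
  states_cnv <- classify_aberration(unclass(cnv)[genes_all, pair_samples, drop = FALSE],
                                    "CNV", config$thresholds)
  states_met <- classify_aberration(unclass(metg)[genes_all, pair_samples, drop = FALSE],
                                    "MET", config$thresholds)
  dim(states_cnv) <- dim(states_met) <- c(length(genes_all), length(pair_samples))
  p_cnv <- p_met <- rep(NA_real_, length(genes_all))
  for (i in seq_along(genes_all)) {
    p_cnv[i] <- as.numeric(aberration_contingency_test(states_cnv[i, ], pair_groups))
    p_met[i] <- as.numeric(aberration_contingency_test(states_met[i, ], pair_groups))
  }
  diffs <- data.frame(gene_id = genes_all, fisher_p_cnv = p_cnv,
                      fisher_p_met = p_met,
                      de_log2fc = de$log2fc[match(genes_all, de$gene_id)],
                      de_p = de$p[match(genes_all, de$gene_id)],
                      de_fdr = de$fdr[match(genes_all, de$gene_id)])
  diffs$selected <- diffs$gene_id %in% intersect_candidates(diffs, config$p_char)
  candidates <- diffs$gene_id[diffs$selected]
  tri_log("characterization: %d candidate gene(s) aberrant in all three layers",
          length(candidates))

  ## prognostic filter of the candidates (univariate Cox on expression)
  cand_surv <- do.call(rbind, lapply(candidates, function(g) {
    v <- unclass(fpkm)[g, samples]
    cx <- tryCatch(cox_univariate(v, clinical$os_time, clinical$os_event),
                   error = function(e) NULL)
    if (is.null(cx)) return(NULL)
    grp <- median_split(v)
    lr <- logrank_test(clinical$os_time, clinical$os_event, grp)
    data.frame(gene_id = g, cox_p = cx$p, hr = cx$hr, ci_low = cx$ci_low,
               ci_high = cx$ci_high, logrank_p = lr$p)
  }))
  prognostic_candidates <- if (!is.null(cand_surv))
    cand_surv$gene_id[cand_surv$cox_p < config$p_surv] else character(0)

  spectrum <- mutation_spectrum_compare(mutations, pair_groups)

  ## SNV-expression correlations for the prognostic candidates
  loci <- unique(mutations[, c("gene_name", "hgvs_c")])
  carrier_count <- vapply(seq_len(nrow(loci)), function(i)
    length(unique(mutations$sample_id[
      mutations$gene_name == loci$gene_name[i] &
        mutations$hgvs_c == loci$hgvs_c[i]])), integer(1))
  loci <- loci[carrier_count >= 3, , drop = FALSE]
  loci <- utils::head(loci[order(-carrier_count[carrier_count >= 3]), ], 300)
  snv_corr <- do.call(rbind, lapply(prognostic_candidates, function(tg) {
    res <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
      carriers <- samples %in% mutations$sample_id[
        mutations$gene_name == loci$gene_name[i] &
          mutations$hgvs_c == loci$hgvs_c[i]]
      snv_expression_correlation(unclass(fpkm)[tg, samples], as.integer(carriers),
                                 target_gene = tg, snv_gene = loci$gene_name[i],
                                 hgvs_c = loci$hgvs_c[i])
    }))
    if (is.null(res)) return(NULL)
    utils::head(res[order(res$corr_p), ], 10)
  }))
  tick("characterize")

  manifest <- list(
    seed = config$seed,
    thresholds = list(p_set = config$p_set, p_surv = config$p_surv,
                      p_char = config$p_char,
                      aberration = config$thresholds,
                      nmf_k_range = config$nmf_k_range, nmf_runs = config$nmf_runs,
                      lambda_points = config$lambda_points,
                      K_range = config$K_range,
                      min_cluster_size = config$min_cluster_size),
    counts = list(
      samples = length(samples),
      genes_cnv = nrow(cnv), genes_met = nrow(metg), genes_exp = nrow(fpkm),
      cnvcor = length(cnvcor), metcor = length(metcor),
      cnvcor_prognostic = sum(prog_cnv$selected),
      metcor_prognostic = sum(prog_met$selected),
      corgene_overlap = overlap$overlap,
      nmf_k_cnv = nmf_cnv$k, nmf_k_met = nmf_met$k,
      icluster_K = length(unique(ic_labels)),
      icluster_sizes = as.integer(table(ic_labels)),
      candidates = length(candidates),
      prognostic_candidates = length(prognostic_candidates)))

  report <- structure(list(
    samples = samples, clinical = clinical,
    matrices = list(cnv = cnv, met = metg, fpkm = fpkm),
    corgene = list(records_cnv = rec_cnv, records_met = rec_met,
                   cnvcor = cnvcor, metcor = metcor, zshift = zshift,
                   prognostic_cnv = prog_cnv, prognostic_met = prog_met,
                   sel_cnv = sel_cnv, sel_met = sel_met,
                   overlap = overlap, enrichment = enrichment),
    nmf = list(cnv = nmf_cnv, met = nmf_met),
    icluster = ic, ic_labels = ic_labels, nmf_overlap = nmf_overlap,
    burdens = burdens, burden_correlations = burden_cors,
    survival = list(os_logrank = os_logrank, pfs_logrank = pfs_logrank,
                    median_os = medians, worst = worst, best = best,
                    candidate_survival = cand_surv),
    characterization = list(diffs = diffs, de_method = attr(de, "method"),
                            candidates = candidates,
                            prognostic_candidates = prognostic_candidates,
                            mutation_spectrum = spectrum, snv_corr = snv_corr),
    truth = cohort$truth, manifest = manifest, timings = timings,
    config = config), class = "pipeline_report")

  if (!is.null(cohort$truth)) {
    tl <- cohort$truth$subtype_labels[samples]
    report$ari <- list(
      nmf_cnv = adjusted_rand_index(nmf_cnv$labels, tl),
      nmf_met = adjusted_rand_index(nmf_met$labels, tl),
      icluster = adjusted_rand_index(ic_labels, tl))
  }
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("Multi-omics subtyping pipeline report\n")
  cat(sprintf("  samples: %d | genes (CNV/MET/EXP): %d/%d/%d\n",
              cnt$samples, cnt$genes_cnv, cnt$genes_met, cnt$genes_exp))
  cat(sprintf("  CNVcor: %d (prognostic %d) | METcor: %d (prognostic %d) | overlap: %d\n",
              cnt$cnvcor, cnt$cnvcor_prognostic, cnt$metcor,
              cnt$metcor_prognostic, cnt$corgene_overlap))
  cat(sprintf("  NMF ranks: CNVcor k = %d, METcor k = %d\n",
              cnt$nmf_k_cnv, cnt$nmf_k_met))
  cat(sprintf("  integrative subtypes: %d (sizes %s)\n", cnt$icluster_K,
              paste(cnt$icluster_sizes, collapse = "/")))
  cat(sprintf("  OS log-rank across subtypes: chi2 = %.2f, p = %.3g\n",
              x$survival$os_logrank$chi2, x$survival$os_logrank$p))
  bc <- x$burden_correlations
  gh <- bc[bc$pair == "Gain-MetHypo", ]
  cat(sprintf("  burden correlation Gain~MetHypo: r = %.3f (p = %.3g)\n", gh$r, gh$p))
  cat(sprintf("  candidate genes (CNV+MET+EXP): %d; prognostic: %d\n",
              cnt$candidates, cnt$prognostic_candidates))
  if (!is.null(x$ari))
    cat(sprintf("  ARI vs planted subtypes: NMF-CNV %.2f, NMF-MET %.2f, integrative %.2f\n",
                x$ari$nmf_cnv, x$ari$nmf_met, x$ari$icluster))
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  cg <- rbind(report$corgene$records_cnv, report$corgene$records_met)
  cg$selected <- cg$gene_id %in% c(report$corgene$cnvcor, report$corgene$metcor)
  wt(cg, "corgenes.tsv")
  wt(do.call(rbind, Map(function(df, nm) cbind(layer = nm, df),
                        report$corgene$enrichment,
                        names(report$corgene$enrichment))), "enrichment.tsv")
  wt(data.frame(sample = report$samples,
                nmf_cnv = report$nmf$cnv$labels,
                nmf_met = report$nmf$met$labels,
                icluster = report$ic_labels), "labels.tsv")
  wt(report$burdens, "burdens.tsv")
  wt(report$burden_correlations, "burden_correlations.tsv")
  wt(report$characterization$diffs, "subtype_diff.tsv")
  if (!is.null(report$characterization$snv_corr)) {
    sc <- report$characterization$snv_corr
    wt(data.frame(gName = sc$target_gene, snvGene = sc$snv_gene, SNV = sc$hgvs_c,
                  CorrP = sc$corr_p, Corr = sc$corr), "snv_corr.tsv")
  }
  wt(report$characterization$mutation_spectrum, "mutation_spectrum.tsv")
  jsonlite::write_json(report$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
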