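## Synthetic multi-omics cohort generator with known ground truth: planted
## molecular subtypes drive blocks of copy number and promoter methylation,
## cis effects couple expression positively to copy number and negatively to
## promoter methylation, a shared per-sample instability factor couples the
## CNV-gain and methylation-hypo burdens, survival follows subtype-specific
## exponential hazards, and sparse binary mutations carry optional expression
## effects. Decoy content (low-probe segments, silent/intronic mutations,
## high-missingness probes, all-zero genes) is on by default so every
## preprocessing filter has work to do.

#' Simulation configuration
#'
#' Defaults describe a cohort of 350 samples in three subtypes with the
#' 66/128/156 proportions, 2000 genes of which 10% are copy-number cis
#' drivers and 10% methylation cis drivers, a Gain/MetHypo burden coupling
#' of 0.29, subtype-specific exponential overall-survival hazards with
#' subtype 1 worst, and five planted triple-aberrant genes that differ
#' between the worst and best subtypes in all three layers.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_subtypes number of planted subtypes.
#' @param subtype_props subtype proportions (summing to 1).
#' @param cnv_driver_frac,met_driver_frac fractions of genes with planted
#'   cis effects.
#' @param cnv_effect expression slope per copy-number unit (> 0).
#' @param met_effect expression slope per beta unit (< 0).
#' @param noise_sd residual expression noise (FPKM units).
#' @param burden_coupling latent correlation between the per-sample CNV-gain
#'   and methylation-hypo burdens.
#' @param hazard_per_subtype exponential OS hazards per day, one per subtype.
#' @param censor_hazard independent exponential censoring hazard per day.
#' @param mutation_rate background per-(gene, sample) mutation probability.
#' @param n_triple_aberrant planted genes aberrant in all three layers.
#' @param n_spectrum_genes genes with subtype-dependent mutation rates.
#' @param n_snv_effect_loci mutation loci whose carriers shift a target
#'   gene's expression.
#' @param aberr_gain_rate,aberr_loss_rate,aberr_hyper_rate,aberr_hypo_rate
#'   mean per-gene rates of the sporadic aberration overlay.
#' @param decoy_segment_frac fraction of extra low-probe (< 5) decoy
#'   segments per sample.
#' @param zero_gene_frac fraction of all-zero expression genes.
#' @param seed RNG seed driving every random draw.
#' @return list of class `"sim_config"`.
#' @export
simulation_config <- function(n_samples = 350, n_genes = 2000, n_subtypes = 3,
                              subtype_props = c(66, 128, 156) / 350,
                              cnv_driver_frac = 0.10, met_driver_frac = 0.10,
                              cnv_effect = 1.0, met_effect = -1.5,
                              noise_sd = 0.5, burden_coupling = 0.29,
                              hazard_per_subtype = c(0.0016, 0.0008, 0.0004),
                              censor_hazard = 4e-4, mutation_rate = 0.02,
                              n_triple_aberrant = 5, n_spectrum_genes = 20,
                              n_snv_effect_loci = 3,
                              aberr_gain_rate = 0.05, aberr_loss_rate = 0.04,
                              aberr_hyper_rate = 0.04, aberr_hypo_rate = 0.05,
                              decoy_segment_frac = 0.05, zero_gene_frac = 0.01,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(subtype_props) - 1) > 1e-8) stop("subtype_props must sum to 1")
  if (length(subtype_props) != n_subtypes || length(hazard_per_subtype) != n_subtypes)
    stop("subtype_props and hazard_per_subtype need one entry per subtype")
  if (cnv_driver_frac + met_driver_frac > 1) stop("driver fractions exceed 1")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (mutation_rate < 0 || mutation_rate > 1) stop("mutation_rate outside [0, 1]")
  if (cnv_effect <= 0 || met_effect >= 0)
    stop("cnv_effect must be > 0 and met_effect < 0")
  structure(cfg, class = "sim_config")
}

clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(pmax(x, lo), hi)

#' Simulate a multi-omics cohort
#'
#' Generates segments, methylation, expression (FPKM and counts), mutations,
#' clinical follow-up, gene model and probe annotation, plus a `truth`
#' element recording everything that was planted. All randomness flows from
#' `config$seed`; the same configuration reproduces the cohort exactly.
#'
#' @param config a [simulation_config()].
#' @return list with `segments`, `met` (probe-level, with missing values),
#'   `exp_fpkm`, `exp_counts`, `mutations`, `clinical`, `gene_model`,
#'   `probes`, `samples` and `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples; G <- config$n_genes; S <- config$n_subtypes

  samples <- sprintf("S%04d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(G))

  ## ---- gene model: 22 autosomes, genes spaced 100 kb, bodies 10 kb -------
  per_chrom <- ceiling(G / 22)
  chrom <- paste0("chr", ((seq_len(G) - 1) %/% per_chrom) + 1)
  idx_on_chrom <- ((seq_len(G) - 1) %% per_chrom)
  gene_start <- idx_on_chrom * 100000 + 10000
  gene_end <- gene_start + 10000
  strand <- rep(c("+", "-"), length.out = G)
  tss <- ifelse(strand == "+", gene_start, gene_end - 1)
  gene_type <- sample(c("protein_coding", "lncRNA", "miRNA", "other"), G,
                      replace = TRUE, prob = c(0.9, 0.05, 0.03, 0.02))
  gene_model <- data.frame(gene_id = genes, gene_name = genes, chrom = chrom,
                           strand = strand, tss = tss, gene_start = gene_start,
                           gene_end = gene_end, gene_type = gene_type,
                           stringsAsFactors = FALSE)

  ## ---- subtype labels ----------------------------------------------------
  sizes <- floor(config$subtype_props * n)
  sizes[S] <- n - sum(sizes[-S])
  subtype <- sample(rep(seq_len(S), times = sizes))
  names(subtype) <- samples

  ## ---- planted gene roles ------------------------------------------------
  n_cnv_drv <- round(config$cnv_driver_frac * G)
  n_met_drv <- round(config$met_driver_frac * G)
  pool <- sample(genes)
  cnv_drivers <- pool[seq_len(n_cnv_drv)]
  met_drivers <- pool[n_cnv_drv + seq_len(n_met_drv)]
  rest <- pool[-(seq_len(n_cnv_drv + n_met_drv))]
  triple <- rest[seq_len(config$n_triple_aberrant)]
  rest <- rest[-(seq_len(config$n_triple_aberrant))]
  spectrum_genes <- rest[seq_len(config$n_spectrum_genes)]
  rest <- rest[-(seq_len(config$n_spectrum_genes))]
  zero_genes <- rest[seq_len(round(config$zero_gene_frac * G))]
  cnv_drv_subtype <- stats::setNames(sample(seq_len(S), n_cnv_drv, TRUE), cnv_drivers)
  met_drv_subtype <- stats::setNames(sample(seq_len(S), n_met_drv, TRUE), met_drivers)

  ## worst / best prognosis subtypes anchor the triple-aberrant contrast
  worst <- which.max(config$hazard_per_subtype)
  best <- which.min(config$hazard_per_subtype)

  ## ---- CNV gene x sample values -----------------------------------------
  cnv <- matrix(stats::rnorm(G * n, 0, 0.08), G, n, dimnames = list(genes, samples))
  for (g in cnv_drivers) {
    mu <- ifelse(subtype == cnv_drv_subtype[g], 0.2, -0.1)
    cnv[g, ] <- cnv[g, ] + mu
  }
  ## shared instability latent couples the Gain and MetHypo burdens
  u <- stats::rnorm(n)
  v <- config$burden_coupling * u +
    sqrt(1 - config$burden_coupling^2) * stats::rnorm(n)
  n_gain <- stats::qbinom(stats::pnorm(u), G, config$aberr_gain_rate)
  n_hypo <- stats::qbinom(stats::pnorm(v), G, config$aberr_hypo_rate)
  n_loss <- stats::rbinom(n, G, config$aberr_loss_rate)
  n_hyper <- stats::rbinom(n, G, config$aberr_hyper_rate)
  for (j in seq_len(n)) {
    gi <- sample.int(G, n_gain[j])
    cnv[gi, j] <- stats::runif(n_gain[j], 0.35, 0.70)
    li <- sample.int(G, n_loss[j])
    cnv[li, j] <- stats::runif(n_loss[j], -0.70, -0.35)
  }
  ## triple-aberrant genes: loss+hyper+low expression in the worst subtype,
  ## gain+hypo+high expression in the best
  for (g in triple) {
    cnv[g, subtype == worst] <- stats::rnorm(sum(subtype == worst), -0.55, 0.05)
    cnv[g, subtype == best] <- stats::rnorm(sum(subtype == best), 0.55, 0.05)
    other <- !(subtype %in% c(worst, best))
    cnv[g, other] <- stats::rnorm(sum(other), 0, 0.05)
  }

  ## ---- methylation gene x sample betas ----------------------------------
  met_base <- stats::runif(G, 0.35, 0.75)
  met <- matrix(stats::rnorm(G * n, 0, 0.04), G, n, dimnames = list(genes, samples)) +
    met_base
  for (g in met_drivers) {
    mu <- ifelse(subtype == met_drv_subtype[g], 0.15, -0.07)
    met[g, ] <- met[g, ] + mu
  }
  for (j in seq_len(n)) {
    hi <- sample.int(G, n_hypo[j])
    met[hi, j] <- stats::runif(n_hypo[j], 0.03, 0.17)
    hy <- sample.int(G, n_hyper[j])
    met[hy, j] <- stats::runif(n_hyper[j], 0.83, 0.97)
  }
  for (g in triple) {
    met[g, subtype == worst] <- stats::rnorm(sum(subtype == worst), 0.88, 0.03)
    met[g, subtype == best] <- stats::rnorm(sum(subtype == best), 0.12, 0.03)
    other <- !(subtype %in% c(worst, best))
    met[g, other] <- stats::rnorm(sum(other), 0.5, 0.03)
  }
  met <- clip01(met)

  ## ---- expression: additive cis coupling, Gaussian noise ----------------
  baseline <- exp(stats::rnorm(G, log(5), 0.5))
  ## planted triple-aberrant genes get a moderate fixed baseline so their
  ## additive contrast is a clear fold change on the count scale too
  baseline[match(triple, genes)] <- 4
  fpkm <- matrix(stats::rnorm(G * n, 0, config$noise_sd), G, n,
                 dimnames = list(genes, samples)) + baseline
  fpkm[cnv_drivers, ] <- fpkm[cnv_drivers, ] +
    config$cnv_effect * cnv[cnv_drivers, ]
  fpkm[met_drivers, ] <- fpkm[met_drivers, ] +
    config$met_effect * (met[met_drivers, ] - 0.5)
  fpkm[triple, ] <- fpkm[triple, ] + config$cnv_effect * cnv[triple, ] +
    config$met_effect * (met[triple, ] - 0.5)

  ## ---- mutations ---------------------------------------------------------
  gene_rate <- rep(config$mutation_rate, G)
  names(gene_rate) <- genes
  mut <- matrix(stats::rbinom(G * n, 1, gene_rate), G, n,
                dimnames = list(genes, samples))  # gene rates recycle by row
  for (g in spectrum_genes) {
    mut[g, ] <- stats::rbinom(n, 1, ifelse(subtype == worst, 0.15, 0.03))
  }
  ## expression-effect loci: carriers shift a triple gene's expression
  n_loci <- if (length(triple)) config$n_snv_effect_loci else 0L
  effect_loci <- data.frame(
    snv_gene = sample(setdiff(genes, c(triple, zero_genes)), n_loci),
    target_gene = rep_len(triple, n_loci),
    hgvs_c = sprintf("c.%dC>T", sample(100:2000, n_loci)),
    shift = rep(0.8, n_loci), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(effect_loci))) {
    carriers <- stats::rbinom(n, 1, 0.08)
    mut[effect_loci$snv_gene[i], ] <- carriers
    fpkm[effect_loci$target_gene[i], ] <-
      fpkm[effect_loci$target_gene[i], ] + effect_loci$shift[i] * carriers
  }
  hit <- which(mut == 1, arr.ind = TRUE)
  vclass <- sample(c("Missense", "Nonsense", "Frameshift", "Splice", "Silent", "Intron"),
                   nrow(hit), replace = TRUE,
                   prob = c(0.60, 0.10, 0.10, 0.05, 0.10, 0.05))
  ## one canonical coding change per gene so loci recur across samples
  gene_hgvs <- stats::setNames(sprintf("c.%dG>A", sample(100:3000, G, TRUE)), genes)
  gene_hgvs[effect_loci$snv_gene] <- effect_loci$hgvs_c
  vclass[hit[, 1] %in% match(effect_loci$snv_gene, genes)] <- "Missense"
  mutations <- data.frame(
    sample_id = samples[hit[, 2]],
    gene_name = genes[hit[, 1]],
    hgvs_c = unname(gene_hgvs[genes[hit[, 1]]]),
    variant_class = vclass, stringsAsFactors = FALSE)

  ## ---- zero genes, FPKM floor, counts -----------------------------------
  fpkm <- pmax(fpkm, 0.01)
  fpkm[zero_genes, ] <- 0
  depth <- exp(stats::rnorm(n, 0, 0.1)) * 30
  mu_counts <- sweep(fpkm, 2, depth, "*")
  counts <- matrix(stats::rnbinom(G * n, mu = mu_counts, size = 10), G, n,
                   dimnames = list(genes, samples))

  ## ---- segments: one per (gene, sample), plus low-probe decoys ----------
  segments <- data.frame(
    sample_id = rep(samples, each = G),
    chrom = rep(chrom, n),
    start = rep(gene_start, n),
    end = rep(gene_end, n),
    num_probes = 5L + stats::rpois(G * n, 20),
    seg_value = as.numeric(cnv),
    stringsAsFactors = FALSE)
  n_decoy <- round(config$decoy_segment_frac * G)
  if (n_decoy > 0) {
    dg <- sample.int(G, n_decoy)
    decoys <- data.frame(
      sample_id = rep(samples, each = n_decoy),
      chrom = rep(chrom[dg], n),
      start = rep(gene_end[dg] + 20000, n),
      end = rep(gene_end[dg] + 25000, n),
      num_probes = sample(1:4, n_decoy * n, TRUE),
      seg_value = stats::rnorm(n_decoy * n, 0, 0.5),
      stringsAsFactors = FALSE)
    segments <- rbind(segments, decoys)
  }

  ## ---- probes: two promoter probes per gene, decoys, missingness --------
  off1 <- ifelse(strand == "+", -500, 500)
  off2 <- ifelse(strand == "+", 100, -100)
  probes <- data.frame(
    probe_id = c(sprintf("cg%05d_1", seq_len(G)), sprintf("cg%05d_2", seq_len(G)),
                 sprintf("cgdecoy%04d", seq_len(round(0.02 * G)))),
    chrom = c(chrom, chrom, chrom[seq_len(round(0.02 * G))]),
    position = c(tss + off1, tss + off2,
                 tss[seq_len(round(0.02 * G))] + 5000),
    region_class = sample(REGION_CLASSES, 2 * G + round(0.02 * G), TRUE,
                          prob = c(0.40, 0.18, 0.17, 0.05, 0.05, 0.15)),
    stringsAsFactors = FALSE)
  gene_of_probe <- c(seq_len(G), seq_len(G), seq_len(round(0.02 * G)))
  pm <- met[gene_of_probe, , drop = FALSE] +
    stats::rnorm(length(gene_of_probe) * n, 0, 0.02)
  pm <- clip01(pm)
  rownames(pm) <- probes$probe_id
  ## 10% of real probes get ~10% missing entries; decoys are >70% missing
  n_real <- 2 * G
  missy <- sample.int(n_real, round(0.10 * n_real))
  for (i in missy) pm[i, sample.int(n, round(0.10 * n))] <- NA
  decoy_rows <- n_real + seq_len(round(0.02 * G))
  for (i in decoy_rows) pm[i, sample.int(n, round(0.85 * n))] <- NA

  ## ---- survival ----------------------------------------------------------
  haz <- config$hazard_per_subtype[subtype]
  t_event <- stats::rexp(n, haz)
  t_cens <- stats::rexp(n, config$censor_hazard)
  os_time <- ceiling(pmin(t_event, t_cens))
  os_event <- as.integer(t_event <= t_cens)
  t_event_p <- stats::rexp(n, haz * 1.5)
  t_cens_p <- stats::rexp(n, config$censor_hazard)
  pfs_time <- ceiling(pmin(t_event_p, t_cens_p))
  pfs_event <- as.integer(t_event_p <= t_cens_p)
  clinical <- data.frame(
    sample_id = samples, os_time = os_time, os_event = os_event,
    pfs_time = pfs_time, pfs_event = pfs_event,
    stage = sample(c("II", "III", "IV"), n, TRUE, prob = c(0.1, 0.75, 0.15)),
    grade = sample(c("G1_G2", "G3_G4"), n, TRUE, prob = c(0.13, 0.87)),
    age = sample(35:85, n, TRUE), stringsAsFactors = FALSE)

  truth <- list(
    subtype_labels = subtype,
    cnv_driver_genes = cnv_drivers, met_driver_genes = met_drivers,
    cnv_driver_subtype = cnv_drv_subtype, met_driver_subtype = met_drv_subtype,
    triple_aberrant_genes = triple, spectrum_genes = spectrum_genes,
    zero_genes = zero_genes, snv_effect_loci = effect_loci,
    cnv_effect = config$cnv_effect, met_effect = config$met_effect,
    burden_coupling = config$burden_coupling,
    hazard_per_subtype = config$hazard_per_subtype,
    worst_subtype = worst, best_subtype = best)

  list(segments = segments,
       met = omics_matrix(pm, "MET"),
       exp_fpkm = omics_matrix(fpkm, "EXP_FPKM"),
       exp_counts = omics_matrix(counts, "EXP_COUNTS"),
       mutations = mutations, clinical = clinical,
       gene_model = gene_model, probes = probes,
       samples = samples, truth = truth, config = config)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_matrix_tsv <- function(mat, path, id_col) {
  df <- cbind(stats::setNames(data.frame(rownames(mat)), id_col),
              as.data.frame(apply(unclass(mat), 2, fmt_num)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Emits SEG (1-based inclusive coordinates), matrix TSVs, a MAF-like
#' mutation table, clinical and annotation TSVs, and a `truth.json` sidecar,
#' so a simulated cohort round-trips through [load_cohort()] exactly.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return named list of the file paths written, invisibly usable as the
#'   `paths` argument of [load_cohort()].
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    seg = file.path(dir, "cnv.seg"), met = file.path(dir, "met.tsv"),
    exp_fpkm = file.path(dir, "exp_fpkm.tsv"),
    exp_counts = file.path(dir, "exp_counts.tsv"),
    mutations = file.path(dir, "mutations.maf.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    gene_model = file.path(dir, "gene_model.tsv"),
    probes = file.path(dir, "probes.tsv"),
    truth = file.path(dir, "truth.json"))
  seg <- data.frame(Sample = cohort$segments$sample_id,
                    Chromosome = cohort$segments$chrom,
                    Start = cohort$segments$start + 1,  # back to 1-based inclusive
                    End = cohort$segments$end,
                    Num_Probes = cohort$segments$num_probes,
                    Segment_Mean = fmt_num(cohort$segments$seg_value))
  utils::write.table(seg, paths$seg, sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(cohort$met, paths$met, "probe_id")
  write_matrix_tsv(cohort$exp_fpkm, paths$exp_fpkm, "gene_id")
  write_matrix_tsv(cohort$exp_counts, paths$exp_counts, "gene_id")
  maf <- data.frame(Hugo_Symbol = cohort$mutations$gene_name,
                    Tumor_Sample_Barcode = cohort$mutations$sample_id,
                    Variant_Classification = cohort$mutations$variant_class,
                    HGVSc = cohort$mutations$hgvs_c)
  utils::write.table(maf, paths$mutations, sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- cohort$clinical
  names(cl)[names(cl) == "sample_id"] <- "sample"
  utils::write.table(cl, paths$clinical, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$gene_model, paths$gene_model, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$probes, paths$probes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$subtype_labels <- as.list(truth$subtype_labels)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
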