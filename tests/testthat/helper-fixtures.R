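## Small in-code fixtures shared across test files.

## segment table constructor (0-based half-open)
seg_df <- function(sample, chrom, start, end, probes, value) {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             num_probes = probes, seg_value = value, stringsAsFactors = FALSE)
}

## minimal gene model
gm_df <- function(gene_id, chrom, strand, gene_start, gene_end,
                  tss = ifelse(strand == "+", gene_start, gene_end - 1),
                  gene_type = "protein_coding") {
  data.frame(gene_id = gene_id, gene_name = gene_id, chrom = chrom,
             strand = strand, tss = tss, gene_start = gene_start,
             gene_end = gene_end, gene_type = gene_type,
             stringsAsFactors = FALSE)
}

named_matrix <- function(values, nrow, ncol, rpre = "g", cpre = "s") {
  matrix(values, nrow, ncol,
         dimnames = list(paste0(rpre, seq_len(nrow)), paste0(cpre, seq_len(ncol))))
}

## noisy block-structured non-negative matrix with planted sample clusters
block_matrix <- function(n_blocks = 3, feats_per_block = 20,
                         samples_per_block = 30, signal = 4, noise = 1,
                         seed = 1) {
  set.seed(seed)
  p <- n_blocks * feats_per_block
  n <- n_blocks * samples_per_block
  truth <- rep(seq_len(n_blocks), each = samples_per_block)
  V <- matrix(abs(rnorm(p * n, 0, noise)), p, n)
  for (b in seq_len(n_blocks)) {
    rows <- (b - 1) * feats_per_block + seq_len(feats_per_block)
    V[rows, truth == b] <- V[rows, truth == b] + signal
  }
  dimnames(V) <- list(paste0("f", seq_len(p)), paste0("s", seq_len(n)))
  list(V = V, truth = truth)
}

## small simulated cohort reused by several files (cached per session)
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulation_config(
        n_samples = 100, n_genes = 400, subtype_props = c(0.25, 0.35, 0.4),
        seed = 11))
    cache
  }
})
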