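test_that("the generator is deterministic under a fixed seed", {
  cfg <- simulation_config(n_samples = 40, n_genes = 120, seed = 31,
                           subtype_props = c(0.3, 0.3, 0.4))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$segments, b$segments)
  expect_identical(unclass(a$met), unclass(b$met))
  expect_identical(unclass(a$exp_counts), unclass(b$exp_counts))
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$subtype_labels, b$truth$subtype_labels)
})

test_that("generated data respect their type invariants", {
  co <- tiny_cohort()
  m <- unclass(co$met)
  expect_true(all(m[is.finite(m)] >= 0 & m[is.finite(m)] <= 1))
  expect_true(all(unclass(co$exp_fpkm) >= 0))
  cnt <- unclass(co$exp_counts)
  expect_true(all(cnt >= 0 & cnt == round(cnt)))
  expect_true(all(co$segments$start < co$segments$end))
  expect_true(all(co$clinical$os_time >= 0))
  expect_true(all(co$clinical$os_event %in% 0:1))
  ## decoy content exists for the filters to remove
  expect_gt(sum(co$segments$num_probes < 5), 0)
  expect_gt(sum(co$mutations$variant_class %in% c("Silent", "Intron")), 0)
  expect_gt(length(co$truth$zero_genes), 0)
  expect_true(all(rowSums(unclass(co$exp_fpkm)[co$truth$zero_genes, ]) == 0))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(cnv_driver_frac = 0.7, met_driver_frac = 0.5),
               "exceed")
  expect_error(simulation_config(subtype_props = c(0.5, 0.2)), "sum to 1|entry per subtype")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(met_effect = 1), "met_effect")
})

test_that("planted cis drivers carry the predicted correlation", {
  co <- simulate_cohort(simulation_config(
    n_samples = 350, n_genes = 600, subtype_props = c(66, 128, 156) / 350,
    seed = 37))
  fpkm <- unclass(co$exp_fpkm)
  ## reconstruct gene-level CNV directly from the per-gene segments
  segs <- co$segments[co$segments$num_probes >= 5, ]
  cnv <- map_cnv_to_genes(segs, co$gene_model)
  devs <- vapply(sample(co$truth$cnv_driver_genes, 25), function(g) {
    pred <- co$truth$cnv_effect * sd(cnv[g, ]) / sd(fpkm[g, ])
    abs(cor(cnv[g, ], fpkm[g, colnames(cnv)]) - pred)
  }, numeric(1))
  ## r-hat carries ~0.04 sampling noise at n = 350, so check the bulk
  expect_lt(unname(quantile(devs, 0.9)), 0.1)
  expect_lt(median(devs), 0.05)
  ## methylation drivers correlate negatively with expression
  met_cors <- vapply(sample(co$truth$met_driver_genes, 25), function(g) {
    pr <- sprintf("cg%05d_1", as.integer(substring(g, 2)))
    cor(unclass(co$met)[pr, ], fpkm[g, ], use = "complete.obs")
  }, numeric(1))
  expect_lt(median(met_cors), -0.1)
})

test_that("subtype survival medians track their exponential hazards", {
  co <- simulate_cohort(simulation_config(
    n_samples = 600, n_genes = 60, subtype_props = c(1, 1, 1) / 3,
    hazard_per_subtype = c(0.002, 0.001, 0.0005), censor_hazard = 1e-4,
    seed = 41))
  tl <- co$truth$subtype_labels
  for (s in 1:3) {
    idx <- tl == s
    km <- km_estimate(co$clinical$os_time[idx], co$clinical$os_event[idx])
    expect_lte(abs(km$median / (log(2) / co$truth$hazard_per_subtype[s]) - 1), 0.15)
  }
})

test_that("a written fixture round-trips through load_cohort exactly", {
  co <- simulate_cohort(simulation_config(n_samples = 25, n_genes = 80,
                                          subtype_props = c(0.3, 0.3, 0.4),
                                          seed = 43))
  dir <- withr::local_tempdir()
  paths <- write_fixture(co, dir)
  loaded <- load_cohort(paths)
  expect_equal(unclass(loaded$met), unclass(co$met))
  expect_equal(unclass(loaded$exp_fpkm), unclass(co$exp_fpkm))
  expect_equal(unclass(loaded$exp_counts), unclass(co$exp_counts))
  expect_equal(nrow(loaded$segments), nrow(co$segments))
  expect_setequal(loaded$samples, co$samples)
  expect_equal(sort(loaded$mutations$hgvs_c), sort(co$mutations$hgvs_c))
  ## truth sidecar is valid JSON
  truth <- jsonlite::read_json(paths$truth)
  expect_setequal(unlist(truth$triple_aberrant_genes), co$truth$triple_aberrant_genes)
})

test_that("both clusterings recover the planted subtypes from the driver layers", {
  co <- simulate_cohort(simulation_config(seed = 53))
  tl <- co$truth$subtype_labels
  segs <- filter_low_probe_segments(co$segments)
  cnv <- map_cnv_to_genes(segs, co$gene_model)
  metg <- aggregate_met_to_genes(filter_and_impute_met(co$met),
                                 co$probes, co$gene_model)
  fpkm <- co$exp_fpkm
  d_cnv <- unclass(cnv)[co$truth$cnv_driver_genes, ]
  d_met <- unclass(metg)[co$truth$met_driver_genes, ]
  d_exp <- unclass(fpkm)[union(co$truth$cnv_driver_genes,
                               co$truth$met_driver_genes), colnames(cnv)]

  ## consensus NMF at the planted rank on the CNV driver layer
  cc <- consensus_cluster(nonneg_embed(d_cnv), 3, n_runs = 25, seed = 53)
  expect_gte(adjusted_rand_index(cc$labels, tl[colnames(d_cnv)]), 0.9)

  ## integrative clustering across the three layers
  ic <- tune_and_cluster(list(d_cnv, d_met, d_exp), seed = 53)
  expect_equal(ic$K, 3)
  expect_gte(adjusted_rand_index(ic$labels, tl[names(ic$labels)]), 0.9)
})

test_that("a null cohort yields a calibrated correlation screen", {
  ## no planted effects and one subtype: ~1% of genes pass at p < 0.01
  cfg <- simulation_config(
    n_samples = 120, n_genes = 1000, n_subtypes = 1, subtype_props = 1,
    cnv_driver_frac = 0, met_driver_frac = 0, n_triple_aberrant = 0,
    n_spectrum_genes = 0, n_snv_effect_loci = 0, zero_gene_frac = 0,
    hazard_per_subtype = 0.001, cnv_effect = 1, met_effect = -1, seed = 47)
  co <- simulate_cohort(cfg)
  segs <- co$segments[co$segments$num_probes >= 5, ]
  cnv <- map_cnv_to_genes(segs, co$gene_model)
  rec <- gene_correlation(cnv, co$exp_fpkm)
  expect_lte(abs(mean(rec$p < 0.01) - 0.01), 0.012)
})
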