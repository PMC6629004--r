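test_that("Fisher z-transform matches 2*artanh(r) and is odd", {
  r <- seq(-0.999, 0.999, length.out = 997)
  expect_equal(fisher_z(r), 2 * atanh(r), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), log(3), tolerance = 1e-12)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  ## capping keeps z finite at |r| = 1
  expect_true(is.finite(fisher_z(1)))
})

test_that("per-gene correlation handles perfect, null and degenerate genes", {
  set.seed(4)
  n <- 30
  cnv <- named_matrix(rnorm(3 * n), 3, n)
  fpkm <- abs(cnv) + 0.1
  fpkm[1, ] <- 2 * cnv[1, ] + 10          # exact linearity -> r = 1 (capped)
  fpkm[3, ] <- 7                          # zero variance -> omitted
  rec <- gene_correlation(omics_matrix(cnv, "CNV"),
                          omics_matrix(fpkm, "EXP_FPKM"))
  expect_false("g3" %in% rec$gene_id)
  g1 <- rec[rec$gene_id == "g1", ]
  expect_equal(g1$r, 1)
  expect_true(g1$capped)
  expect_true(is.finite(g1$z))
  expect_equal(sign(rec$z), sign(rec$r))

  ## direct formula oracle on random vectors
  x <- rnorm(25); y <- abs(rnorm(25))
  one <- gene_correlation(omics_matrix(named_matrix(x, 1, 25), "CNV"),
                          omics_matrix(named_matrix(y, 1, 25), "EXP_FPKM"))
  want <- cor.test(x, y)
  expect_equal(one$r, unname(want$estimate), tolerance = 1e-12)
  expect_equal(one$p, want$p.value, tolerance = 1e-12)
})

test_that("correlation p-values are uniform under the null", {
  set.seed(9)
  n <- 40; G <- 5000
  X <- named_matrix(rnorm(G * n), G, n)
  Y <- named_matrix(abs(rnorm(G * n)), G, n)
  rec <- gene_correlation(omics_matrix(X, "CNV"), omics_matrix(Y, "EXP_FPKM"))
  ks <- suppressWarnings(ks.test(rec$p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("screen threshold endpoints select all or none", {
  rec <- data.frame(gene_id = paste0("g", 1:10), r = 0.1, z = 0.2,
                    p = seq(0.001, 0.9, length.out = 10))
  expect_length(screen_corgenes(rec, p_set = 1), 10)
  expect_length(screen_corgenes(rec, p_set = 0), 0)
  expect_false("g10" %in% screen_corgenes(rec, p_set = 0.01))
})

test_that("skewness test reproduces independent reference values", {
  right <- zshift_test(skew_right_x)
  expect_equal(right$statistic, skew_right_stat, tolerance = 1e-9)
  expect_equal(right$p, skew_right_p, tolerance = 1e-9)
  expect_equal(right$direction, "right")

  sym <- zshift_test(skew_sym_y)
  expect_equal(sym$statistic, skew_sym_stat, tolerance = 1e-9)
  expect_equal(sym$p, skew_sym_p, tolerance = 1e-9)
  expect_equal(sym$direction, "none")

  expect_error(zshift_test(rnorm(10)), "20")
})

test_that("skewness test is calibrated on symmetric data and detects right skew", {
  set.seed(12)
  dir_none <- vapply(1:20, function(i) {
    zshift_test(rnorm(10000))$direction == "none"
  }, logical(1))
  expect_gte(mean(dir_none), 0.9)
  ex <- zshift_test(rexp(1000))
  expect_lt(ex$p, 0.05)
  expect_equal(ex$direction, "right")
})

test_that("prognostic screen recovers a planted hazard gene and drops constants", {
  set.seed(21)
  n <- 300
  x <- rnorm(n)                       # log-HR 1 per unit
  t_event <- rexp(n, 0.01 * exp(x))
  t_cens <- rexp(n, 0.004)
  clinical <- data.frame(sample_id = paste0("s", 1:n),
                         os_time = pmin(t_event, t_cens),
                         os_event = as.integer(t_event <= t_cens))
  vals <- named_matrix(rnorm(2 * n), 2, n)
  vals[1, ] <- x
  vals[2, ] <- 3                      # constant -> omitted
  om <- omics_matrix(vals, "CNV")
  res <- prognostic_screen(c("g1", "g2"), om, clinical)
  expect_true(res$selected[res$gene_id == "g1"])
  expect_false("g2" %in% res$gene_id)
  expect_lte(abs(res$coef[res$gene_id == "g1"] - 1), 0.2)

  ## log-rank mode runs on the same inputs
  res_lr <- prognostic_screen("g1", om, clinical, mode = "logrank")
  expect_lt(res_lr$p, 0.05)
})

test_that("chromosome enrichment matches the hypergeometric tail", {
  ## universe of 10 genes, 5 on chrA; the set is exactly the chrA genes
  gm <- gm_df(paste0("g", 1:10), rep(c("chrA", "chrB"), each = 5), "+",
              1:10 * 1000, 1:10 * 1000 + 500)
  enr <- chromosome_enrichment(paste0("g", 1:5), gm)
  rowA <- enr[enr$chrom == "chrA", ]
  expect_equal(rowA$fisher_p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(rowA$gene_count, 5)
  expect_equal(enr$chrom[which.min(enr$fisher_p)], "chrA")
  expect_true(all(enr$fdr >= enr$fisher_p - 1e-12 | enr$fdr <= 1))
})

test_that("random gene sets are not spuriously enriched", {
  set.seed(33)
  gm <- gm_df(paste0("g", 1:400), paste0("chr", rep(1:20, each = 20)), "+",
              1:400 * 1000, 1:400 * 1000 + 500)
  hits <- replicate(200, {
    enr <- chromosome_enrichment(sample(gm$gene_id, 60), gm)
    mean(enr$fisher_p < 0.05)
  })
  ## the exact test is discrete and conservative: the nominal rate is an
  ## upper bound, not an exact level
  expect_lte(mean(hits), 0.06)
  expect_gt(mean(hits), 0.005)
})

test_that("set overlap test enumerates the hypergeometric correctly", {
  u <- paste0("g", 1:10)
  res <- set_overlap_test(u[1:5], u[1:5], 10)
  expect_equal(res$overlap, 5)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)

  big <- set_overlap_test(paste0("a", 1:50), paste0("b", 1:50), 1e5)
  expect_equal(big$overlap, 0)
  expect_gt(big$p, 0.95)

  ## A inside B with B = universe: overlap is certain
  res3 <- set_overlap_test(u[1:3], u, 10)
  expect_equal(res3$p, 1, tolerance = 1e-12)
  expect_error(set_overlap_test(u, u, 5), "larger than universe")
})
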