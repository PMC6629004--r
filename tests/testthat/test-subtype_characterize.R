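test_that("exact contingency test matches enumeration on hand cases", {
  ## 2x2 collapse: [[3,1],[1,3]] two-sided Fisher p = 34/70
  states <- c(rep("Gain", 3), "Normal", "Gain", rep("Normal", 3))
  groups <- rep(c("A", "B"), each = 4)
  p <- aberration_contingency_test(states, groups)
  expect_equal(as.numeric(p), 34 / 70, tolerance = 1e-12)
  expect_equal(attr(p, "method"), "fisher")

  ## identical group compositions -> p = 1
  st2 <- rep(c("Gain", "Loss", "Normal"), 4)
  gr2 <- rep(c("A", "B"), each = 6)
  expect_equal(as.numeric(aberration_contingency_test(st2, gr2)), 1,
               tolerance = 1e-12)

  ## maximally different groups, 2 states
  st3 <- c(rep("Gain", 5), rep("Loss", 5))
  gr3 <- rep(c("A", "B"), each = 5)
  p3 <- aberration_contingency_test(st3, gr3)
  expect_equal(as.numeric(p3), oracle_exact_rxc_p(table(gr3, st3)),
               tolerance = 1e-10)
})

test_that("Freeman-Halton p equals exhaustive enumeration on random 2x3 tables", {
  set.seed(41)
  for (rep in 1:25) {
    tab <- matrix(rpois(6, 3), 2, 3)
    if (sum(tab) > 40 || any(colSums(tab) == 0)) next
    p_pkg <- stats::fisher.test(tab)$p.value
    expect_equal(p_pkg, oracle_exact_rxc_p(tab), tolerance = 1e-9)
  }
})

test_that("oversized tables fall back to chi-square with a flag", {
  states <- sample(c("Gain", "Loss", "Normal"), 600, TRUE)
  groups <- rep(c("A", "B"), each = 300)
  p <- aberration_contingency_test(states, groups, budget = 100)
  expect_equal(attr(p, "method"), "chisq")
  expect_true(as.numeric(p) >= 0 && as.numeric(p) <= 1)
})

test_that("differential expression is calibrated, powered and antisymmetric", {
  set.seed(43)
  n <- 30; G <- 800
  mu <- exp(rnorm(G, log(100), 1))
  C <- named_matrix(rnbinom(G * n, mu = rep(mu, n), size = 10), G, n)
  grp <- factor(rep(c("A", "B"), each = n / 2)); names(grp) <- colnames(C)
  de <- differential_expression(omics_matrix(C, "EXP_COUNTS"), grp)
  expect_equal(attr(de, "method"), "nbwald_moment")
  expect_lte(abs(mean(de$p < 0.05) - 0.05), 0.025)

  ## planted 4-fold genes are detected
  up <- sample(G, 80)
  C2 <- C
  C2[up, grp == "B"] <- rnbinom(80 * n / 2, mu = rep(mu[up] * 4, n / 2), size = 10)
  de2 <- differential_expression(omics_matrix(C2, "EXP_COUNTS"), grp)
  expect_gte(mean(de2$fdr[match(rownames(C2)[up], de2$gene_id)] < 0.05), 0.9)
  expect_gt(median(de2$log2fc[match(rownames(C2)[up], de2$gene_id)]), 1)

  ## reversing the level order negates every log2 fold change
  grp_rev <- factor(as.character(grp), levels = c("B", "A")); names(grp_rev) <- names(grp)
  de3 <- differential_expression(omics_matrix(C2, "EXP_COUNTS"), grp_rev)
  expect_equal(de3$log2fc, -de2$log2fc, tolerance = 1e-8)

  ## all-zero genes are excluded
  C2[1, ] <- 0
  de4 <- differential_expression(omics_matrix(C2, "EXP_COUNTS"), grp)
  expect_false(rownames(C2)[1] %in% de4$gene_id)
})

test_that("NB Wald results track DESeq2 on a planted fold-change fixture", {
  set.seed(47)
  n <- 20; G <- 300
  mu <- exp(rnorm(G, log(80), 0.8))
  C <- named_matrix(rnbinom(G * n, mu = rep(mu, n), size = 10), G, n)
  up <- 1:30
  grp <- factor(rep(c("A", "B"), each = n / 2)); names(grp) <- colnames(C)
  C[up, grp == "B"] <- rnbinom(length(up) * n / 2,
                               mu = rep(mu[up] * 3, n / 2), size = 10)
  de_own <- differential_expression(omics_matrix(C, "EXP_COUNTS"), grp)
  de_ref <- differential_expression(omics_matrix(C, "EXP_COUNTS"), grp,
                                    method = "deseq2")
  expect_equal(attr(de_ref, "method"), "deseq2")
  shared <- intersect(de_own$gene_id, de_ref$gene_id)
  lfc_own <- de_own$log2fc[match(shared, de_own$gene_id)]
  lfc_ref <- de_ref$log2fc[match(shared, de_ref$gene_id)]
  expect_gt(cor(lfc_own, lfc_ref), 0.95)
  ## the two routes agree on which planted genes are significant
  own_hits <- de_own$gene_id[de_own$fdr < 0.05]
  ref_hits <- de_ref$gene_id[de_ref$fdr < 0.05]
  expect_gt(length(intersect(own_hits, ref_hits)) /
              max(length(union(own_hits, ref_hits)), 1), 0.7)
})

test_that("candidate intersection is a conjunction and monotone in p", {
  diffs <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    fisher_p_cnv = c(0.001, 0.001, 0.2, 0.04),
    fisher_p_met = c(0.001, 0.3, 0.001, 0.04),
    de_p = c(0.001, 0.001, 0.001, 0.04))
  expect_equal(intersect_candidates(diffs, 0.05), c("g1", "g4"))
  expect_equal(intersect_candidates(diffs, 0.01), "g1")  # monotone subset
  expect_setequal(intersect_candidates(diffs, 1.000001), diffs$gene_id)
  expect_true(all(intersect_candidates(diffs, 0.01) %in%
                    intersect_candidates(diffs, 0.05)))
  expect_equal(top_diff_genes(diffs, 2), c("g1", "g2"))
})

test_that("mutation spectrum contrast matches the hypergeometric on extremes", {
  groups <- stats::setNames(rep(c("A", "B"), each = 5), paste0("s", 1:10))
  mut <- data.frame(sample_id = paste0("s", 1:5), gene_name = "gX",
                    hgvs_c = "c.1A>G", variant_class = "Missense")
  res <- mutation_spectrum_compare(mut, groups, min_carriers = 3,
                                   alternative = "greater")
  expect_equal(res$fisher_p, 1 / choose(10, 5), tolerance = 1e-12)

  ## identical carrier fractions -> p = 1
  mut2 <- data.frame(sample_id = c("s1", "s6"), gene_name = "gY",
                     hgvs_c = "c.2A>G", variant_class = "Missense")
  res2 <- mutation_spectrum_compare(mut2, groups, min_carriers = 2)
  expect_equal(res2$fisher_p, 1, tolerance = 1e-12)

  ## genes below the carrier floor are skipped
  res3 <- mutation_spectrum_compare(mut2, groups, min_carriers = 3)
  expect_equal(nrow(res3), 0)
})

test_that("mutation spectrum null produces ~5% nominal hits", {
  set.seed(53)
  groups <- stats::setNames(rep(c("A", "B"), each = 30), paste0("s", 1:60))
  hits <- replicate(300, {
    carriers <- sample(names(groups), 12)
    mut <- data.frame(sample_id = carriers, gene_name = "g",
                      hgvs_c = "c.1A>G", variant_class = "Missense")
    mutation_spectrum_compare(mut, groups)$fisher_p < 0.05
  })
  ## Fisher is conservative at these sizes: nominal rate bounded by 5%
  expect_lte(mean(hits), 0.07)
  expect_gt(mean(hits), 0)
})

test_that("SNV-expression correlation equals the direct formula", {
  r <- snv_expression_correlation(c(1, 1, 1, 2, 2, 2), c(0, 0, 0, 1, 1, 1),
                                  target_gene = "t", snv_gene = "s", hgvs_c = "c.1A>G")
  expect_equal(r$corr, 1, tolerance = 1e-12)

  set.seed(59)
  x <- rnorm(40); carrier <- rbinom(40, 1, 0.3)
  if (sum(carrier) %in% c(0, 40)) carrier[1:5] <- 1 - carrier[1]
  got <- snv_expression_correlation(x, carrier)
  want <- sum((x - mean(x)) * (carrier - mean(carrier))) /
    sqrt(sum((x - mean(x))^2) * sum((carrier - mean(carrier))^2))
  expect_equal(got$corr, want, tolerance = 1e-12)

  ## constant carrier vector is omitted
  expect_null(snv_expression_correlation(x, rep(0, 40)))
})
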