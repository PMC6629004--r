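# triomics

Integrative molecular subtyping of tumor cohorts from three omics layers:
segmented DNA copy number (CNV), DNA methylation (MET, 450K-style beta
values) and mRNA expression (FPKM + read counts), together with somatic
mutations and clinical follow-up.

The package is aimed at computational biologists who want a tested,
reproducible implementation of the common "CNVcor/METcor" subtyping recipe
for cancer cohorts:

1. **Cis-correlation screen.** For every gene, the Pearson correlation
   between its expression and its own copy number (and, separately, its
   promoter methylation) is computed and transformed to the Fisher z scale,
   `z = ln((1+r)/(1-r)) = 2 artanh(r)`. Genes with correlation-test
   p < 0.01 form the CNVcor and METcor sets; their z distributions are
   tested for left/right shift with D'Agostino's skewness test, and the
   sets are reduced to the prognostic subset by univariate Cox regression
   (Wald p < 0.05).
2. **Per-layer subtyping.** Consensus non-negative matrix factorization
   (Brunet multiplicative updates minimizing generalized Kullback-Leibler
   divergence, 50 random restarts per rank, ranks k = 2-10, minimum
   subtype size 10) with rank selection by cophenetic correlation,
   dispersion and silhouette.
3. **Integrative subtyping.** A joint sparse Gaussian latent factor model
   across the three layers, `X_d = W_d Z + e_d`, fit by EM with
   lasso-style soft-thresholding of the loadings; the penalty is tuned on
   the 101-point midpoint grid `(2i-1)/202` over K = 2-3, clusters smaller
   than 10 samples are merged into their nearest neighbour.
4. **Aberration burdens.** Per sample, the number of genes with CNV Gain
   (beta > 0.3), CNV Loss (beta < -0.3), hypermethylation (beta > 0.8) and
   hypomethylation (beta < 0.2), and the Pearson correlations among all six
   burden pairs.
5. **Subtype characterization.** The two subtypes with extreme overall
   survival are contrasted per gene by Freeman-Halton exact tests on
   aberration states, negative-binomial Wald differential expression, and
   mutation-spectrum Fisher tests; genes significant on all three layers
   are screened for prognosis, and candidate expression is correlated with
   individual mutation loci (point-biserial r).
6. **Survival statistics.** Kaplan-Meier curves, log-rank tests, hazard
   ratios with 95% CIs (via the `survival` package), median splits and
   Benjamini-Hochberg adjustment.

A synthetic-cohort generator (`simulate_cohort()`) with planted subtypes,
cis-driven genes, coupled aberration burdens, subtype-specific survival
hazards and decoy content for every filter makes the entire pipeline
testable without any external download; every simulated cohort ships its
ground truth.

## Worked example

Simulate a small cohort with three planted subtypes and run the whole
pipeline:

```r
library(triomics)

cfg <- pipeline_config(
  simulate = simulation_config(n_samples = 100, n_genes = 400,
                               subtype_props = c(0.25, 0.35, 0.4), seed = 11),
  seed = 11, nmf_k_range = 2:4, nmf_runs = 10, lambda_points = 21)
report <- run_pipeline(cfg)
report
```

```
Multi-omics subtyping pipeline report
  samples: 100 | genes (CNV/MET/EXP): 400/400/396
  CNVcor: 47 (prognostic 28) | METcor: 48 (prognostic 24) | overlap: 5
  NMF ranks: CNVcor k = 2, METcor k = 2
  integrative subtypes: 2 (sizes 40/60)
  OS log-rank across subtypes: chi2 = 18.53, p = 1.67e-05
  burden correlation Gain~MetHypo: r = 0.444 (p = 3.69e-06)
  candidate genes (CNV+MET+EXP): 5; prognostic: 5
  ARI vs planted subtypes: NMF-CNV 0.65, NMF-MET 0.63, integrative 0.65
```

Reading the report: the correlation screen found 47 genes whose expression
tracks their own copy number and 48 tracking their own promoter
methylation (the generator planted 40 of each among 400 genes, so at this
cohort size the screen recovers essentially all of them plus a few false
positives at p < 0.01). At this small size both clusterings settle on two
subtypes — the two poor-prognosis subtypes merge, a known behaviour of
prognosis-filtered feature sets discussed in the methods vignette — and the
subtypes still separate survival sharply (log-rank p = 1.7e-05). The
per-sample CNV-gain and hypomethylation burdens are positively coupled
(r = 0.444), and all five planted triple-aberrant genes are reported as
candidates, all five with a significant univariate survival association.
(The adjusted-Rand-index line appears whenever the cohort was simulated,
since the planted labels are then known.) The
`report$characterization$snv_corr` table lists the mutation loci most
correlated with each prognostic candidate's expression, in the format
(gName, snvGene, SNV, CorrP, Corr).

At the full default scale (350 samples, 2000 genes, NMF ranks 2-10 with 50
restarts, the 101-point penalty grid) the run takes roughly ten minutes on
one core.

Individual stages are exported and usable on their own — e.g.
`gene_correlation()`, `consensus_cluster()` + `select_rank()`,
`tune_and_cluster()`, `burden_counts()`, `differential_expression()`,
`km_estimate()` / `logrank_test()` / `cox_univariate()` — see the help
pages and the methods vignette (`vignettes/multiomics-subtyping.Rmd`).

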