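# mqtlnet

Multi-environment mQTL mapping and causal metabolite network inference for
inbred crop panels.

## What it is for

Metabolite abundances measured on a diversity panel grown in replicated
multi-environment field trials are quantitative traits: they have genotypic
and genotype-by-environment (G×E) variance, heritability, and mappable loci
(metabolomic QTL, "mQTL"). `mqtlnet` implements the full analysis chain for
such studies — the setting it emulates is a panel of 135 elite winter wheat
inbred lines, ~17k post-QC SNPs, 76 leaf metabolites scored in 3 environments
× 2 replicates laid out in incomplete blocks:

1. **Synthetic data** (`sim_config()`, `simulate_genotypes()`,
   `simulate_metabolome()`): family-structured inbred genotypes and a
   metabolome generated from a linear causal DAG with planted mQTL, polygenic
   effects, G×E and replicate noise — every downstream stage is testable
   against known truth.
2. **Preprocessing** (`filter_snps()`, `normalize_to_reference()`,
   `boxcox_fit_transform()`): SNP QC (monomorphic / >5% missing / >5%
   heterozygous / <5% MAF), mixed-reference drift normalization, and Box–Cox
   variance stabilization with `lambda` chosen by profile likelihood on a
   grid.
3. **Trial model** (`adjusted_entry_means()`, `blues_across_envs()`,
   `reml_varcomp()`, `heritability()`, `repeatability()`,
   `subgroup_heritability()`): per-environment adjusted entry means with
   incomplete-block recovery, cross-environment BLUEs, one-step REML variance
   components (σ²_G, σ²_G×E, σ²_ε) with the halved-p boundary LRT, entry-mean
   heritability `H² = σ²_G / (σ²_G + σ²_G×E/nE + σ²_ε/(nE·nR))` and
   within-environment repeatability `w² = σ²_G / (σ²_G + σ²_ε/nR)`.
4. **Correlation structure** (`pairwise_correlations()`, `cluster_traits()`,
   `distance_matrix_correlation()`): Pearson correlations on BLUEs with
   cumulative significance tiers (P < 0.05 / 0.01 / 0.001), UPGMA clustering
   on `1 − r`, and a Mantel test between metabolomic and genomic line
   distances.
5. **GWAS** (`kinship()`, `mlm_scan()`, `fdr_adjust()`,
   `variance_explained()`, `pg()`): VanRaden kinship; the multi-environment
   mixed model `Y = Xβ + Ss + (S⊗X)m + Zu + e` with per-environment entry
   means stacked as the response, a fixed SNP effect `s` tested by Wald F, a
   random SNP×environment variance tested by the halved-p LRT, and a polygenic
   effect `u ~ (0, σ²_u K)` solved once per trait by eigendecomposition and
   reused across markers (P3D); Benjamini–Hochberg FDR (report at q < 0.20,
   network anchors at q < 0.10); per-SNP R² and the proportion of genotypic
   variance `p_G = R² / H²`.
6. **Causal network** (`pc_skeleton()`, `qpso_orient()`): PC-skeleton over
   the traits with significant genotypic variance (Fisher-z conditional
   independence tests), then QTL-supervised orientation — an mQTL anchor `q`
   of trait `yi` votes for `yi → yj` when `q` associates with `yj` marginally
   but not given `yi`; edges orient by strict majority, cycles are refused.

`run_pipeline()` chains all stages with one seed and writes
TSV/CSV/JSON/Newick/GraphML artifacts plus an MD5 manifest;
`inst/scripts/mqtl_pipeline.R` is a command-line wrapper.

## Worked example

```r
library(mqtlnet)
cfg <- list(seed = 42L,
  sim = list(n_lines = 135, n_families = 15, n_snps = 800, n_traits = 12,
             dag_edges = data.frame(parent = c(1, 2), child = c(2, 3),
                                    coef = c(0.8, 0.7)),
             qtl_map = data.frame(trait = c(1, 5), snp = c(100, 400),
                                  effect = c(sqrt(0.45), sqrt(0.35)))))
res <- run_pipeline(cfg)
head(res$varcomp[, 1:6], 4)
subset(res$gwas, significant)[, c("trait", "snp", "p_snp", "q", "R2", "p_G")]
res$network$edges
```

```
  trait sigma2_G sigma2_GxE sigma2_e  p_G_lrt    H2
1   M01    0.571       2.17    0.937 3.94e-04 0.393
2   M02    1.899       2.06    0.987 3.58e-16 0.690
3   M03    2.181       2.06    1.014 1.87e-18 0.718
4   M04    0.711       2.20    0.962 3.57e-05 0.443

          trait      snp    p_snp        q   R2  p_G
SNP00100    M01 SNP00100 4.80e-08 3.57e-05 25.7 65.3
SNP001001   M02 SNP00100 1.06e-05 7.89e-03 23.0 33.4
SNP004806   M07 SNP00480 4.99e-05 3.71e-02 10.8 24.1

      from  to       type     weight
1      M01 M02 undirected  0.4160211
2      M02 M03   directed  0.5860222
3 SNP00100 M01        qtl 65.2564067
4 SNP00100 M02        qtl 33.3949825
5 SNP00480 M07        qtl 24.1393048
```

Reading this: each trait's G×E variance is roughly twice its genotypic
variance (the simulated regime), so heritabilities sit near 0.5. The QTL
planted on trait M01 is detected there (R² = 25.7% of phenotypic variance;
`p_G` = 65.3% of genotypic variance after standardizing by H² = 0.39) and
again on the downstream trait M02 — pleiotropy induced by the causal edge
M01→M02. Because that SNP anchors both M01 and M02 it is excluded from voting
on the M01–M02 edge, which therefore stays undirected, while M02→M03 is
oriented by the anchor logic. SNP edges carry `p_G` as weight; trait edges
carry the Pearson correlation.

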