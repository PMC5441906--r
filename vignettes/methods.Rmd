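---
title: "Models and methods in mqtlnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mqtlnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models behind each stage of the
pipeline, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the methodology left room.

## The study design being modelled

The package targets genome–metabolite association studies on inbred crop
panels: a fixed set of lines is grown in replicated trials at several
locations, metabolite abundances are profiled per plot, and each trait is
treated as a quantitative phenotype with genotypic variance, G×E variance and
measurement noise. The default configuration mirrors a panel of 135 winter
wheat lines genotyped at ~17k post-QC SNPs, with 76 metabolite traits scored
in 3 environments × 2 replicates in incomplete blocks, and a G×E variance
about twice the genotypic variance — the regime in which heritabilities land
around 0.25–0.5 and single-trait mapping is power-limited.

## Synthetic data

`simulate_genotypes()` builds an inbred panel with family structure and no
global stratification axis: per-SNP founder allele frequencies are drawn
uniformly from `maf_range`; each family owns two founder haplotypes; each
line is one recombinant gamete of its family founders, doubled (lines are
fully homozygous before the residual heterozygosity and missingness rates are
injected). Two founders per family is the simplest generator that makes
within-family relatedness exceed between-family relatedness, which is exactly
the gradient the kinship correction in the scan must absorb. The panel is cut
into `n_families = 15` families — the family sizes of the real panel are not
public, so this is a free parameter chosen once as plausible for a European
elite breeding panel.

`simulate_metabolome()` generates genetic values in topological order of a
user-supplied causal DAG:

* each trait's *own* genetic value mixes planted QTL effects on standardized
  dosages with a polygenic component, scaled so their variances sum to
  `var_G`; a `qtl_map` effect `e` contributes exactly `e^2` of the trait's
  own genotypic variance, making planted `p_G` controllable a priori;
* the polygenic component is a genome-wide sum of small i.i.d. SNP effects
  (rescaled to its target variance), not an i.i.d. normal deviate — this ties
  the polygenic background to the realized kinship so that omitting the
  kinship correction produces the test-statistic inflation the calibration
  tests look for;
* inherited variation enters through linear path coefficients on parent
  genetic values;
* observations add an environment main effect (SD `env_effect_sd = 2`,
  reflecting the strong location effects such trials show), a G×E deviate
  (`var_GxE = 2` against `var_G = 1` by default), an incomplete-block effect
  (lines allocated to `n_blocks_per_rep = 5` blocks cyclically, offset per
  replicate) and replicate noise (`var_resid = 1`);
* heading dates are drawn independently of everything else, so
  maturity-subgroup analyses have a null ground truth.

What the generator does **not** emulate: linkage disequilibrium decay along
chromosomes (SNPs are exchangeable; the map is decorative), epistasis,
selection, non-Gaussian measurement error, and GC-MS artefacts (drift is
reduced to a per-batch reference ratio). Tests passing on this generator
therefore validate the statistical machinery — unbiasedness, calibration,
power, orientation logic — not robustness to real-data pathologies such as
strong LD or heavy-tailed residuals.

All substreams derive from one integer seed; fixed seed implies byte-identical
outputs.

## Preprocessing

SNP QC removes monomorphic markers and markers with >5% missing calls, >5%
heterozygous calls, or minor allele frequency <5% (the standard array-QC cuts
for inbred material; all four thresholds are arguments). MAF counts a
heterozygote as one copy of each allele; "monomorphic" means zero variance
among non-missing calls. The rules are independent, so filtering is
idempotent and order-free.

Box–Cox stabilization fits `lambda` on the grid −2..2 (step 0.1) by maximum
profile log-likelihood of the normal model; exact ties break toward
`lambda = 1`, then `0`, preferring interpretability. Non-positive series are
shifted by `1e-6 − min(x)`. The fit is per trait on replicate-level data
pooled across environments — the level is a package choice; fitting per
environment would also be defensible but couples the transform to the
environment partition.

The trait-level CV filter (`max_cv`, default off) is a deliberately simple
stand-in for compound-level quality assessment, which in real studies uses
instrument-specific criteria that have no equivalent on synthetic data.

## Trial model

Two-stage structure: per environment, adjusted entry means are estimated with
line fixed and replicate and block-within-replicate random (intra-block
information recovery); across environments, BLUEs are the line estimates from
a two-way fixed line + environment fit (equal to the row means when the table
is complete). Variance components come from the one-step model

    value = env (fixed) + rep/block (random) + line + line:env + error

fitted by REML via lme4. On balanced data the estimates agree with the
closed-form ANOVA expected-mean-square estimators to optimizer precision
(the test suite asserts 1e-6). The significance of σ²_G uses the boundary
likelihood-ratio test with halved p-values (an equal mixture of a point mass
and χ²₁ under the null), so the smallest attainable p at LR = 0 is 0.5.

Entry-mean heritability uses the design closed form
`H² = σ²_G / (σ²_G + σ²_G×E/nE + σ²_ε/(nE·nR))` — the plant-breeding
convention for trials with nE environments and nR replicates. Repeatability
is the within-environment analogue on replicates only; note that within one
environment the "genotypic" variance necessarily includes the G×E component,
which is why repeatabilities exceed heritability in high-G×E regimes.
Maturity subgroups are heading-date terciles (cut rules are not standardized;
terciles are the neutral choice), with a warned fallback to random equal
groups when the covariate is degenerate.

## Correlation structure

Pairwise Pearson correlations are computed on BLUEs (configurable to
per-environment entry means), with two-sided t-test p-values and *cumulative*
significance tiers at 0.05/0.01/0.001 — a pair significant at 0.001 also
counts at the looser tiers, which is the reading consistent with published
nested tier counts. Clustering is UPGMA on `d = 1 − r`. The
metabolome-genome comparison uses Euclidean distance on standardized BLUEs
versus an allele-sharing distance (mean dosage mismatch over non-missing
calls, scaled to [0, 1] — the metric is a package choice; none is canonical),
tested by a Mantel permutation test (default 9999 permutations, seeded).

## GWAS

Kinship is the VanRaden cross-product of centered dosages scaled by
`Σ 2p(1−p)`, with per-SNP mean imputation of missing calls and a 1e-6
diagonal ridge. For a fully inbred panel the diagonal sits near 1 + F ≈ 2.

The scan stacks per-environment entry means of one trait as the response and
models a fixed environment effect, a fixed SNP effect, a polygenic line
effect `u ~ N(0, σ²_u K)` shared across environments, and i.i.d. residuals.
Computationally, one eigendecomposition of K per trait rotates the model to
independent coordinates (the environment dimension is rotated so the shared
line effect loads on a single block); the two background variances are
estimated once by REML under the no-SNP null and reused for every marker
(the P3D strategy — the standard trade of a small approximation for a
~17000-fold speedup). The SNP Wald F uses the per-SNP residual scale, so with
the polygenic variance forced to zero the statistic reproduces the ordinary
least-squares F exactly (asserted to 1e-8). Environment effects are fitted
fixed; with three levels the numerical difference from a random formulation
is negligible, and fixing them keeps the per-SNP GLS closed-form.

The SNP×environment interaction is a single random variance `σ²_m` on
environment-specific SNP effects, tested per SNP by the halved-p boundary
LRT against the main-effect model (1-D REML optimization with rank-one
covariance updates; background variances held at their null estimates).
Under no interaction the LRT sits at its boundary mass, p = 0.5.

Multiple testing uses Benjamini–Hochberg q-values, flagged at q < 0.20 for
reporting and q < 0.10 for network anchors. Variance decomposition: per-SNP
R² is the marginal squared correlation of BLUEs with dosage (×100); the joint
adjusted R² comes from the multiple regression on all flagged SNPs with
rank-deficient designs handled by pivoting (duplicated markers do not inflate
it); `p_G = R²/H²` is capped at 100% with a warning. A sequential
(forward) R² would be an alternative for clusters of linked markers; the
marginal definition is the default because it is reproducible row by row.

## Causal network

Traits entering the network are those whose genotypic variance passes the
halved-p LRT at 0.05. The PC-skeleton phase starts from the complete graph
and removes an edge as soon as any conditioning subset of either endpoint's
current neighbours (size 0, 1, 2, ...) renders the pair independent by the
Fisher-z partial-correlation test at `alpha_skeleton = 0.01`. Pair order is
lexicographic and subset order is `combn()` order, making the result
deterministic for a fixed trait ordering; stability under label permutation
is tested rather than assumed. PC's neighbour restriction equals the
exhaustive all-subset search in the well-powered faithful regime (the
equivalence test runs n = 5000 with path coefficients bounded away from
zero); at small n the two can differ on borderline independence calls, which
is a property of finite-sample PC, not of this implementation.

Orientation follows instrumental-variable logic: an anchor SNP `q` of trait
`yi` (FDR-significant at q < 0.10, and not an anchor of `yj`) votes for
`yi → yj` if `q` is marginally associated with `yj` (p < `alpha_orient` =
0.05) and independent of `yj` given `yi` (p ≥ `alpha_orient`). Edges orient
to the strict-majority direction; ties and zero votes stay undirected; an
orientation that would close a directed cycle among traits is skipped and
logged. The concrete vote/veto scheme is this package's instantiation of
QTL-supervised orientation — published descriptions leave the scoring rule
open, so the rule here is documented as a design choice and validated on
anchored chain/fork/collider motifs (≥80% correct orientation at n = 500 in
the test suite). Full constraint-based orientation (collider detection, Meek
rules) and latent-variable search are out of scope: anchors are the only
source of direction, which is the point of the QTL-supervised approach.

Trait–trait edges carry the Pearson correlation of the BLUEs; SNP→trait
edges carry `p_G`.

## Numerical choices and degenerate inputs

* REML fits run through lme4 with singular fits tolerated (variance
  components may land exactly on zero); a zero-noise dataset short-circuits
  to the empirical line variance.
* `lrt_variance()` clips small negative LR to zero but errors when the
  reduced model beats the full model beyond 1e-6 — that indicates a broken
  fit, not chance.
* Collinear SNP columns (constant dosage) get NA p-values with a warning
  rather than silently dropping rows.
* Constant traits produce NA correlations excluded from tier counts;
  constant distance matrices are rejected in the Mantel test.
* Exact Box–Cox likelihood ties prefer `lambda = 1` then `0`.
* All writers emit plain text; reruns with identical config and seed are
  byte-identical (MD5-verified in the manifest).

## Problem sizes in the test suite

The suite exercises the study design at its real dimensions where the cost
is low (135 lines, 3 environments, 2 replicates for variance-component
recovery over 50 seeds; 500 SNPs × 20 seeds for scan calibration and power)
and scales the marker dimension down elsewhere, since the scan's per-marker
cost is linear and the statistical behaviour under test does not depend on
the number of markers. Network-recovery tests use n = 500 (motifs) and
n = 5000 (skeleton-oracle equivalence) observations, the sizes at which the
asymptotic guarantees being tested actually bind.

## Known limitations

* No LD structure means marker-density questions (clumping, lead-SNP
  selection, "s.a." clusters of linked markers) cannot be studied on the
  synthetic data.
* The P3D approximation slightly understates per-SNP variance-parameter
  uncertainty; for the panel sizes targeted here the calibration tests show
  the Wald test holds its size at α = 0.001.
* The interaction LRT holds background variances at their null estimates;
  very strong interactions could bias the main-effect test mildly upward.
* PC + anchor orientation recovers a partially directed graph; edges with no
  informative anchor stay undirected by design.
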