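# small helper: complete pipeline pieces for one simulated trait
scan_setup <- function(seed, n_lines = 135, n_snps = 300, qtl = NULL,
                       var_G = 1, var_GxE = 2, var_resid = 1) {
  cfg <- sim_config(n_lines = n_lines, n_families = 15, n_snps = n_snps,
                    n_traits = 1, missing_rate = 0, het_rate = 0,
                    var_G = var_G, var_GxE = var_GxE, var_resid = var_resid,
                    qtl_map = qtl, seed = seed)
  g <- simulate_genotypes(cfg)
  sim <- simulate_metabolome(g, cfg)
  em <- adjusted_entry_means(sim$pheno)
  list(geno = g, em = em, pheno = sim$pheno, truth = sim$truth)
}

test_that("kinship matches the hand-computed VanRaden cross-product", {
  dos <- matrix(c(0, 2, 2, 2, 0, 2), 3, 2,
                dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  K <- kinship(genotype_matrix(dos))
  # p = (2/3, 2/3); denominator = 2 * 2 * (2/3)(1/3) = 8/9
  expected <- matrix(c(2.5, -2, -0.5,
                       -2, 2.5, -0.5,
                       -0.5, -0.5, 1), 3, 3)
  expect_equal(unclass(K) - diag(1e-6, 3), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("duplicated lines have kinship equal to their diagonal average", {
  set.seed(5)
  dos <- matrix(sample(c(0, 2), 40 * 30, TRUE), 40, 30,
                dimnames = list(sprintf("L%02d", 1:40), sprintf("S%02d", 1:30)))
  dos[2, ] <- dos[1, ]
  K <- unclass(kinship(genotype_matrix(dos)))
  expect_equal(K[1, 2], (K[1, 1] + K[2, 2]) / 2 - 1e-6, tolerance = 1e-12)
})

test_that("unrelated equifrequent panels give near-zero mean off-diagonal kinship", {
  set.seed(11)
  dos <- matrix(2 * rbinom(200 * 5000, 1, 0.5), 200, 5000,
                dimnames = list(sprintf("L%03d", 1:200), sprintf("S%04d", 1:5000)))
  K <- unclass(kinship(genotype_matrix(dos)))
  # centering forces the mean off-diagonal to -diag/(L-1); inbred diag ~ 2
  expect_lt(abs(mean(K[upper.tri(K)])), 0.02)
  expect_lt(median(abs(K[upper.tri(K)] + 2 / 199)), 0.02)
  expect_error(kinship(genotype_matrix(
    matrix(2, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y"))))),
    "monomorphic")
})

test_that("the kinship-free scan reproduces ordinary least squares exactly", {
  st <- scan_setup(seed = 21, n_lines = 60, n_snps = 50)
  K <- kinship(st$geno)
  sc <- mlm_scan(st$em, st$geno, K, "M01", test_gxe = FALSE,
                 use_kinship = FALSE)
  M <- st$em[["M01"]]
  y <- as.vector(M)
  env <- factor(rep(colnames(M), each = nrow(M)))
  X <- as.matrix(st$geno)[rownames(M), ]
  for (s in c(3, 17, 42)) {
    fit <- summary(lm(y ~ env + rep(X[, s], ncol(M))))
    Fols <- fit$coefficients[nrow(fit$coefficients), 3]^2
    expect_equal(sc$wald_F[s], Fols, tolerance = 1e-8)
  }
})

test_that("Wald p-values are invariant to trait rescaling and allele relabeling", {
  st <- scan_setup(seed = 22, n_lines = 60, n_snps = 40)
  K <- kinship(st$geno)
  sc1 <- mlm_scan(st$em, st$geno, K, "M01", test_gxe = FALSE)
  em2 <- st$em
  em2[["M01"]] <- 2.5 * em2[["M01"]] + 7
  sc2 <- mlm_scan(em2, st$geno, K, "M01", test_gxe = FALSE)
  expect_equal(sc1$p_snp, sc2$p_snp, tolerance = 1e-6)
  # flip alleles of one SNP (0 <-> 2)
  g2 <- st$geno
  g2$dosage[, 5] <- 2 - g2$dosage[, 5]
  sc3 <- mlm_scan(st$em, g2, K, "M01", test_gxe = FALSE)
  expect_equal(sc3$p_snp[5], sc1$p_snp[5], tolerance = 1e-8)
  expect_equal(sc3$effect[5], -sc1$effect[5], tolerance = 1e-8)
})

test_that("null scans are calibrated with kinship and inflated without", {
  set.seed(1)
  ps <- c(); ps_nok <- c()
  for (s in 1:12) {
    st <- scan_setup(seed = 2000 + s, n_snps = 400)
    fs <- filter_snps(st$geno)
    K <- kinship(fs$geno)
    sc <- mlm_scan(st$em, fs$geno, K, "M01", test_gxe = FALSE)
    sc0 <- mlm_scan(st$em, fs$geno, K, "M01", test_gxe = FALSE,
                    use_kinship = FALSE)
    ps <- c(ps, sc$p_snp)
    ps_nok <- c(ps_nok, sc0$p_snp)
  }
  n <- sum(!is.na(ps))
  rate <- mean(ps < 0.001, na.rm = TRUE)
  ci_half <- 1.96 * sqrt(0.001 * 0.999 / n)
  expect_lt(abs(rate - 0.001), ci_half + 1e-12)
  expect_gt(genomic_inflation(ps_nok), 1.05)
  expect_lt(genomic_inflation(ps), 1.05)
})

test_that("a strong planted QTL is the top-ranked marker", {
  hits <- vapply(1:10, function(s) {
    st <- scan_setup(seed = 3000 + s, n_snps = 300,
                     qtl = data.frame(trait = 1, snp = 150, effect = sqrt(0.4)),
                     var_GxE = 1.5, var_resid = 1)  # entry-mean H2 = 0.6
    K <- kinship(st$geno)
    sc <- suppressWarnings(mlm_scan(st$em, st$geno, K, "M01", test_gxe = FALSE))
    which.min(sc$p_snp) == 150
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("power rises with planted effect size", {
  grid <- c(0.05, 0.2, 0.5)
  minp <- sapply(grid, function(fr) {
    vapply(1:6, function(s) {
      st <- scan_setup(seed = 6000 + s, n_lines = 100, n_snps = 60,
                       qtl = data.frame(trait = 1, snp = 30, effect = sqrt(fr)))
      K <- kinship(st$geno)
      sc <- suppressWarnings(mlm_scan(st$em, st$geno, K, "M01",
                                      test_gxe = FALSE))
      -log10(sc$p_snp[30])
    }, numeric(1))
  })
  m <- colMeans(minp)
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("SNP-by-environment interaction LRT detects a planted interaction", {
  set.seed(77)
  L <- 120; E <- 3
  dos <- matrix(2 * rbinom(L * 40, 1, 0.5), L, 40,
                dimnames = list(sprintf("L%03d", 1:L), sprintf("S%02d", 1:40)))
  g <- genotype_matrix(dos)
  base <- rnorm(L)
  M <- sapply(1:E, function(e) base + rnorm(L, 0, .5))
  # SNP 7 has an environment-specific effect
  gxe_coef <- c(-1.2, 0, 1.2)
  for (e in 1:E) M[, e] <- M[, e] + gxe_coef[e] * scale(dos[, 7])
  dimnames(M) <- list(rownames(dos), paste0("E", 1:E))
  em <- structure(list(M01 = M), lines = rownames(M), envs = colnames(M),
                  class = "entry_means")
  K <- kinship(g)
  sc <- mlm_scan(em, g, K, "M01", test_gxe = TRUE)
  expect_lt(sc$p_gxe[7], 0.01)
  # no interaction anywhere else: boundary LRT sits at its 0.5 mass
  expect_gt(median(sc$p_gxe[-7]), 0.2)
  expect_lte(max(sc$p_gxe, na.rm = TRUE), 0.5)
})

test_that("BH adjustment matches the step-up hand example and is monotone", {
  fa <- fdr_adjust(c(0.01, 0.02, 0.03, 0.04), 0.20)
  expect_equal(fa$q, rep(0.04, 4))
  expect_true(all(fa$significant))
  expect_equal(fdr_adjust(0.07)$q, 0.07)
  allone <- fdr_adjust(rep(1, 5))
  expect_true(all(allone$q == 1) && !any(allone$significant))
  expect_equal(nrow(fdr_adjust(numeric(0))), 0L)
  set.seed(3)
  p <- runif(50)
  q <- fdr_adjust(p)$q
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # flags at 0.10 are a subset of flags at 0.20
  f10 <- fdr_adjust(p, 0.10)$significant
  f20 <- fdr_adjust(p, 0.20)$significant
  expect_true(all(!f10 | f20))
})

test_that("variance explained handles exact fits, nulls and collinearity", {
  set.seed(4)
  dos <- matrix(sample(c(0, 2), 135 * 3, TRUE), 135, 3)
  b <- 2 + 0.7 * dos[, 1]
  ve <- variance_explained(b, dos[, 1, drop = FALSE])
  expect_equal(unname(ve$r2), 100)
  expect_equal(ve$adj_r2_joint, 100)
  # independent dosage: E[R2] ~ 100 / (n - 1)
  r2null <- mean(replicate(200, {
    x <- sample(c(0, 2), 135, TRUE)
    variance_explained(rnorm(135), cbind(x))$r2
  }))
  expect_lt(abs(r2null - 100 / 134), 0.25)
  # duplicated SNP column does not inflate the joint adjusted R2
  y <- 0.5 * dos[, 1] + rnorm(135)
  v1 <- variance_explained(y, dos[, 1, drop = FALSE])
  v2 <- variance_explained(y, dos[, c(1, 1)])
  expect_equal(v2$adj_r2_joint, v1$adj_r2_joint, tolerance = 1e-10)
  expect_warning(variance_explained(y, cbind(dos[, 1], rep(1, 135))), "constant")
})

test_that("p_G standardizes R2 by heritability with a cap at 100", {
  expect_equal(pg(12.69, 0.737), 17.22, tolerance = 1e-3)
  expect_equal(pg(17.36, 0.364), 47.69, tolerance = 1e-3)
  expect_equal(pg(0, 0.5), 0)
  expect_warning(out <- pg(90, 0.5), "capped")
  expect_equal(out, 100)
  expect_warning(out2 <- pg(10, 0), "outside")
  expect_true(is.na(out2))
})

test_that("p_G times H2 reproduces R2 for the reported mQTL identities", {
  tab <- read.delim(system.file("extdata", "table1_mqtl_printed.tsv",
                                package = "mqtlnet"))
  recon <- pg(tab$R2, tab$H2) * tab$H2
  expect_equal(recon, tab$R2, tolerance = 1e-10)
  expect_equal(round(pg(tab$R2, tab$H2), 2), tab$pG_printed, tolerance = 0.011)
})

test_that("the assembled scan flags the planted QTL with R2 and p_G attached", {
  st <- scan_setup(seed = 5005, n_snps = 120,
                   qtl = data.frame(trait = 1, snp = 60, effect = sqrt(0.5)),
                   var_GxE = 1.5)
  K <- kinship(st$geno)
  B <- blues_across_envs(st$em)
  v <- reml_varcomp(st$pheno, "M01")
  res <- gwas_scan(st$em, st$geno, K, B, c(M01 = v$H2), traits = "M01",
                   q_threshold = 0.20, test_gxe = FALSE)
  expect_s3_class(res, "gwas_result")
  hit <- res[res$snp == "SNP00060", ]
  expect_true(hit$significant)
  expect_gt(hit$R2, 5)
  expect_gt(hit$p_G, hit$R2)  # H2 < 1 inflates the genotypic share
  expect_true(all(res$q >= res$p_snp - 1e-12, na.rm = TRUE))
})
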