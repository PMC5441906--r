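test_that("entry means reduce to arithmetic line means on balanced complete data", {
  d <- balanced_trial_sim(1, L = 20, E = 2, R = 2)
  em <- adjusted_entry_means(d)
  raw <- tapply(d$value[d$env == "E1"], d$line[d$env == "E1"], mean)
  expect_equal(unname(em[["M1"]][names(raw), "E1"]), as.numeric(raw),
               tolerance = 1e-8)
})

test_that("entry means absorb a planted additive block effect", {
  set.seed(21)
  L <- 12
  mu <- rnorm(L, 10)
  # incomplete blocks: each rep splits lines into 3 blocks; block effects large
  d <- expand.grid(line = sprintf("L%02d", 1:L), rep = c("R1", "R2"),
                   stringsAsFactors = FALSE)
  d$env <- "E1"; d$trait <- "M1"
  i <- match(d$line, sprintf("L%02d", 1:L))
  d$block <- paste0("B", ifelse(d$rep == "R1",
                                (i - 1) %/% 4 + 1, (i + 3) %% 3 + 1))
  beff <- c(B1 = 5, B2 = 0, B3 = -5)
  d$value <- mu[i] + beff[d$block] + rnorm(nrow(d), 0, 0.05)
  em <- adjusted_entry_means(d)[["M1"]][, "E1"]
  naive <- tapply(d$value, d$line, mean)
  err_adj <- max(abs(scale(em, scale = FALSE) - scale(mu, scale = FALSE)))
  err_naive <- max(abs(scale(naive, scale = FALSE) - scale(mu, scale = FALSE)))
  expect_lt(err_adj, err_naive)
  expect_gt(cor(em, mu), 0.99)
})

test_that("a single unreplicated observation per line is returned as is", {
  d <- data.frame(line = c("A", "B", "C"), env = "E1", rep = "R1",
                  block = "B1", trait = "M1", value = c(1, 2, 3))
  em <- adjusted_entry_means(d)
  expect_equal(unname(em[["M1"]][, "E1"]), c(1, 2, 3))
})

test_that("BLUEs equal the row mean of entry means on a complete table", {
  d <- balanced_trial_sim(2, L = 15, E = 3, R = 2)
  em <- adjusted_entry_means(d)
  B <- blues_across_envs(em)
  expect_equal(unname(B[, "M1"]), unname(rowMeans(em[["M1"]])), tolerance = 1e-8)
  # constant trait: all BLUEs equal
  d2 <- d; d2$value <- 7
  B2 <- blues_across_envs(adjusted_entry_means(d2))
  expect_true(all(abs(B2 - 7) < 1e-8))
})

test_that("BLUEs for a line missing one environment solve the two-way normal equations", {
  M <- matrix(c(10, 12, 11,
                13, 15, 14,
                9, NA, 10), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("E1", "E2", "E3")))
  em <- structure(list(M1 = M), lines = rownames(M), envs = colnames(M),
                  class = "entry_means")
  B <- suppressWarnings(blues_across_envs(em))
  # independent oracle: explicit least-squares solve with sum-to-zero envs
  long <- na.omit(data.frame(v = as.vector(M),
                             line = rep(rownames(M), 3),
                             env = rep(colnames(M), each = 3)))
  Xl <- model.matrix(~ 0 + line, long)
  Xe <- model.matrix(~ env, long,
                     contrasts.arg = list(env = contr.sum))[, -1, drop = FALSE]
  X <- cbind(Xl, Xe)
  beta <- solve(crossprod(X), crossprod(X, long$v))
  expect_equal(unname(B[, "M1"]), unname(beta[1:3]), tolerance = 1e-10)
})

test_that("BLUEs are invariant to environment relabeling", {
  d <- balanced_trial_sim(3, L = 10, E = 3, R = 2)
  B1 <- blues_across_envs(adjusted_entry_means(d))
  d2 <- d
  d2$env <- c(E1 = "E3", E2 = "E1", E3 = "E2")[d$env]
  B2 <- blues_across_envs(adjusted_entry_means(d2))
  expect_equal(B1, B2, tolerance = 1e-8)
})

test_that("REML matches the closed-form ANOVA estimators on balanced data", {
  d <- balanced_trial_sim(1)
  v <- reml_varcomp(d, "M1", include_design_effects = FALSE)
  m <- anova_mom(d)
  expect_equal(v$sigma2_G, unname(m["s2g"]), tolerance = 1e-6)
  expect_equal(v$sigma2_GxE, unname(m["s2ge"]), tolerance = 1e-6)
  expect_equal(v$sigma2_e, unname(m["s2e"]), tolerance = 1e-6)
})

test_that("noise-free data return the empirical line variance as genotypic", {
  set.seed(4)
  g <- rnorm(12)
  d <- expand.grid(line = sprintf("L%02d", 1:12), env = c("E1", "E2"),
                   rep = c("R1", "R2"), stringsAsFactors = FALSE)
  d$block <- "B1"; d$trait <- "M1"
  d$value <- g[match(d$line, sprintf("L%02d", 1:12))]
  v <- reml_varcomp(d, "M1")
  lm_ <- tapply(d$value, d$line, mean)
  expect_equal(v$sigma2_G, var(as.numeric(lm_)), tolerance = 1e-6)
  expect_equal(v$sigma2_GxE, 0)
  expect_equal(v$sigma2_e, 0)
  expect_equal(v$H2, 1)
})

test_that("permuting line labels within environments destroys the genotypic variance", {
  est <- vapply(1:10, function(s) {
    d <- balanced_trial_sim(900 + s, L = 50, s2g = 1, s2ge = 0.5, s2e = 1)
    orig <- reml_varcomp(d, "M1", include_design_effects = FALSE)$sigma2_G
    set.seed(s)
    for (ev in unique(d$env)) {
      sel <- d$env == ev
      perm <- sample(unique(d$line))
      names(perm) <- unique(d$line)
      d$line[sel] <- perm[d$line[sel]]
    }
    perm_est <- reml_varcomp(d, "M1", include_design_effects = FALSE)$sigma2_G
    c(orig, perm_est)
  }, numeric(2))
  expect_lt(mean(est[2, ]), 0.15 * mean(est[1, ]))
})

test_that("halved-p variance LRT follows the boundary mixture", {
  expect_equal(lrt_variance(-100, -100), 0.5)
  expect_equal(lrt_variance(-98.08, -100), 0.5 * pchisq(3.84, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(lrt_variance(-98.08, -100), 3), 0.025)
  expect_error(lrt_variance(-100, -99), "exceeds")
  # tiny numerical violations are clipped, not fatal
  expect_equal(lrt_variance(-100 - 1e-9, -100), 0.5)
})

test_that("entry-mean heritability follows the design closed form", {
  expect_equal(heritability(c(1, 0, 0), 3, 2), 1)
  expect_equal(heritability(c(1, 1, 1), 3, 2), 1 / (1 + 1/3 + 1/6))
  expect_equal(heritability(c(0, 1, 1), 3, 2), 0)
  expect_true(is.na(heritability(c(0, 0, 0), 3, 2)))
  expect_error(heritability(c(-1, 0, 0), 3, 2), ">= 0")
})

test_that("repeatability follows its closed form and is recovered from data", {
  expect_equal(repeatability(1, 0, 2), 1)
  expect_equal(repeatability(1, 2, 2), 0.5)
  w2 <- vapply(1:25, function(s) {
    set.seed(1200 + s)
    L <- 135
    g <- rnorm(L)
    d <- expand.grid(line = sprintf("L%03d", 1:L), rep = c("R1", "R2"),
                     stringsAsFactors = FALSE)
    d$env <- "E1"; d$block <- "B1"; d$trait <- "M1"
    d$value <- g[match(d$line, sprintf("L%03d", 1:L))] + rnorm(nrow(d), 0, sqrt(2))
    v <- mqtlnet:::env_repeatability(d, include_design_effects = FALSE)
    v
  }, numeric(1))
  expect_lt(abs(mean(w2) - 0.5), 0.05)
})

test_that("H2 and repeatability are invariant to affine trait rescaling", {
  d <- balanced_trial_sim(7, L = 40)
  v1 <- reml_varcomp(d, "M1", include_design_effects = FALSE)
  d2 <- d; d2$value <- 3.7 * d$value - 12
  v2 <- reml_varcomp(d2, "M1", include_design_effects = FALSE)
  expect_equal(v1$H2, v2$H2, tolerance = 1e-5)
  expect_equal(v1$repeatability, v2$repeatability, tolerance = 1e-5)
  expect_equal(v2$sigma2_G, 3.7^2 * v1$sigma2_G, tolerance = 1e-3)
})

test_that("maturity-subgroup heritabilities are similar when heading date is independent", {
  cfg <- sim_config(n_lines = 90, n_families = 9, n_snps = 100, n_traits = 3,
                    missing_rate = 0, het_rate = 0, seed = 31)
  g <- simulate_genotypes(cfg)
  sim <- simulate_metabolome(g, cfg)
  sg <- subgroup_heritability(sim$pheno, sim$truth$heading_dates)
  expect_equal(nrow(sg), 3L)
  expect_equal(sum(sg$n_lines), 90L)
  expect_lt(max(sg$mean_H2) - min(sg$mean_H2), 0.2)
})

test_that("degenerate heading dates fall back to random equal-size groups", {
  cfg <- small_sim_config(seed = 32, n_traits = 2)
  sim <- simulate_metabolome(simulate_genotypes(cfg), cfg)
  hd <- sim$truth$heading_dates * 0 + 160
  expect_warning(sg <- subgroup_heritability(sim$pheno, hd), "degenerate")
  expect_equal(sum(sg$n_lines), 60L)
  expect_lt(max(sg$n_lines) - min(sg$n_lines), 2L)
})
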