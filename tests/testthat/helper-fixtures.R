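# Shared fixture builders and independent oracles.

# Balanced multi-environment trial data generated outside the package's own
# simulator (plain i.i.d. normal components), for variance-component oracles.
balanced_trial_sim <- function(seed, L = 135, E = 3, R = 2,
                               s2g = 1, s2ge = 2, s2e = 1) {
  set.seed(seed)
  g <- rnorm(L, 0, sqrt(s2g))
  ge <- matrix(rnorm(L * E, 0, sqrt(s2ge)), L, E)
  envfx <- rnorm(E, 0, 2)
  d <- expand.grid(line = sprintf("L%03d", 1:L),
                   env = sprintf("E%d", 1:E),
                   rep = sprintf("R%d", 1:R),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i <- match(d$line, sprintf("L%03d", 1:L))
  e <- match(d$env, sprintf("E%d", 1:E))
  d$block <- "B1"
  d$trait <- "M1"
  d$value <- 10 + g[i] + envfx[e] + ge[cbind(i, e)] + rnorm(nrow(d), 0, sqrt(s2e))
  d
}

# Closed-form ANOVA expected-mean-square estimators for the balanced design.
anova_mom <- function(d) {
  yb <- tapply(d$value, list(d$line, d$env), mean)
  L <- nrow(yb); E <- ncol(yb)
  R <- length(unique(d$rep))
  cell <- yb[cbind(match(d$line, rownames(yb)), match(d$env, colnames(yb)))]
  ms_w <- sum((d$value - cell)^2) / (L * E * (R - 1))
  lm_ <- rowMeans(yb); em <- colMeans(yb); gm <- mean(yb)
  ms_l <- E * R * sum((lm_ - gm)^2) / (L - 1)
  resid2 <- sweep(sweep(yb, 1, lm_), 2, em) + gm
  ms_le <- R * sum(resid2^2) / ((L - 1) * (E - 1))
  c(s2g = (ms_l - ms_le) / (E * R), s2ge = (ms_le - ms_w) / R, s2e = ms_w)
}

# Linear-SEM motif data with an anchored root: returns BLUE-like trait matrix,
# genotypes carrying the anchor SNPs, the anchor table and true directed edges.
sem_motif_data <- function(motif = c("chain", "fork", "collider"),
                           n = 500, seed = 1) {
  motif <- match.arg(motif)
  set.seed(seed)
  q1 <- sample(0:2, n, TRUE, prob = c(.36, .48, .16))
  q2 <- sample(0:2, n, TRUE, prob = c(.36, .48, .16))
  mk <- function(x) as.numeric(scale(x))
  noise <- function(s) rnorm(n, 0, s)
  if (motif == "chain") {
    y1 <- sqrt(.5) * mk(q1) + noise(sqrt(.5))
    y2 <- .8 * y1 + noise(.6)
    y3 <- .8 * y2 + noise(.6)
    B <- cbind(y1 = y1, y2 = y2, y3 = y3)
    anchors <- data.frame(trait = "y1", snp = "Q1", p_G = 50)
    true_edges <- rbind(c("y1", "y2"), c("y2", "y3"))
  } else if (motif == "fork") {
    y1 <- sqrt(.5) * mk(q1) + noise(sqrt(.5))
    y2 <- .8 * y1 + noise(.6)
    y3 <- .8 * y1 + noise(.6)
    B <- cbind(y1 = y1, y2 = y2, y3 = y3)
    anchors <- data.frame(trait = "y1", snp = "Q1", p_G = 50)
    true_edges <- rbind(c("y1", "y2"), c("y1", "y3"))
  } else {
    y1 <- sqrt(.5) * mk(q1) + noise(sqrt(.5))
    y2 <- sqrt(.5) * mk(q2) + noise(sqrt(.5))
    y3 <- .6 * y1 + .6 * y2 + noise(.5)
    B <- cbind(y1 = y1, y2 = y2, y3 = y3)
    anchors <- data.frame(trait = c("y1", "y2"), snp = c("Q1", "Q2"),
                          p_G = c(50, 50))
    true_edges <- rbind(c("y1", "y3"), c("y2", "y3"))
  }
  rownames(B) <- sprintf("L%03d", 1:n)
  G <- genotype_matrix(matrix(as.numeric(c(q1, q2)), n, 2,
                              dimnames = list(rownames(B), c("Q1", "Q2"))))
  list(B = B, G = G, anchors = anchors, true_edges = true_edges)
}

# Exhaustive conditional-independence skeleton: edge (i, j) kept iff NO subset
# of the remaining variables (any size) separates the pair. Independent of the
# PC search order and neighbour restriction.
exhaustive_ci_skeleton <- function(data, alpha = 0.01) {
  p <- ncol(data)
  adj <- matrix(FALSE, p, p, dimnames = list(colnames(data), colnames(data)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      rest <- setdiff(seq_len(p), c(i, j))
      sep <- FALSE
      for (k in 0:length(rest)) {
        subs <- if (k == 0) list(integer(0)) else
          combn(rest, k, simplify = FALSE)
        for (S in subs) {
          if (fisher_z_test(data, i, j, S, alpha)$p >= alpha) {
            sep <- TRUE
            break
          }
        }
        if (sep) break
      }
      adj[i, j] <- adj[j, i] <- !sep
    }
  }
  adj
}

# Random sparse linear SEM over p traits (upper-triangular DAG). Coefficients
# are bounded away from zero and share a sign, so the distribution is faithful
# to the DAG with margin (no near-cancelling paths).
random_sem <- function(p = 5, n = 800, edge_prob = 0.35, seed = 1) {
  set.seed(seed)
  Bcoef <- matrix(0, p, p)
  for (i in seq_len(p - 1))
    for (j in (i + 1):p)
      if (runif(1) < edge_prob) Bcoef[i, j] <- runif(1, 0.5, 0.9)
  X <- matrix(0, n, p)
  for (j in seq_len(p))
    X[, j] <- X %*% Bcoef[, j] + rnorm(n)
  colnames(X) <- paste0("V", seq_len(p))
  list(data = X, coef = Bcoef)
}

small_sim_config <- function(seed = 1, ...) {
  args <- list(n_lines = 60, n_families = 6, n_snps = 200, n_traits = 6,
               missing_rate = 0.01, het_rate = 0.01, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}
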