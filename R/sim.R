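#' Simulation configuration for a multi-environment metabolomics trial
#'
#' Bundles every parameter of the synthetic-data generator: panel and marker
#' design, trial layout, the causal trait model and variance components.
#' Defaults describe a panel of 135 inbred winter wheat lines with family
#' structure, ~17k post-QC biallelic SNPs, three environments with two
#' replicates laid out in incomplete blocks, and 76 metabolite traits whose
#' genotype-by-environment interaction variance is twice the genotypic
#' variance.
#'
#' @param n_lines number of inbred lines in the panel.
#' @param n_families number of families the lines are partitioned into; each
#'   family descends from its own pair of founder haplotypes.
#' @param n_snps number of biallelic SNPs.
#' @param maf_range length-2 numeric in (0, 0.5]; founder allele frequencies
#'   are drawn uniformly from this interval.
#' @param missing_rate per-call probability of a missing genotype.
#' @param het_rate per-call probability of a residual heterozygous genotype.
#' @param n_envs number of environments (locations).
#' @param n_reps number of replicates per environment.
#' @param n_blocks_per_rep number of incomplete blocks within each replicate.
#' @param n_traits number of metabolite traits.
#' @param dag_edges data.frame (or NULL) with columns `parent`, `child`,
#'   `coef` giving path coefficients of the linear causal DAG among traits
#'   (traits are indexed 1..n_traits).
#' @param qtl_map data.frame (or NULL) with columns `trait`, `snp`, `effect`:
#'   `effect` is the signed square root of the fraction of the trait's own
#'   genotypic variance attributable to that SNP, so `effect^2` is the planted
#'   proportion of genotypic variance explained.
#' @param var_G genotypic variance of each trait's own (non-inherited) genetic
#'   value.
#' @param var_GxE genotype-by-environment interaction variance.
#' @param var_resid replicate-level residual (measurement) variance.
#' @param block_sd standard deviation of incomplete-block effects.
#' @param env_effect_sd standard deviation of environment main effects.
#' @param heading_date_sd standard deviation (days) of per-line heading dates.
#' @param seed integer seed; all random substreams derive from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 135L,
                       n_families = 15L,
                       n_snps = 17372L,
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       het_rate = 0.01,
                       n_envs = 3L,
                       n_reps = 2L,
                       n_blocks_per_rep = 5L,
                       n_traits = 76L,
                       dag_edges = NULL,
                       qtl_map = NULL,
                       var_G = 1,
                       var_GxE = 2,
                       var_resid = 1,
                       block_sd = 0.5,
                       env_effect_sd = 2,
                       heading_date_sd = 3,
                       seed = 1L) {
  cfg <- list(
    n_lines = as.integer(n_lines), n_families = as.integer(n_families),
    n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
    missing_rate = missing_rate, het_rate = het_rate,
    n_envs = as.integer(n_envs), n_reps = as.integer(n_reps),
    n_blocks_per_rep = as.integer(n_blocks_per_rep),
    n_traits = as.integer(n_traits),
    dag_edges = dag_edges, qtl_map = qtl_map,
    var_G = var_G, var_GxE = var_GxE, var_resid = var_resid,
    block_sd = block_sd, env_effect_sd = env_effect_sd,
    heading_date_sd = heading_date_sd, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_families > cfg$n_lines)
    stop("n_families must not exceed n_lines")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5] and be non-decreasing")
  for (r in c("missing_rate", "het_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1)
      stop(sprintf("%s must be a probability in [0, 1]", r))
  for (v in c("var_G", "var_GxE", "var_resid"))
    if (cfg[[v]] < 0) stop(sprintf("%s must be >= 0", v))
  if (!is.null(cfg$dag_edges)) {
    de <- cfg$dag_edges
    stopifnot(is.data.frame(de), all(c("parent", "child", "coef") %in% names(de)))
    if (any(de$parent == de$child)) stop("dag_edges may not contain self-loops")
    if (!dag_is_acyclic(de, cfg$n_traits)) stop("dag_edges encode a cyclic graph")
  }
  if (!is.null(cfg$qtl_map)) {
    qm <- cfg$qtl_map
    stopifnot(is.data.frame(qm), all(c("trait", "snp", "effect") %in% names(qm)))
    if (any(qm$snp < 1L | qm$snp > cfg$n_snps)) stop("qtl_map snp index out of range")
    if (any(qm$trait < 1L | qm$trait > cfg$n_traits)) stop("qtl_map trait index out of range")
    ss <- tapply(qm$effect^2, qm$trait, sum)
    if (any(ss > 1 + 1e-8))
      stop("per-trait sum of squared qtl_map effects must not exceed 1")
  }
  invisible(cfg)
}

# Kahn's algorithm on an integer edge list; TRUE if acyclic.
dag_is_acyclic <- function(edges, n) {
  indeg <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    p <- edges$parent[k]; c <- edges$child[k]
    adj[[p]] <- c(adj[[p]], c)
    indeg[c] <- indeg[c] + 1L
  }
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen == n
}

topological_order <- function(edges, n) {
  if (is.null(edges) || nrow(edges) == 0L) return(seq_len(n))
  indeg <- integer(n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$parent[k]]] <- c(adj[[edges$parent[k]]], edges$child[k])
    indeg[edges$child[k]] <- indeg[edges$child[k]] + 1L
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- min(queue); queue <- setdiff(queue, v)
    out <- c(out, v)
    for (w in adj[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != n) stop("dag_edges encode a cyclic graph")
  out
}

#' Construct a genotype matrix object
#'
#' @param dosage numeric matrix, lines in rows, SNPs in columns, entries in
#'   \{0, 1, 2, NA\} with 1 = heterozygous.
#' @param map optional data.frame with columns `snp`, `chrom`, `pos_cM`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, map = NULL) {
  stopifnot(is.matrix(dosage))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("dosage matrix must carry line ids (rownames) and snp ids (colnames)")
  if (anyDuplicated(rownames(dosage))) stop("duplicate line ids")
  if (anyDuplicated(colnames(dosage))) stop("duplicate snp ids")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(map)) {
    stopifnot(is.data.frame(map), all(c("snp", "chrom", "pos_cM") %in% names(map)))
    map <- map[match(colnames(dosage), map$snp), , drop = FALSE]
  }
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
as.matrix.genotype_matrix <- function(x, ...) x$dosage

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d SNPs (%.2f%% missing%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage)),
              if (is.null(x$map)) ", no map" else ", mapped"))
  invisible(x)
}

#' Simulate a structured inbred genotype panel
#'
#' Lines are partitioned into families; each family owns two founder
#' haplotypes drawn from per-SNP allele frequencies sampled uniformly from
#' `maf_range`. Each line's two gametes are independent per-SNP mosaics of the
#' family founders, so realized within-family relatedness exceeds
#' between-family relatedness while no global stratification axis exists.
#' Residual heterozygous calls and missing calls are injected at the
#' configured rates. SNPs receive a genetic map (21 wheat chromosomes,
#' positions in cM).
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] with attribute `family` (per-line family id).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  L <- cfg$n_lines; S <- cfg$n_snps; Fm <- cfg$n_families
  p <- stats::runif(S, cfg$maf_range[1], cfg$maf_range[2])
  family <- rep(seq_len(Fm), length.out = L)
  # founder haplotypes: Fm families x 2 founders x S sites
  h1 <- matrix(stats::rbinom(Fm * S, 1L, rep(p, each = Fm)), Fm, S)
  h2 <- matrix(stats::rbinom(Fm * S, 1L, rep(p, each = Fm)), Fm, S)
  dosage <- matrix(0L, L, S)
  for (i in seq_len(L)) {
    f <- family[i]
    # fully inbred line: a single recombinant gamete of the two family
    # founders, doubled (panel lines are near-homozygous)
    pick <- stats::runif(S) < 0.5
    gam <- ifelse(pick, h1[f, ], h2[f, ])
    dosage[i, ] <- 2L * gam
  }
  if (cfg$het_rate > 0) {
    het <- matrix(stats::runif(L * S) < cfg$het_rate, L, S)
    dosage[het] <- 1L
  }
  mode(dosage) <- "numeric"
  if (cfg$missing_rate > 0) {
    mis <- matrix(stats::runif(L * S) < cfg$missing_rate, L, S)
    dosage[mis] <- NA_real_
  }
  rownames(dosage) <- sprintf("L%03d", seq_len(L))
  colnames(dosage) <- sprintf("SNP%05d", seq_len(S))
  chroms <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  map <- data.frame(
    snp = colnames(dosage),
    chrom = chroms[((seq_len(S) - 1L) %% 21L) + 1L],
    pos_cM = round(stats::runif(S, 0, 750), 2),
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dosage, map)
  attr(g, "family") <- stats::setNames(family, rownames(dosage))
  g
}

#' Simulate a replicated multi-environment metabolome with known causal truth
#'
#' Per-line genetic values are built in topological order of the causal DAG:
#' each trait's own genetic value combines its planted QTL effects (on
#' standardized centered dosages) with a genome-wide polygenic component, the
#' two scaled so the trait's own genotypic variance equals `var_G` and each
#' QTL contributes `effect^2` of it; inherited variation enters through the
#' DAG path coefficients applied to parent genetic values. Observations add an
#' environment main effect, a genotype-by-environment deviate, an
#' incomplete-block effect (lines allocated to blocks cyclically within each
#' replicate) and replicate-level residual noise. Heading dates are drawn
#' independently of all trait values.
#'
#' @param geno a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return list with `pheno` (long data.frame: line, env, rep, block, trait,
#'   value) and `truth` (dag, qtl_effects, genetic value matrix, variance
#'   parameters, heading dates, environment means).
#' @export
simulate_metabolome <- function(geno, cfg) {
  validate_sim_config(cfg)
  X <- as.matrix(geno)
  L <- nrow(X); Tt <- cfg$n_traits
  if (!is.null(cfg$qtl_map) && nrow(cfg$qtl_map) > 0 &&
      any(cfg$qtl_map$snp > ncol(X)))
    stop("qtl_map snp index out of range for supplied genotypes")
  set.seed(cfg$seed + 77003L)
  Ximp <- impute_dosage_mean(X)
  Xc <- scale(Ximp, center = TRUE, scale = FALSE)

  ord <- topological_order(cfg$dag_edges, Tt)
  G <- matrix(0, L, Tt)
  for (t in ord) {
    own <- numeric(L)
    frac_qtl <- 0
    if (!is.null(cfg$qtl_map)) {
      qm <- cfg$qtl_map[cfg$qtl_map$trait == t, , drop = FALSE]
      for (k in seq_len(nrow(qm))) {
        x <- Xc[, qm$snp[k]]
        sdx <- stats::sd(x)
        if (sdx > 0) {
          own <- own + qm$effect[k] * sqrt(cfg$var_G) * (x / sdx)
          frac_qtl <- frac_qtl + qm$effect[k]^2
        }
      }
    }
    # genome-wide polygenic component, scaled to the residual genetic variance
    alpha <- stats::rnorm(ncol(Xc))
    u <- as.vector(Xc %*% alpha)
    su <- stats::sd(u)
    if (su > 0 && frac_qtl < 1)
      own <- own + sqrt(cfg$var_G * (1 - frac_qtl)) * (u / su)
    inherited <- numeric(L)
    if (!is.null(cfg$dag_edges)) {
      pe <- cfg$dag_edges[cfg$dag_edges$child == t, , drop = FALSE]
      for (k in seq_len(nrow(pe)))
        inherited <- inherited + pe$coef[k] * G[, pe$parent[k]]
    }
    G[, t] <- own + inherited
  }
  rownames(G) <- rownames(X)
  colnames(G) <- sprintf("M%02d", seq_len(Tt))

  envs <- sprintf("E%d", seq_len(cfg$n_envs))
  env_mean <- matrix(stats::rnorm(cfg$n_envs * Tt, 0, cfg$env_effect_sd),
                     cfg$n_envs, Tt, dimnames = list(envs, colnames(G)))
  gxe <- array(stats::rnorm(L * cfg$n_envs * Tt, 0, sqrt(cfg$var_GxE)),
               dim = c(L, cfg$n_envs, Tt))
  heading <- stats::rnorm(L, 160, cfg$heading_date_sd)
  names(heading) <- rownames(X)

  nb <- max(1L, cfg$n_blocks_per_rep)
  recs <- vector("list", cfg$n_envs * cfg$n_reps)
  idx <- 0L
  for (e in seq_len(cfg$n_envs)) {
    for (r in seq_len(cfg$n_reps)) {
      idx <- idx + 1L
      # cyclic allocation, offset by replicate so blocks differ between reps
      block <- ((seq_len(L) - 1L + (r - 1L)) %% nb) + 1L
      beff <- stats::rnorm(nb, 0, cfg$block_sd)
      eps <- matrix(stats::rnorm(L * Tt, 0, sqrt(cfg$var_resid)), L, Tt)
      vals <- 10 + G +
        matrix(env_mean[e, ], L, Tt, byrow = TRUE) +
        gxe[, e, ] + beff[block] + eps
      recs[[idx]] <- data.frame(
        line = rep(rownames(X), Tt),
        env = envs[e],
        rep = sprintf("R%d", r),
        block = sprintf("B%d", rep(block, Tt)),
        trait = rep(colnames(G), each = L),
        value = as.vector(vals),
        stringsAsFactors = FALSE
      )
    }
  }
  pheno <- do.call(rbind, recs)
  rownames(pheno) <- NULL
  truth <- list(
    dag = cfg$dag_edges,
    qtl_effects = cfg$qtl_map,
    genetic_values = G,
    env_means = env_mean,
    heading_dates = heading,
    var_G = cfg$var_G, var_GxE = cfg$var_GxE, var_resid = cfg$var_resid,
    block_sd = cfg$block_sd, seed = cfg$seed
  )
  list(pheno = pheno, truth = truth)
}

impute_dosage_mean <- function(X) {
  if (!anyNA(X)) return(X)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.na(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  X[idx] <- mu[idx[, 2]]
  X
}

#' Validate a long-format replicated phenotype table
#'
#' @param pheno data.frame with columns line, env, rep, block, trait, value.
#' @return the validated data.frame (invisibly usable downstream).
#' @export
validate_phenotypes <- function(pheno) {
  req <- c("line", "env", "rep", "block", "trait", "value")
  if (!is.data.frame(pheno) || !all(req %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  if (!is.numeric(pheno$value)) stop("value column must be numeric")
  key <- paste(pheno$line, pheno$env, pheno$rep, pheno$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line, env, rep, trait) observations")
  pheno
}
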