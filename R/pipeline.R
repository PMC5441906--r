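#' Run the genome-metabolite analysis pipeline end to end
#'
#' Executes, in dependency order: data acquisition (simulation under the
#' configured design, or ingestion of genotype/phenotype files), SNP quality
#' control, the trial model (entry means, BLUEs, variance components,
#' heritability), metabolite correlation structure, the kinship-corrected
#' mixed-model mQTL scan with FDR control and variance decomposition, and
#' causal-network inference over the traits with significant genotypic
#' variance. Every stage is a pure function of its inputs plus the seed, so a
#' rerun with the same configuration reproduces identical numeric outputs.
#'
#' @param config a `run_config` list (see [read_run_config()]) or a path to a
#'   YAML/JSON config file. Recognized fields: `genotypes`/`phenotypes`/`map`
#'   (input paths; if absent, data are simulated), `sim` (named overrides for
#'   [sim_config()]), QC thresholds (`max_missing`, `max_het`, `min_maf`),
#'   `fdr_report`, `fdr_network`, `alpha_skeleton`, `alpha_orient`,
#'   `alpha_varG`, `test_gxe`, `seed`, `stages`, `outdir`, `force`.
#' @param outdir output directory (overrides the config field).
#' @return list with all stage results plus the written manifest.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(max_missing = 0.05, max_het = 0.05, min_maf = 0.05,
                   fdr_report = 0.20, fdr_network = 0.10,
                   alpha_skeleton = 0.01, alpha_orient = 0.05,
                   alpha_varG = 0.05, test_gxe = TRUE, seed = 1L,
                   stages = c("simulate", "qc", "trial", "corr", "gwas",
                              "network"))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  stages <- config$stages
  res <- list(seed = config$seed)
  say <- function(...) message(sprintf(...))

  if (!is.null(config$genotypes) && !is.null(config$phenotypes)) {
    say("[ingest] reading genotypes from %s", config$genotypes)
    fmt <- if (grepl("\\.vcf(\\.gz)?$", config$genotypes)) "vcf" else "matrix_tsv"
    res$geno <- read_genotypes(config$genotypes, fmt, map_path = config$map)
    res$pheno <- read_phenotypes(config$phenotypes)
    res$truth <- NULL
  } else if ("simulate" %in% stages) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    say("[simulate] %d lines x %d SNPs, %d traits, %d envs x %d reps (seed %d)",
        cfg$n_lines, cfg$n_snps, cfg$n_traits, cfg$n_envs, cfg$n_reps, cfg$seed)
    res$geno <- simulate_genotypes(cfg)
    sim <- simulate_metabolome(res$geno, cfg)
    res$pheno <- sim$pheno
    res$truth <- sim$truth
  } else stop("no input data: supply genotypes/phenotypes or enable 'simulate'")

  if ("qc" %in% stages) {
    say("[qc] SNP filters: missing <= %.2f, het <= %.2f, MAF >= %.2f",
        config$max_missing, config$max_het, config$min_maf)
    fs <- filter_snps(res$geno, config$max_missing, config$max_het,
                      config$min_maf)
    res$geno <- fs$geno
    res$qc_report <- fs$report
    say("[qc] kept %d / %d SNPs", sum(fs$report$kept), nrow(fs$report))
    if (!is.null(config$max_cv) && is.finite(config$max_cv)) {
      fc <- filter_traits_cv(res$pheno, config$max_cv)
      res$pheno <- fc$pheno
    }
  }

  if ("trial" %in% stages) {
    say("[trial] adjusted entry means, BLUEs, REML variance components")
    res$entry_means <- adjusted_entry_means(res$pheno)
    res$blues <- blues_across_envs(res$entry_means)
    res$varcomp <- varcomp_table(res$pheno)
    say("[trial] mean H2 = %.3f across %d traits",
        mean(res$varcomp$H2, na.rm = TRUE), nrow(res$varcomp))
  }

  if ("corr" %in% stages) {
    if (is.null(res$blues)) stop("correlation stage requires the trial stage")
    say("[corr] pairwise correlations and average-linkage clustering")
    res$correlation <- pairwise_correlations(res$blues)
    res$dendrogram <- if (!anyNA(res$correlation$r))
      cluster_traits(res$correlation) else NULL
  }

  if ("gwas" %in% stages) {
    if (is.null(res$entry_means)) stop("gwas stage requires the trial stage")
    say("[gwas] kinship-corrected scan; FDR report threshold %.2f",
        config$fdr_report)
    res$kinship <- kinship(res$geno)
    h2 <- stats::setNames(res$varcomp$H2, res$varcomp$trait)
    scan_traits <- res$varcomp$trait[
      !is.na(res$varcomp$p_G_lrt) & res$varcomp$p_G_lrt < config$alpha_varG]
    say("[gwas] %d trait(s) with significant genotypic variance (P < %.2f)",
        length(scan_traits), config$alpha_varG)
    res$gwas <- if (length(scan_traits))
      gwas_scan(res$entry_means, res$geno, res$kinship, res$blues, h2,
                traits = scan_traits, q_threshold = config$fdr_report,
                test_gxe = isTRUE(config$test_gxe))
    else NULL
  }

  if ("network" %in% stages) {
    if (is.null(res$gwas)) stop("network stage requires the gwas stage")
    say("[network] PC-skeleton (alpha = %.3g) + QPSO (anchors at FDR < %.2f)",
        config$alpha_skeleton, config$fdr_network)
    net_traits <- unique(res$gwas$trait)
    if (length(net_traits) >= 2L) {
      skel <- pc_skeleton(res$blues[, net_traits, drop = FALSE],
                          alpha = config$alpha_skeleton)
      sig10 <- unlist(lapply(split(seq_len(nrow(res$gwas)), res$gwas$trait),
                             function(ix) ix[fdr_adjust(res$gwas$p_snp[ix],
                                                        config$fdr_network)$significant]))
      anchors <- res$gwas[sort(sig10), , drop = FALSE]
      anchors <- data.frame(trait = anchors$trait, snp = anchors$snp,
                            p_G = anchors$p_G, stringsAsFactors = FALSE)
      res$network <- qpso_orient(skel, skel$sepset, anchors, res$geno,
                                 res$blues, alpha_orient = config$alpha_orient)
      res$skeleton <- skel
    } else say("[network] fewer than 2 scanned traits; skipping")
  }

  if (!is.null(outdir) || !is.null(config$outdir)) {
    od <- outdir %||% config$outdir
    res$manifest <- write_outputs(res, od, force = isTRUE(config$force),
                                  config = config[setdiff(names(config), "stages")])
    say("[done] outputs written to %s", od)
  }
  res
}
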