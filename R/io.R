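#' Read a genotype matrix
#'
#' Two formats are supported. `matrix_tsv`: tab-separated, lines as rows with
#' the line id in the first column, a header row of SNP ids, missing coded
#' "NA"; an optional map file (`snp`, `chrom`, `pos_cM`) may accompany it.
#' `vcf`: GT fields are converted to dosage (0/0 -> 0, 0/1 -> 1, 1/1 -> 2,
#' ./. -> missing); multi-allelic records are rejected.
#'
#' @param path genotype file.
#' @param format `"matrix_tsv"` or `"vcf"`.
#' @param map_path optional map TSV for `matrix_tsv`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("matrix_tsv", "vcf"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "matrix_tsv") {
    d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 2L) stop("genotype TSV needs a line-id column and >= 1 SNP")
    ids <- as.character(d[[1]])
    if (anyDuplicated(ids)) stop("duplicate line ids in ", path)
    X <- as.matrix(d[, -1, drop = FALSE])
    if (!is.numeric(X)) {
      bad <- which(apply(d[, -1, drop = FALSE], 1,
                         function(r) any(is.na(suppressWarnings(as.numeric(r))) &
                                           !is.na(r) & r != "NA")))[1]
      stop("malformed genotype row at line ", bad + 1L, " of ", path)
    }
    storage.mode(X) <- "double"
    rownames(X) <- ids
    map <- NULL
    if (!is.null(map_path)) {
      map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
      if (!all(c("snp", "chrom", "pos_cM") %in% names(map)))
        stop("map file needs columns snp, chrom, pos_cM")
    }
    return(genotype_matrix(X, map))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multi-allelic VCF record(s): ",
         paste(vcfR::getID(v)[multi], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% "1/1"] <- 2
    out
  }
  X <- t(apply(gt, 1, conv))
  dimnames(X) <- dimnames(gt)
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0(vcfR::getCHROM(v), "_", vcfR::getPOS(v))[is.na(ids)]
  rownames(X) <- ids
  map <- data.frame(snp = ids, chrom = vcfR::getCHROM(v),
                    pos_cM = as.numeric(vcfR::getPOS(v)),
                    stringsAsFactors = FALSE)
  genotype_matrix(t(X), map)
}

#' Write a genotype matrix (and its map) to TSV
#'
#' @param geno a [genotype_matrix()].
#' @param path output TSV path.
#' @param map_path optional path for the map TSV.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, map_path = NULL) {
  X <- as.matrix(geno)
  d <- data.frame(line = rownames(X), X, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(map_path) && !is.null(geno$map))
    utils::write.table(geno$map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read a long-format replicated phenotype table
#'
#' CSV with columns line, env, rep, block, trait, value; duplicate
#' (line, env, rep, trait) keys or non-numeric values are errors.
#'
#' @param path CSV path.
#' @return validated phenotype data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("line", "env", "rep", "block", "trait", "value")
  if (!all(req %in% names(d)))
    stop("phenotype CSV needs columns: ", paste(req, collapse = ", "))
  if (!is.numeric(d$value)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$value))))[1]
    stop("non-numeric value at data row ", bad, " of ", path)
  }
  validate_phenotypes(d)
}

#' Write a phenotype table to CSV
#'
#' @param pheno phenotype data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(validate_phenotypes(pheno), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Unknown fields are kept; missing fields take package defaults. Thresholds
#' are validated to lie in \[0, 1\].
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(
    max_missing = 0.05, max_het = 0.05, min_maf = 0.05,
    fdr_report = 0.20, fdr_network = 0.10,
    alpha_skeleton = 0.01, alpha_orient = 0.05,
    alpha_varG = 0.05, max_cv = Inf,
    test_gxe = TRUE, seed = 1L,
    stages = c("simulate", "qc", "trial", "corr", "gwas", "network")
  )
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (th in c("max_missing", "max_het", "min_maf", "fdr_report",
               "fdr_network", "alpha_skeleton", "alpha_orient", "alpha_varG"))
    if (cfg[[th]] < 0 || cfg[[th]] > 1)
      stop(th, " must lie in [0, 1]")
  cfg$seed <- as.integer(cfg$seed)
  for (pth in c("genotypes", "phenotypes", "map"))
    if (!is.null(cfg[[pth]]) && !file.exists(cfg[[pth]]))
      stop("configured path does not exist: ", cfg[[pth]])
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write pipeline outputs with a reproducibility manifest
#'
#' Writes whichever result components are present in `results` (genotypes,
#' phenotypes, variance components, correlation matrices and tier summary,
#' dendrogram as Newick, GWAS table, network as GraphML/SIF/DOT) and a JSON
#' manifest holding the seed, configuration echo and MD5 content hashes, so a
#' rerun with the same config and seed is byte-verifiable.
#'
#' @param results named list of pipeline results.
#' @param outdir output directory.
#' @param force overwrite existing files.
#' @param config optional configuration list echoed into the manifest.
#' @return manifest list, invisibly.
#' @export
write_outputs <- function(results, outdir, force = FALSE, config = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest_path <- file.path(outdir, "manifest.json")
  paths <- character(0)
  emit <- function(fname) {
    p <- file.path(outdir, fname)
    if (file.exists(p) && !force)
      stop("output exists (use force = TRUE): ", p)
    paths[[length(paths) + 1L]] <<- p
    p
  }
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  if (!is.null(results$geno)) {
    write_genotypes(results$geno, emit("genotypes.tsv"), emit("map.tsv"))
  }
  if (!is.null(results$pheno))
    write_phenotypes(results$pheno, emit("phenotypes.csv"))
  if (!is.null(results$qc_report))
    utils::write.table(results$qc_report, emit("snp_qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(results$varcomp))
    utils::write.table(results$varcomp, emit("variance_components.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(results$blues)) {
    B <- data.frame(line = rownames(results$blues),
                    unclass(results$blues), check.names = FALSE)
    utils::write.table(B, emit("blues.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(results$correlation)) {
    cs <- results$correlation
    utils::write.table(cs$r, emit("correlation_r.tsv"), sep = "\t", quote = FALSE)
    utils::write.table(cs$p, emit("correlation_p.tsv"), sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(n_pairs = cs$n_pairs, tiers = cs$tiers),
      emit("correlation_tiers.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$dendrogram))
    ape::write.tree(ape::as.phylo(results$dendrogram), emit("dendrogram.nwk"))
  if (!is.null(results$gwas))
    utils::write.table(results$gwas, emit("gwas_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(results$network)) {
    write_graphml(results$network, emit("network.graphml"))
    write_sif(results$network, emit("network.sif"))
    write_dot(results$network, emit("network.dot"))
  }
  manifest <- list(
    seed = results$seed %||% NA,
    config = config,
    files = lapply(stats::setNames(paths, basename(unlist(paths))),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
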