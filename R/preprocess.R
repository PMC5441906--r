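#' SNP quality control
#'
#' Removes SNPs that are monomorphic (zero variance among non-missing calls),
#' exceed the missing-call or heterozygosity thresholds, or fall below the
#' minor-allele-frequency threshold. MAF is computed on non-missing calls with
#' heterozygotes contributing one copy of each allele. The default thresholds
#' (5% missing, 5% heterozygosity, 5% MAF) are the conventional array-QC cuts
#' for inbred panels.
#'
#' @param geno a [genotype_matrix()].
#' @param max_missing maximum tolerated missing-call fraction.
#' @param max_het maximum tolerated heterozygous-call fraction.
#' @param min_maf minimum tolerated minor allele frequency.
#' @return list with `geno` (filtered matrix) and `report` (per-SNP QcReport
#'   data.frame plus attribute `removed`, counts per rule).
#' @export
filter_snps <- function(geno, max_missing = 0.05, max_het = 0.05,
                        min_maf = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  for (th in c(max_missing, max_het, min_maf))
    if (th < 0 || th > 1) stop("thresholds must lie in [0, 1]")
  X <- as.matrix(geno)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty genotype matrix")
  n_call <- colSums(!is.na(X))
  miss <- 1 - n_call / nrow(X)
  het <- colMeans(X == 1, na.rm = TRUE)
  het[n_call == 0L] <- 0
  f_alt <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(f_alt, 1 - f_alt)
  maf[n_call == 0L] <- 0
  mono <- apply(X, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) == 0L || stats::var(v) == 0
  })
  kept <- !mono & miss <= max_missing & het <= max_het & maf >= min_maf
  report <- data.frame(
    snp = colnames(X),
    missing_frac = miss,
    het_frac = het,
    maf = maf,
    monomorphic = mono,
    kept = kept,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(report, "removed") <- c(
    monomorphic = sum(mono),
    missing = sum(miss > max_missing),
    heterozygosity = sum(het > max_het),
    maf = sum(!mono & maf < min_maf),
    total = sum(!kept)
  )
  out <- genotype_matrix(X[, kept, drop = FALSE],
                         if (is.null(geno$map)) NULL
                         else geno$map[kept, , drop = FALSE])
  attr(out, "family") <- attr(geno, "family")
  list(geno = out, report = report)
}

#' Normalize abundances to a per-batch reference sample
#'
#' Each observation is divided by its batch's mixed-reference abundance and
#' rescaled by the grand mean of the references, removing systematic drift
#' between measurement batches while keeping the original scale.
#'
#' @param values numeric abundance vector.
#' @param batch batch label per observation.
#' @param reference named numeric vector of reference abundances, one per
#'   batch label.
#' @return normalized abundance vector.
#' @export
normalize_to_reference <- function(values, batch, reference) {
  stopifnot(length(values) == length(batch))
  batch <- as.character(batch)
  bad <- setdiff(unique(batch), names(reference))
  if (length(bad)) stop("no reference value for batch: ", paste(bad, collapse = ", "))
  nonpos <- names(reference)[!is.finite(reference) | reference <= 0]
  if (length(nonpos))
    stop("non-positive reference value for batch: ", paste(nonpos, collapse = ", "))
  unname(values / reference[batch] * mean(reference))
}

#' Fit and apply a Box-Cox power transformation
#'
#' Selects the power `lambda` on a grid by maximum profile log-likelihood of
#' the normal model (via [MASS::boxcox()]); exact likelihood ties are broken
#' toward `lambda = 1`, then `lambda = 0`. Non-positive inputs are handled by
#' an additive shift of `1e-6 - min(x)`. The transform is
#' `((x + shift)^lambda - 1) / lambda` for `lambda != 0` and `log(x + shift)`
#' at `lambda = 0`.
#'
#' @param x numeric abundance series with at least 3 distinct finite values.
#' @param grid candidate lambda values.
#' @return list with `transformed` (numeric vector) and `fit` (list: lambda,
#'   shift, loglik).
#' @export
boxcox_fit_transform <- function(x, grid = seq(-2, 2, by = 0.1)) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("series contains non-finite values")
  if (length(unique(x)) < 3L)
    stop("series must contain at least 3 distinct finite values")
  shift <- if (min(x) <= 0) 1e-6 - min(x) else 0
  y <- x + shift
  bc <- MASS::boxcox(y ~ 1, data = data.frame(y = y), lambda = grid,
                     plotit = FALSE)
  best <- max(bc$y)
  cand <- bc$x[bc$y >= best - 1e-9]
  lambda <- if (any(abs(cand - 1) < 1e-12)) 1 else
    if (any(abs(cand) < 1e-12)) 0 else cand[which.max(bc$y[bc$y >= best - 1e-9])]
  transformed <- boxcox_apply(y, lambda)
  list(transformed = transformed,
       fit = list(lambda = lambda, shift = shift, loglik = best))
}

boxcox_apply <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

#' Drop traits with excessive replicate-level coefficient of variation
#'
#' A simple configurable stand-in for compound-level quality assessment: the
#' CV of raw replicate values within each (line, environment) cell is averaged
#' per trait and traits above the cut are dropped. Off by default
#' (`max_cv = Inf`).
#'
#' @param pheno long phenotype table.
#' @param max_cv maximum tolerated mean within-cell CV.
#' @return list with `pheno` (filtered) and `cv` (per-trait mean CV).
#' @export
filter_traits_cv <- function(pheno, max_cv = Inf) {
  validate_phenotypes(pheno)
  cell <- interaction(pheno$trait, pheno$line, pheno$env, drop = TRUE)
  mu <- tapply(pheno$value, cell, mean)
  sdv <- tapply(pheno$value, cell, stats::sd)
  cv <- abs(sdv / mu)
  trait_of_cell <- tapply(as.character(pheno$trait), cell, `[`, 1L)
  trait_cv <- tapply(cv, trait_of_cell, mean, na.rm = TRUE)
  keep <- names(trait_cv)[is.na(trait_cv) | trait_cv <= max_cv]
  list(pheno = pheno[pheno$trait %in% keep, , drop = FALSE],
       cv = trait_cv)
}
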