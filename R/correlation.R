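#' Pairwise metabolite correlations with cumulative significance tiers
#'
#' Pearson correlations and two-sided t-test p-values for every unordered
#' trait pair on line-level BLUEs, with cumulative counts at the p < 0.05,
#' 0.01 and 0.001 tiers (a pair significant at 0.001 also counts at the looser
#' tiers). Constant traits yield missing correlations, excluded from the tier
#' counts with a warning.
#'
#' @param blues numeric matrix of BLUEs, lines x traits.
#' @return object of class `correlation_summary`: list with `r`, `p`,
#'   `n_pairs`, `n` (lines) and `tiers` (data.frame alpha, count, percent).
#' @export
pairwise_correlations <- function(blues) {
  B <- unclass(blues)
  stopifnot(is.matrix(B), ncol(B) >= 2L)
  n <- nrow(B)
  if (n < 3L) stop("need at least 3 lines")
  sds <- apply(B, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE))
    warning("constant trait(s): ",
            paste(colnames(B)[which(sds == 0)], collapse = ", "),
            "; their pairs are excluded from tier counts")
  r <- suppressWarnings(stats::cor(B, use = "pairwise.complete.obs"))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  Tn <- ncol(B)
  n_pairs <- as.integer(Tn * (Tn - 1L) / 2L)
  plow <- p[lower.tri(p)]
  alphas <- c(0.05, 0.01, 0.001)
  counts <- vapply(alphas, function(a) sum(plow < a, na.rm = TRUE), numeric(1))
  tiers <- data.frame(alpha = alphas, count = counts,
                      percent = 100 * counts / n_pairs)
  structure(list(r = r, p = p, n_pairs = n_pairs, n = n, tiers = tiers),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf("correlation_summary: %d traits, %d pairs, n = %d lines\n",
              ncol(x$r), x$n_pairs, x$n))
  for (i in seq_len(nrow(x$tiers)))
    cat(sprintf("  P < %-5s: %5d pairs (%.2f%%)\n", x$tiers$alpha[i],
                x$tiers$count[i], x$tiers$percent[i]))
  invisible(x)
}

#' Average-linkage clustering of traits on correlation distance
#'
#' UPGMA agglomeration on the distance `d = 1 - r` between traits.
#'
#' @param summary a [pairwise_correlations()] result (or a correlation
#'   matrix).
#' @return an [stats::hclust] dendrogram.
#' @export
cluster_traits <- function(summary) {
  r <- if (inherits(summary, "correlation_summary")) summary$r else summary
  if (anyNA(r)) stop("correlation matrix contains missing values")
  stats::hclust(stats::as.dist(1 - r), method = "average")
}

#' Euclidean distance between lines on standardized BLUEs
#'
#' @param blues lines x traits BLUE matrix.
#' @return a line x line distance matrix.
#' @export
metabolite_distance <- function(blues) {
  B <- scale(unclass(blues))
  as.matrix(stats::dist(B))
}

#' Allele-sharing genomic distance between lines
#'
#' Mean absolute dosage mismatch over non-missing SNP pairs, scaled to
#' \[0, 1\] (identical lines 0, opposite homozygotes everywhere 1).
#'
#' @param geno a [genotype_matrix()].
#' @return a line x line distance matrix.
#' @export
genomic_distance <- function(geno) {
  X <- as.matrix(geno)
  # stats::dist drops missing pairs and rescales the sum by n / n_used,
  # so dividing by 2 * n_snps yields the mean mismatch over non-missing calls
  D <- as.matrix(stats::dist(X, method = "manhattan")) / (2 * ncol(X))
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Mantel correlation between two line-distance matrices
#'
#' Pearson correlation of the lower-triangle entries, with significance from a
#' Mantel permutation test (label permutations of one matrix, via
#' [vegan::mantel()]).
#'
#' @param metabolite_dist square symmetric distance matrix.
#' @param genomic_dist square symmetric distance matrix over the same lines.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @return list with `r` and `p`.
#' @export
distance_matrix_correlation <- function(metabolite_dist, genomic_dist,
                                        n_perm = 9999L, seed = 1L) {
  m <- as.matrix(metabolite_dist); g <- as.matrix(genomic_dist)
  if (!all(dim(m) == dim(g)) || nrow(m) != ncol(m))
    stop("distance matrices must be square and of equal dimension")
  if (max(abs(m - t(m))) > 1e-8 || max(abs(g - t(g))) > 1e-8)
    stop("distance matrices must be symmetric")
  for (d in list(m, g))
    if (stats::sd(d[lower.tri(d)]) == 0)
      stop("distance matrix is constant off-diagonal; correlation undefined")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(m), stats::as.dist(g),
                       method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p = unname(fit$signif))
}
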