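#' Genomic relationship (kinship) matrix
#'
#' VanRaden-form kinship: missing dosages are mean-imputed per SNP, dosages
#' centered at twice the allele frequency, and the cross-product scaled by
#' `sum(2 p (1 - p))`. A ridge of 1e-6 is added to the diagonal so downstream
#' eigendecompositions are strictly positive definite.
#'
#' @param geno a [genotype_matrix()] (post-QC).
#' @return symmetric line x line matrix of class `kinship`.
#' @export
kinship <- function(geno) {
  X <- as.matrix(geno)
  if (ncol(X) < 2L) stop("need at least 2 SNPs to build a kinship matrix")
  X <- impute_dosage_mean(X)
  p <- colMeans(X) / 2
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("all SNPs monomorphic; kinship undefined")
  Xc <- sweep(X, 2, 2 * p)
  K <- tcrossprod(Xc) / denom
  diag(K) <- diag(K) + 1e-6
  dimnames(K) <- list(rownames(X), rownames(X))
  class(K) <- c("kinship", class(K))
  K
}

# Orthonormal basis of R^E whose first column is 1/sqrt(E): rotates the
# environment dimension so the shared line effect loads on one block only.
env_rotation <- function(E) {
  Q <- qr.Q(qr(cbind(rep(1, E), diag(E)[, -E, drop = FALSE])))
  Q * sign(Q[1, 1])
}

# REML log-likelihood, up to a constant in X, for V = diag(v) + c * blockdiag
# rank-one tt' per environment block. y, X are rotated; v is the full diagonal.
reml_loglik_rank1 <- function(y, X, v, tvec, cc, L, E) {
  n <- length(y); p <- ncol(X)
  logdet <- 0
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  for (j in seq_len(E)) {
    idx <- ((j - 1L) * L + 1L):(j * L)
    vj <- v[idx]
    yj <- y[idx]; Xj <- X[idx, , drop = FALSE]
    logdet <- logdet + sum(log(vj))
    Xv <- Xj / vj
    yv <- yj / vj
    if (cc > 0) {
      tv <- tvec / vj
      den <- 1 + cc * sum(tvec * tv)
      logdet <- logdet + log(den)
      tX <- as.vector(crossprod(Xv, tvec))   # t' V0^-1 X
      ty <- sum(tv * yj)
      XtVX <- XtVX + crossprod(Xj, Xv) - (cc / den) * tcrossprod(tX)
      XtVy <- XtVy + as.vector(crossprod(Xv, yj)) - (cc / den) * tX * ty
      ytVy <- ytVy + sum(yv * yj) - (cc / den) * ty^2
    } else {
      XtVX <- XtVX + crossprod(Xj, Xv)
      XtVy <- XtVy + as.vector(crossprod(Xv, yj))
      ytVy <- ytVy + sum(yv * yj)
    }
  }
  ch <- tryCatch(chol(XtVX), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  beta <- backsolve(ch, forwardsolve(t(ch), XtVy))
  yPy <- ytVy - sum(XtVy * beta)
  -0.5 * ((n - p) * log(2 * pi) + logdet + 2 * sum(log(diag(ch))) + yPy)
}

#' Multi-environment mixed-model association scan
#'
#' Stacks per-environment adjusted entry means of one trait as the response
#' and fits, per SNP, the mixed model with fixed environment effects, a fixed
#' SNP main effect, a polygenic line effect with covariance proportional to
#' the kinship matrix (identical line effect across environments), and
#' i.i.d. residuals. The two background variance components are estimated once
#' by REML under the no-SNP null (EMMA-style eigendecomposition of K) and
#' reused for every marker (P3D strategy); each SNP is then tested by a Wald F
#' statistic with one numerator degree of freedom. Optionally, a random
#' SNP-by-environment interaction variance is tested per SNP by the halved-p
#' boundary likelihood-ratio test against the main-effect-only model.
#'
#' @param em an [adjusted_entry_means()] object.
#' @param geno a [genotype_matrix()] (post-QC).
#' @param K kinship matrix from [kinship()] (or identity).
#' @param trait trait name present in `em`.
#' @param test_gxe test the SNP-by-environment interaction variance per SNP
#'   (costs one 1-D REML optimization per marker).
#' @param use_kinship set FALSE to force the polygenic variance to zero
#'   (fixed-effects scan; used for diagnostics).
#' @return data.frame, one row per SNP: trait, snp, chrom, pos_cM, effect,
#'   wald_F, p_snp, p_gxe; attributes `sigma2_u`, `sigma2_e` hold the null
#'   variance components.
#' @export
mlm_scan <- function(em, geno, K, trait, test_gxe = TRUE, use_kinship = TRUE) {
  stopifnot(inherits(em, "entry_means"), trait %in% names(em))
  M <- em[[trait]]
  keep <- rowSums(is.na(M)) == 0L
  if (!all(keep)) {
    warning(sprintf("dropping %d line(s) with incomplete entry means", sum(!keep)))
    M <- M[keep, , drop = FALSE]
  }
  if (ncol(M) < 2L) stop("need entry means for at least 2 environments")
  X <- impute_dosage_mean(as.matrix(geno))[rownames(M), , drop = FALSE]
  L <- nrow(M); E <- ncol(M); n <- L * E
  K <- unclass(K)[rownames(M), rownames(M)]
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8) stop("kinship matrix is not positive semi-definite")
  U <- eg$vectors
  d <- pmax(eg$values, 0)
  Q <- env_rotation(E)

  rotate <- function(v) as.vector(crossprod(U, matrix(v, L, E)) %*% Q)
  ystar <- rotate(as.vector(M))
  Xenv <- matrix(0, n, E)
  for (e in seq_len(E)) {
    z <- matrix(0, L, E); z[, e] <- 1
    Xenv[, e] <- rotate(as.vector(z))
  }
  lambda <- c(E * d, rep(0, L * (E - 1L)))   # eigenvalues of J_E (x) K

  # null REML over delta = sigma2_u / sigma2_e
  prof <- function(logdelta) {
    w <- exp(logdelta) * lambda + 1
    Xw <- Xenv / w
    A <- crossprod(Xenv, Xw)
    b <- as.vector(crossprod(Xw, ystar))
    beta <- solve(A, b)
    rss <- sum((ystar - Xenv %*% beta)^2 / w)
    s2 <- rss / (n - E)
    -0.5 * ((n - E) * (log(2 * pi * s2) + 1) + sum(log(w)) +
              determinant(A, logarithm = TRUE)$modulus)
  }
  if (use_kinship) {
    opt <- stats::optimize(prof, interval = c(-12, 12), maximum = TRUE)
    delta <- exp(opt$maximum)
  } else delta <- 0
  w <- delta * lambda + 1
  Xw <- Xenv / w
  A <- crossprod(Xenv, Xw)
  beta0 <- solve(A, as.vector(crossprod(Xw, ystar)))
  s2e <- sum((ystar - Xenv %*% beta0)^2 / w) / (n - E)
  s2u <- delta * s2e
  v <- s2u * lambda + s2e

  # rotated SNP main effects live in the first block only, scaled by sqrt(E)
  Tm <- crossprod(U, X) * sqrt(E)          # L x S
  b1 <- seq_len(L)
  w1 <- v[b1]
  y1 <- ystar[b1]
  X1 <- Xenv[b1, , drop = FALSE]
  Av <- crossprod(Xenv, Xenv / v)
  Xy <- as.vector(crossprod(Xenv / v, ystar))
  Ainv <- solve(Av)
  AinvXy <- Ainv %*% Xy
  beta_v <- as.vector(AinvXy)
  yPy0 <- sum(ystar^2 / v) - sum(Xy * beta_v)
  sxx <- colSums(Tm^2 / w1)
  sxy <- as.vector(crossprod(Tm / w1, y1))
  sxX <- crossprod(Tm / w1, X1)            # S x E
  Mh <- sxX %*% Ainv                       # S x E
  schur <- sxx - rowSums(Mh * sxX)
  bnum <- sxy - as.vector(sxX %*% AinvXy)
  ok <- schur > 1e-10
  effect <- ifelse(ok, bnum / schur, NA_real_)
  # Wald F with the per-SNP residual scale, so the kinship-free case
  # reproduces the ordinary least-squares F exactly
  yPys <- pmax(yPy0 - bnum^2 / schur, .Machine$double.eps)
  Fstat <- ifelse(ok, (bnum^2 / schur) * (n - E - 1) / yPys, NA_real_)
  p_snp <- stats::pf(Fstat, 1, n - E - 1, lower.tail = FALSE)
  if (any(!ok)) warning(sum(!ok), " SNP(s) collinear with the intercept; p set NA")

  p_gxe <- rep(NA_real_, ncol(X))
  if (test_gxe) {
    vtot <- stats::var(ystar)
    for (s in which(ok)) {
      xsnp <- numeric(n); xsnp[b1] <- Tm[, s]
      Xf <- cbind(Xenv, xsnp)
      tvec <- Tm[, s] / sqrt(E)            # U's, the per-block loading
      ll0 <- reml_loglik_rank1(ystar, Xf, v, tvec, 0, L, E)
      ofn <- function(cc) reml_loglik_rank1(ystar, Xf, v, tvec, cc, L, E)
      op <- stats::optimize(ofn, interval = c(0, 5 * vtot), maximum = TRUE)
      llm <- max(op$objective, ll0)
      p_gxe[s] <- lrt_variance(llm, ll0)
    }
  }
  map <- geno$map
  res <- data.frame(
    trait = trait,
    snp = colnames(X),
    chrom = if (is.null(map)) NA_character_ else map$chrom[match(colnames(X), map$snp)],
    pos_cM = if (is.null(map)) NA_real_ else map$pos_cM[match(colnames(X), map$snp)],
    effect = effect,
    wald_F = Fstat,
    p_snp = p_snp,
    p_gxe = p_gxe,
    stringsAsFactors = FALSE
  )
  attr(res, "sigma2_u") <- s2u
  attr(res, "sigma2_e") <- s2e
  res
}

#' Benjamini-Hochberg q-values with significance flags
#'
#' @param pvalues numeric p-values in \[0, 1\].
#' @param q_threshold FDR level for the significance flag (the scan reports at
#'   0.20; the network stage consumes anchors at 0.10).
#' @return data.frame with p, q and significant flag.
#' @export
fdr_adjust <- function(pvalues, q_threshold = 0.20) {
  if (length(pvalues) == 0L)
    return(data.frame(p = numeric(0), q = numeric(0), significant = logical(0)))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, q = q, significant = !is.na(q) & q < q_threshold)
}

#' Phenotypic variance explained by selected SNPs
#'
#' Per-SNP marginal R-squared (100 times the squared Pearson correlation of
#' the BLUEs with the dosage) and the joint adjusted R-squared from the
#' multiple regression of the BLUEs on all selected SNPs (rank-deficient
#' designs are handled by pivoting, so duplicated markers do not inflate the
#' joint value).
#'
#' @param blues numeric vector of per-line BLUEs for one trait.
#' @param snps numeric dosage matrix (lines x selected SNPs).
#' @return list with `r2` (named per-SNP, percent) and `adj_r2_joint`
#'   (percent).
#' @export
variance_explained <- function(blues, snps) {
  snps <- as.matrix(snps)
  stopifnot(length(blues) == nrow(snps), ncol(snps) >= 1L)
  snps <- impute_dosage_mean(snps)
  r2 <- apply(snps, 2, function(x) {
    if (stats::sd(x) == 0) {
      warning("constant dosage among selected SNPs; R2 set to 0")
      return(0)
    }
    100 * stats::cor(blues, x)^2
  })
  fit <- stats::lm(blues ~ snps)
  adj <- suppressWarnings(100 * summary(fit)$adj.r.squared)
  list(r2 = r2, adj_r2_joint = adj)
}

#' Proportion of genotypic variance explained by a marker
#'
#' Standardizes the phenotypic variance explained by broad-sense heritability:
#' `p_G = R2 / H2`, capped at 100% (capped values flagged with a warning).
#'
#' @param r2_percent phenotypic variance explained, percent.
#' @param h2 broad-sense heritability in (0, 1].
#' @return p_G in percent (vectorized).
#' @export
pg <- function(r2_percent, h2) {
  out <- rep(NA_real_, length(r2_percent))
  bad <- is.na(h2) | h2 <= 0 | h2 > 1
  if (any(bad)) warning("heritability outside (0, 1]; p_G set to NA")
  ok <- !bad
  out[ok] <- r2_percent[ok] / rep(h2, length.out = length(r2_percent))[ok]
  if (any(out > 100, na.rm = TRUE)) {
    warning("p_G capped at 100%")
    out <- pmin(out, 100)
  }
  out
}

#' Genomic-control inflation factor
#'
#' Ratio of the median association chi-square to its null median; values
#' near 1 indicate a well-calibrated scan.
#'
#' @param p vector of association p-values.
#' @return lambda_GC.
#' @export
genomic_inflation <- function(p) {
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}

#' Scan all traits and assemble the mQTL result table
#'
#' Runs [mlm_scan()] per trait, applies BH-FDR within trait, and for
#' FDR-significant SNPs adds the marginal R-squared, the per-trait joint
#' adjusted R-squared and `p_G`.
#'
#' @param em entry means; @param geno genotypes; @param K kinship.
#' @param blues BLUE matrix (for variance decomposition).
#' @param h2 named per-trait heritability vector.
#' @param traits traits to scan (default: all in `em`).
#' @param q_threshold FDR level for reporting.
#' @param test_gxe test SNP-by-environment interactions.
#' @return data.frame of class `gwas_result` with one row per (trait, SNP):
#'   p_snp, p_gxe, q, significant, R2, adj_R2_joint, p_G.
#' @export
gwas_scan <- function(em, geno, K, blues, h2, traits = names(em),
                      q_threshold = 0.20, test_gxe = TRUE) {
  out <- lapply(traits, function(tr) {
    res <- mlm_scan(em, geno, K, tr, test_gxe = test_gxe)
    fa <- fdr_adjust(res$p_snp, q_threshold)
    res$q <- fa$q
    res$significant <- fa$significant
    res$R2 <- NA_real_
    res$adj_R2_joint <- NA_real_
    res$p_G <- NA_real_
    sig <- which(res$significant)
    if (length(sig)) {
      X <- impute_dosage_mean(as.matrix(geno))[rownames(blues), res$snp[sig], drop = FALSE]
      ve <- variance_explained(blues[, tr], X)
      res$R2[sig] <- ve$r2
      res$adj_R2_joint[sig] <- ve$adj_r2_joint
      res$p_G[sig] <- suppressWarnings(pg(ve$r2, h2[[tr]]))
    }
    res
  })
  res <- do.call(rbind, out)
  class(res) <- c("gwas_result", class(res))
  res
}
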