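#' Per-environment adjusted entry means
#'
#' For each environment and trait, fits line as a fixed effect with replicate
#' and incomplete block within replicate as random effects (intra-block
#' information recovery), and returns the estimated line means. Degenerate
#' designs reduce gracefully: a single observation per line returns the raw
#' values; a design without usable replicate/block structure returns ordinary
#' least-squares line means.
#'
#' @param pheno long phenotype table (line, env, rep, block, trait, value).
#' @param traits optional character subset of traits.
#' @return object of class `entry_means`: a named list (one element per trait)
#'   of line x environment matrices, with attributes `lines` and `envs`.
#' @export
adjusted_entry_means <- function(pheno, traits = NULL) {
  validate_phenotypes(pheno)
  if (is.null(traits)) traits <- sort(unique(as.character(pheno$trait)))
  lines <- sort(unique(as.character(pheno$line)))
  envs <- sort(unique(as.character(pheno$env)))
  out <- vector("list", length(traits))
  names(out) <- traits
  for (tr in traits) {
    M <- matrix(NA_real_, length(lines), length(envs),
                dimnames = list(lines, envs))
    for (ev in envs) {
      d <- pheno[pheno$trait == tr & pheno$env == ev, , drop = FALSE]
      if (nrow(d) == 0L) next
      em <- env_entry_means(d)
      M[names(em), ev] <- em
    }
    out[[tr]] <- M
  }
  structure(out, lines = lines, envs = envs, class = "entry_means")
}

# One environment, one trait: fixed line, random rep and block-within-rep.
env_entry_means <- function(d) {
  d$line <- factor(d$line)
  d$rep <- factor(d$rep)
  d$blk <- factor(paste(d$rep, d$block, sep = ":"))
  per_line <- table(d$line)
  if (all(per_line == 1L))
    return(stats::setNames(d$value, as.character(d$line))[levels(d$line)])
  has_rep <- nlevels(d$rep) > 1L
  has_blk <- nlevels(d$blk) > nlevels(d$rep)
  if (!has_rep && !has_blk) {
    fit <- stats::lm(value ~ 0 + line, data = d)
    return(stats::setNames(stats::coef(fit), levels(d$line)))
  }
  form <- if (has_rep && has_blk) value ~ 0 + line + (1 | rep) + (1 | blk)
          else if (has_rep) value ~ 0 + line + (1 | rep)
          else value ~ 0 + line + (1 | blk)
  fit <- quiet_lmer(form, d)
  if (is.null(fit)) {
    fit <- stats::lm(value ~ 0 + line, data = d)
    return(stats::setNames(stats::coef(fit), levels(d$line)))
  }
  stats::setNames(as.numeric(lme4::fixef(fit)), levels(d$line))
}

quiet_lmer <- function(form, data, ...) {
  res <- tryCatch(
    withCallingHandlers(
      lme4::lmer(form, data = data, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"),
                 ...),
      warning = function(w) invokeRestart("muffleWarning"),
      message = function(m) invokeRestart("muffleMessage")
    ),
    error = function(e) NULL
  )
  res
}

#' Best linear unbiased estimates of lines across environments
#'
#' Fits line and environment as fixed effects on the entry-mean table. With a
#' complete line x environment table this equals the per-line mean of entry
#' means; incomplete tables are solved by two-way least squares. Lines with no
#' entry mean in any environment are dropped with a warning.
#'
#' @param em an [adjusted_entry_means()] object.
#' @return numeric matrix, lines x traits, of BLUEs (class `blues`).
#' @export
blues_across_envs <- function(em) {
  stopifnot(inherits(em, "entry_means"))
  lines <- attr(em, "lines")
  traits <- names(em)
  B <- matrix(NA_real_, length(lines), length(traits),
              dimnames = list(lines, traits))
  for (tr in traits) {
    M <- em[[tr]]
    all_missing <- rowSums(!is.na(M)) == 0L
    if (any(all_missing))
      warning(sprintf("trait %s: dropping %d line(s) with no entry means",
                      tr, sum(all_missing)))
    if (all(!is.na(M[!all_missing, , drop = FALSE]))) {
      B[!all_missing, tr] <- rowMeans(M[!all_missing, , drop = FALSE])
    } else {
      d <- data.frame(
        line = factor(rep(rownames(M), ncol(M)), levels = rownames(M)),
        env = factor(rep(colnames(M), each = nrow(M))),
        value = as.vector(M)
      )
      d <- d[!is.na(d$value), , drop = FALSE]
      fit <- stats::lm(value ~ 0 + line + env,
                       data = d,
                       contrasts = list(env = "contr.sum"))
      cf <- stats::coef(fit)
      lc <- cf[paste0("line", rownames(M))]
      # sum-to-zero env contrasts make line coefficients means over envs
      B[, tr] <- as.numeric(lc)
      B[all_missing, tr] <- NA_real_
    }
  }
  class(B) <- c("blues", class(B))
  B
}

#' One-step REML variance components for a multi-environment trial
#'
#' Fits, per trait, the one-step model
#' `value = env + rep-within-env + block-within-rep + line + line:env + error`
#' with line and line-by-environment random, environments fixed, and trial
#' design terms random, by REML (via lme4). Returns the genotypic,
#' genotype-by-environment and residual variance components, the halved-p
#' likelihood-ratio test of the genotypic variance, entry-mean heritability
#' and per-environment repeatabilities.
#'
#' @param pheno long phenotype table.
#' @param trait trait name.
#' @param include_design_effects include random replicate/block terms (set
#'   FALSE for textbook balanced two-way data).
#' @return list: sigma2_G, sigma2_GxE, sigma2_e, loglik, p_G_lrt, H2,
#'   repeatability (named per env), n_envs, n_reps.
#' @export
reml_varcomp <- function(pheno, trait, include_design_effects = TRUE) {
  validate_phenotypes(pheno)
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("trait not found: ", trait)
  d$line <- factor(d$line)
  d$env <- factor(d$env)
  d$repf <- factor(paste(d$env, d$rep, sep = ":"))
  d$blkf <- factor(paste(d$env, d$rep, d$block, sep = ":"))
  n_envs <- nlevels(d$env)
  n_reps <- length(unique(d$rep))
  if (n_envs < 2L || n_reps < 2L)
    stop("need >= 2 environments and >= 2 replicates to separate all components")

  line_means <- tapply(d$value, d$line, mean)
  if (all(abs(d$value - line_means[d$line]) < 1e-12)) {
    s2g <- stats::var(as.numeric(line_means))
    w <- rep(1, n_envs); names(w) <- levels(d$env)
    return(list(sigma2_G = s2g, sigma2_GxE = 0, sigma2_e = 0,
                loglik = NA_real_, p_G_lrt = 0, H2 = 1,
                repeatability = w, n_envs = n_envs, n_reps = n_reps))
  }

  terms <- "(1 | line) + (1 | line:env)"
  if (include_design_effects) {
    if (nlevels(d$repf) > n_envs) terms <- paste(terms, "+ (1 | repf)")
    if (nlevels(d$blkf) > nlevels(d$repf)) terms <- paste(terms, "+ (1 | blkf)")
  }
  full_form <- stats::as.formula(paste("value ~ env +", terms))
  fit <- quiet_lmer(full_form, d)
  if (is.null(fit)) stop("REML fit failed for trait ", trait)
  vc <- as.data.frame(lme4::VarCorr(fit))
  getvar <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  s2g <- getvar("line")
  s2ge <- getvar("line:env")
  s2e <- vc$vcov[vc$grp == "Residual"]

  red_form <- stats::as.formula(
    paste("value ~ env +", sub("\\(1 \\| line\\) \\+ ", "", terms)))
  fit0 <- quiet_lmer(red_form, d)
  p_g <- if (is.null(fit0)) NA_real_ else
    lrt_variance(as.numeric(stats::logLik(fit)), as.numeric(stats::logLik(fit0)))

  H2 <- heritability(c(s2g, s2ge, s2e), n_envs, n_reps)
  w <- vapply(levels(d$env), function(ev)
    env_repeatability(d[d$env == ev, , drop = FALSE], include_design_effects),
    numeric(1))
  list(sigma2_G = s2g, sigma2_GxE = s2ge, sigma2_e = s2e,
       loglik = as.numeric(stats::logLik(fit)), p_G_lrt = p_g, H2 = H2,
       repeatability = w, n_envs = n_envs, n_reps = n_reps)
}

# within-environment two-component fit -> repeatability w2
env_repeatability <- function(d, include_design_effects = TRUE) {
  d$line <- factor(d$line)
  d$repf <- factor(d$rep)
  d$blkf <- factor(paste(d$rep, d$block, sep = ":"))
  n_reps <- nlevels(d$repf)
  if (n_reps < 2L) return(NA_real_)
  terms <- "(1 | line)"
  fixed <- if (include_design_effects && n_reps > 1L) "repf" else "1"
  if (include_design_effects && nlevels(d$blkf) > n_reps)
    terms <- paste(terms, "+ (1 | blkf)")
  fit <- quiet_lmer(stats::as.formula(paste("value ~", fixed, "+", terms)), d)
  if (is.null(fit)) return(NA_real_)
  vc <- as.data.frame(lme4::VarCorr(fit))
  s2g <- vc$vcov[vc$grp == "line"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  repeatability(s2g, s2e, n_reps)
}

#' Halved-p likelihood ratio test for a variance component on the boundary
#'
#' The likelihood ratio statistic for a single variance component tested
#' against zero has a boundary null distribution approximated by an equal
#' mixture of a point mass at zero and chi-square with 1 df; the resulting
#' p-value is half the chi-square(1) upper tail, with LR clipped at zero.
#'
#' @param full_loglik log-likelihood of the model including the component.
#' @param reduced_loglik log-likelihood of the model without it.
#' @param tol numerical tolerance for `reduced > full` violations.
#' @return p-value.
#' @export
lrt_variance <- function(full_loglik, reduced_loglik, tol = 1e-6) {
  if (reduced_loglik > full_loglik + tol)
    stop("reduced model log-likelihood exceeds full model beyond tolerance")
  lr <- max(0, 2 * (full_loglik - reduced_loglik))
  0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Entry-mean broad-sense heritability
#'
#' `H2 = s2_G / (s2_G + s2_GxE / n_envs + s2_e / (n_envs * n_reps))`, the
#' fraction of entry-mean variance attributable to genotypes under the trial
#' design.
#'
#' @param vc numeric vector `c(sigma2_G, sigma2_GxE, sigma2_e)` (or a list
#'   with those names).
#' @param n_envs number of environments.
#' @param n_reps number of replicates per environment.
#' @return H2 in \[0, 1\], or NA when all components are zero.
#' @export
heritability <- function(vc, n_envs, n_reps) {
  if (is.list(vc)) vc <- c(vc$sigma2_G, vc$sigma2_GxE, vc$sigma2_e)
  stopifnot(length(vc) == 3L)
  if (any(vc < 0)) stop("variance components must be >= 0")
  denom <- vc[1] + vc[2] / n_envs + vc[3] / (n_envs * n_reps)
  if (denom == 0) return(NA_real_)
  unname(vc[1] / denom)
}

#' Within-environment repeatability
#'
#' `w2 = s2_G / (s2_G + s2_e / n_reps)` on replicate means within one
#' environment.
#'
#' @param sigma2_G within-environment genotypic variance.
#' @param sigma2_e within-environment residual variance.
#' @param n_reps number of replicates.
#' @return w2 in \[0, 1\], or NA when both components are zero.
#' @export
repeatability <- function(sigma2_G, sigma2_e, n_reps) {
  if (sigma2_G < 0 || sigma2_e < 0) stop("variance components must be >= 0")
  denom <- sigma2_G + sigma2_e / n_reps
  if (denom == 0) return(NA_real_)
  sigma2_G / denom
}

#' Variance components and heritability for every trait
#'
#' Convenience wrapper running [reml_varcomp()] across traits.
#'
#' @param pheno long phenotype table.
#' @param traits optional subset.
#' @param include_design_effects passed through.
#' @return data.frame: trait, sigma2_G, sigma2_GxE, sigma2_e, p_G_lrt, H2 and
#'   one repeatability column per environment.
#' @export
varcomp_table <- function(pheno, traits = NULL, include_design_effects = TRUE) {
  if (is.null(traits)) traits <- sort(unique(as.character(pheno$trait)))
  rows <- lapply(traits, function(tr) {
    v <- reml_varcomp(pheno, tr, include_design_effects)
    out <- data.frame(trait = tr, sigma2_G = v$sigma2_G,
                      sigma2_GxE = v$sigma2_GxE, sigma2_e = v$sigma2_e,
                      p_G_lrt = v$p_G_lrt, H2 = v$H2,
                      stringsAsFactors = FALSE)
    for (ev in names(v$repeatability))
      out[[paste0("w2_", ev)]] <- v$repeatability[[ev]]
    out
  })
  do.call(rbind, rows)
}

#' Heritability within maturity subgroups
#'
#' Splits lines into groups by heading date (terciles by default), reruns the
#' variance-component model within each group, and reports the per-group mean
#' heritability across traits. When the heading-date covariate is degenerate
#' (a single value), lines are split into equal-size random groups with a
#' warning.
#'
#' @param pheno long phenotype table.
#' @param heading_dates named numeric vector, one heading date per line.
#' @param n_groups number of quantile groups.
#' @param traits optional trait subset.
#' @return data.frame: group, n_lines, mean_H2.
#' @export
subgroup_heritability <- function(pheno, heading_dates, n_groups = 3L,
                                  traits = NULL) {
  validate_phenotypes(pheno)
  lines <- unique(as.character(pheno$line))
  if (!all(lines %in% names(heading_dates)))
    stop("heading date missing for some lines")
  hd <- heading_dates[lines]
  qs <- stats::quantile(hd, probs = seq(0, 1, length.out = n_groups + 1L))
  if (anyDuplicated(qs)) {
    warning("degenerate heading dates; using equal-size random groups")
    grp <- rep(seq_len(n_groups), length.out = length(lines))
    grp <- grp[sample.int(length(grp))]
  } else {
    grp <- as.integer(cut(hd, qs, include.lowest = TRUE, labels = FALSE))
  }
  names(grp) <- lines
  if (is.null(traits)) traits <- sort(unique(as.character(pheno$trait)))
  out <- lapply(seq_len(n_groups), function(g) {
    gl <- lines[grp == g]
    if (length(gl) < 10L)
      warning(sprintf("maturity group %d has only %d lines", g, length(gl)))
    sub <- pheno[pheno$line %in% gl, , drop = FALSE]
    h2 <- vapply(traits, function(tr)
      tryCatch(reml_varcomp(sub, tr)$H2, error = function(e) NA_real_),
      numeric(1))
    data.frame(group = g, n_lines = length(gl),
               mean_H2 = mean(h2, na.rm = TRUE))
  })
  do.call(rbind, out)
}
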