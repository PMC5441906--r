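#' Fisher-z conditional independence test
#'
#' Partial correlation of columns `i` and `j` of `data` given the columns in
#' `cond_set`, computed from the inverse of the submatrix of the correlation
#' matrix; significance from the Fisher z statistic
#' `atanh(r) * sqrt(n - |S| - 3)` against the standard normal.
#'
#' @param data numeric matrix (observations x variables).
#' @param i,j column indices or names of the tested pair.
#' @param cond_set indices/names of the conditioning set (may be empty).
#' @param alpha significance level recorded in the result.
#' @return list: i, j, cond_set, r_partial, z, p, independent (p >= alpha).
#' @export
fisher_z_test <- function(data, i, j, cond_set = integer(0), alpha = 0.01) {
  data <- as.matrix(data)
  idx <- function(k) if (is.character(k)) match(k, colnames(data)) else as.integer(k)
  i <- idx(i); j <- idx(j); cond_set <- vapply(cond_set, idx, integer(1))
  if (anyNA(c(i, j, cond_set))) stop("unknown variable in test")
  if (i == j) stop("cannot test a variable against itself")
  if (i %in% cond_set || j %in% cond_set)
    stop("conditioning set must exclude the tested pair")
  n <- nrow(data)
  if (n <= length(cond_set) + 3L)
    stop("too few observations for conditioning set of size ", length(cond_set))
  if (length(cond_set) == 0L) {
    r <- stats::cor(data[, i], data[, j])
  } else {
    vars <- c(i, j, cond_set)
    R <- stats::cor(data[, vars, drop = FALSE])
    P <- tryCatch(solve(R), error = function(e)
      stop("singular conditioning covariance"))
    r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- atanh(r) * sqrt(n - length(cond_set) - 3)
  p <- 2 * stats::pnorm(-abs(z))
  list(i = i, j = j, cond_set = cond_set, r_partial = r, z = z, p = p,
       independent = p >= alpha)
}

#' PC-skeleton: the edge-deletion phase of the PC algorithm
#'
#' Starts from the complete undirected graph over the columns of `data` and
#' removes the edge (i, j) as soon as some subset of the current neighbours of
#' i (excluding j) or of j (excluding i), of size l = 0, 1, 2, ..., renders
#' the pair conditionally independent at level `alpha` (Fisher-z test).
#' Separation sets are recorded. Deterministic for a fixed column order:
#' pairs are visited lexicographically and subsets in [utils::combn()] order.
#'
#' @param data numeric matrix (observations x variables), e.g. BLUEs of the
#'   traits with significant genotypic variance.
#' @param alpha significance level of the conditional-independence tests.
#' @param max_order largest conditioning-set size to attempt.
#' @return list of class `pc_skeleton`: `adj` (logical adjacency matrix),
#'   `sepset` (list of lists), `tests` (data.frame log of every CI test).
#' @export
pc_skeleton <- function(data, alpha = 0.01, max_order = Inf) {
  data <- as.matrix(data)
  p <- ncol(data); n <- nrow(data)
  vn <- colnames(data)
  if (is.null(vn)) vn <- paste0("V", seq_len(p))
  adj <- matrix(TRUE, p, p, dimnames = list(vn, vn))
  diag(adj) <- FALSE
  sepset <- rep(list(rep(list(NULL), p)), p)
  log <- list()
  ell <- 0L
  repeat {
    if (n <= ell + 3L) {
      warning("sample size too small for conditioning sets of size ", ell,
              "; stopping skeleton search")
      break
    }
    any_big_enough <- FALSE
    for (i in seq_len(p - 1L)) {
      for (j in seq((i + 1L), p)) {
        if (!adj[i, j]) next
        removed <- FALSE
        for (side in list(c(i, j), c(j, i))) {
          a <- side[1]; b <- side[2]
          nbrs <- setdiff(which(adj[a, ]), b)
          if (length(nbrs) < ell) next
          any_big_enough <- TRUE
          subs <- if (ell == 0L) list(integer(0))
            else if (length(nbrs) == ell) list(nbrs)
            else utils::combn(nbrs, ell, simplify = FALSE)
          for (S in subs) {
            ct <- fisher_z_test(data, i, j, S, alpha)
            log[[length(log) + 1L]] <- data.frame(
              i = vn[i], j = vn[j],
              cond = paste(vn[S], collapse = ","),
              r_partial = ct$r_partial, p = ct$p,
              stringsAsFactors = FALSE)
            if (ct$p >= alpha) {
              adj[i, j] <- adj[j, i] <- FALSE
              sepset[[i]][[j]] <- sepset[[j]][[i]] <- S
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
    }
    ell <- ell + 1L
    if (ell > max_order) break
    max_deg <- max(rowSums(adj))
    if (max_deg - 1L < ell || !any(adj)) break
    if (!any_big_enough && ell > 1L) break
  }
  structure(list(adj = adj, sepset = sepset,
                 tests = if (length(log)) do.call(rbind, log) else NULL,
                 alpha = alpha),
            class = "pc_skeleton")
}

#' QTL-supervised orientation of a trait skeleton (QPSO)
#'
#' Adds each FDR-screened mQTL SNP as a node with a directed edge into its
#' trait, then uses the anchors to direct trait-trait edges by
#' instrumental-variable logic: an anchor q of trait yi (and not of yj) votes
#' for yi -> yj when q is marginally associated with yj (p < `alpha_orient`)
#' but independent of yj given yi (p >= `alpha_orient`). Each undirected edge
#' is oriented in its strict-majority direction; ties or zero votes leave it
#' undirected; an orientation that would close a directed cycle among traits
#' is skipped and logged. Trait-trait edges carry the pairwise Pearson
#' correlation, SNP edges carry p_G (percent genotypic variance explained).
#'
#' @param skeleton a [pc_skeleton()] result over the network traits.
#' @param sepsets separation sets from the skeleton (kept for interface
#'   compatibility; the voting scheme does not use them).
#' @param mqtl data.frame of anchors: columns `trait`, `snp`, `p_G`
#'   (FDR-significant at the network threshold, conventionally q < 0.10).
#' @param geno genotypes holding the anchor SNPs.
#' @param blues BLUE matrix over at least the network traits.
#' @param alpha_orient significance level of the orientation votes.
#' @return object of class `causal_network`: list with `nodes` (data.frame
#'   name, type) and `edges` (data.frame from, to, type in
#'   \{undirected, directed, qtl\}, weight), plus `skipped_cycles`.
#' @export
qpso_orient <- function(skeleton, sepsets = NULL, mqtl, geno, blues,
                        alpha_orient = 0.05) {
  stopifnot(inherits(skeleton, "pc_skeleton"))
  adj <- skeleton$adj
  traits <- rownames(adj)
  B <- unclass(blues)
  stopifnot(all(traits %in% colnames(B)))
  X <- impute_dosage_mean(as.matrix(geno))[rownames(B), , drop = FALSE]
  if (nrow(mqtl)) {
    missing_snp <- setdiff(mqtl$snp, colnames(X))
    if (length(missing_snp))
      stop("anchor SNPs absent from genotypes: ",
           paste(missing_snp, collapse = ", "))
    const <- vapply(mqtl$snp, function(s) stats::sd(X[, s]) == 0, logical(1))
    if (any(const)) {
      warning("skipping constant anchor SNP(s): ",
              paste(mqtl$snp[const], collapse = ", "))
      mqtl <- mqtl[!const, , drop = FALSE]
    }
  }
  anchors <- split(mqtl$snp, mqtl$trait)

  n <- nrow(B)
  marg_p <- function(q, y) {
    r <- stats::cor(X[, q], B[, y])
    2 * stats::pt(abs(r) * sqrt((n - 2) / max(1 - r^2, 1e-300)),
                  df = n - 2, lower.tail = FALSE)
  }
  cond_p <- function(q, y, given) {
    d <- cbind(X[, q], B[, c(y, given)])
    colnames(d) <- c("q", "y", "g")
    fisher_z_test(d, "q", "y", "g", alpha_orient)$p
  }

  dir_adj <- matrix(FALSE, length(traits), length(traits),
                    dimnames = list(traits, traits))
  reaches <- function(from, to) {
    seen <- from
    front <- from
    while (length(front)) {
      nxt <- unique(unlist(lapply(front, function(v) which(dir_adj[v, ]))))
      nxt <- setdiff(nxt, seen)
      if (to %in% nxt) return(TRUE)
      seen <- c(seen, nxt)
      front <- nxt
    }
    FALSE
  }

  edges <- list()
  skipped <- character(0)
  pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  ord <- order(pairs[, 1], pairs[, 2])
  votes_of <- function(yi, yj) {
    qs <- setdiff(anchors[[yi]] %||% character(0),
                  anchors[[yj]] %||% character(0))
    sum(vapply(qs, function(q)
      marg_p(q, yj) < alpha_orient && cond_p(q, yj, yi) >= alpha_orient,
      logical(1)))
  }
  for (k in ord) {
    yi <- traits[pairs[k, 1]]; yj <- traits[pairs[k, 2]]
    v_ij <- votes_of(yi, yj)
    v_ji <- votes_of(yj, yi)
    w <- stats::cor(B[, yi], B[, yj])
    if (v_ij > v_ji) {
      from <- yi; to <- yj
    } else if (v_ji > v_ij) {
      from <- yj; to <- yi
    } else {
      edges[[length(edges) + 1L]] <- data.frame(
        from = yi, to = yj, type = "undirected", weight = w,
        stringsAsFactors = FALSE)
      next
    }
    if (reaches(match(to, traits), match(from, traits))) {
      skipped <- c(skipped, paste0(from, "->", to))
      edges[[length(edges) + 1L]] <- data.frame(
        from = yi, to = yj, type = "undirected", weight = w,
        stringsAsFactors = FALSE)
    } else {
      dir_adj[match(from, traits), match(to, traits)] <- TRUE
      edges[[length(edges) + 1L]] <- data.frame(
        from = from, to = to, type = "directed", weight = w,
        stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(nrow(mqtl)))
    edges[[length(edges) + 1L]] <- data.frame(
      from = mqtl$snp[k], to = mqtl$trait[k], type = "qtl",
      weight = mqtl$p_G[k], stringsAsFactors = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               type = character(0), weight = numeric(0))
  nodes <- data.frame(
    name = c(traits, unique(mqtl$snp)),
    type = c(rep("trait", length(traits)),
             rep("snp", length(unique(mqtl$snp)))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, skipped_cycles = skipped),
            class = "causal_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.causal_network <- function(x, ...) {
  tab <- table(factor(x$edges$type, levels = c("directed", "undirected", "qtl")))
  cat(sprintf(
    "causal_network: %d trait node(s), %d SNP node(s); %d directed, %d undirected, %d QTL edge(s)\n",
    sum(x$nodes$type == "trait"), sum(x$nodes$type == "snp"),
    tab[["directed"]], tab[["undirected"]], tab[["qtl"]]))
  invisible(x)
}

causal_network_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  g
}

#' Export a causal network
#'
#' @param net a [qpso_orient()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @name network_export
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(causal_network_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname network_export
#' @export
write_dot <- function(net, path) {
  igraph::write_graph(causal_network_igraph(net), path, format = "dot")
  invisible(path)
}

#' @rdname network_export
#' @export
write_sif <- function(net, path) {
  rel <- c(undirected = "cor", directed = "causes", qtl = "mqtl")
  lines <- sprintf("%s\t%s\t%s", net$edges$from,
                   rel[net$edges$type], net$edges$to)
  writeLines(lines, path)
  invisible(path)
}
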